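# Image2D: single-channel raster with physical calibration.
#
# Pixels are stored as a numeric matrix of integer-valued intensities in
# [0, 2^bit_depth - 1], indexed [row, col] with row 1 at the top of the
# image (screen convention).  All geometric code converts to a y-up
# mathematical frame (x = col, y = -row) before computing angles.

#' Construct a calibrated 2D intensity image
#'
#' @param pixels numeric matrix of non-negative intensities (rows = image
#'   rows, top to bottom).  An array with a third dimension of size 3 (RGB)
#'   is converted to grayscale by luminance.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param hemisphere `"right"` or `"left"`; controls the orientation
#'   convention used when finalising cilium angles.
#' @param channel staining channel: `"ADCY3"` (cilia), `"DAPI"` (nuclei) or
#'   `"other"`.
#' @param bit_depth 8 or 16.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_um, hemisphere = c("right", "left"),
                    channel = c("other", "ADCY3", "DAPI"), bit_depth = 8L) {
  hemisphere <- match.arg(hemisphere)
  channel <- match.arg(channel)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    pixels <- rgb_to_gray(pixels)
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix (or RGB array)")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("pixels must be non-empty")
  if (anyNA(pixels) || any(pixels < 0)) stop("intensities must be non-negative")
  maxval <- 2^bit_depth - 1
  if (any(pixels > maxval)) {
    stop("intensities exceed declared bit depth (", bit_depth, "-bit)")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         hemisphere = hemisphere, channel = channel, bit_depth = bit_depth),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %dx%d px, %.4g um/px, %s, %s, %d-bit>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$hemisphere, x$channel, x$bit_depth))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' Convert an RGB array to grayscale by luminance
#'
#' Uses the Rec. 601 luminance weights (0.299 R + 0.587 G + 0.114 B), the
#' same weighting applied by OpenCV's BGR2GRAY conversion, rounded to the
#' nearest integer intensity.  Idempotent on single-channel input (a matrix
#' is returned unchanged).
#'
#' @param x numeric matrix or 3D array with 3 slices along dim 3.
#' @return numeric matrix.
#' @export
rgb_to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3] %in% c(1L, 3L, 4L))) {
    stop("expected a matrix or an array with 1, 3 or 4 channels")
  }
  if (dim(x)[3] == 1L) return(x[, , 1L])
  g <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
  round(g)
}

#' Read a raster image from disk
#'
#' Supported formats: PNG (8-bit and 16-bit, via the \pkg{png} package) and
#' uncompressed baseline TIFF (8/16-bit grayscale or 8-bit RGB, built-in
#' reader).  RGB inputs are converted to grayscale by luminance.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um physical calibration in micrometres per pixel;
#'   required, the file metadata is not trusted for this.
#' @param hemisphere,channel see [image2d()].
#' @return An [image2d()] object.
#' @export
read_image <- function(path, pixel_size_um, hemisphere = c("right", "left"),
                       channel = c("other", "ADCY3", "DAPI")) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    # readPNG scales to [0,1]; recover integer codes.  16-bit files produce
    # multiples of 1/65535, 8-bit of 1/255 -- detect by representability.
    codes8 <- raw * 255
    if (max(abs(codes8 - round(codes8))) < 1e-9) {
      pixels <- round(codes8); depth <- 8L
    } else {
      pixels <- round(raw * 65535); depth <- 16L
    }
  } else if (ext %in% c("tif", "tiff")) {
    tf <- read_tiff_minimal(path)
    pixels <- tf$pixels
    depth <- tf$bit_depth
  } else {
    stop("unsupported image format: .", ext)
  }
  if (is.array(pixels) && length(dim(pixels)) == 3L) pixels <- rgb_to_gray(pixels)
  image2d(pixels, pixel_size_um, hemisphere = match.arg(hemisphere),
          channel = match.arg(channel), bit_depth = depth)
}

#' Write an image to disk (lossless)
#'
#' PNG output uses the \pkg{png} package; `.tif`/`.tiff` writes a minimal
#' single-strip uncompressed TIFF.  Round-trips through [read_image()] are
#' bit-exact.
#'
#' @param image an [image2d()] object.
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image2d"))
  ext <- tolower(tools::file_ext(path))
  maxval <- 2^image$bit_depth - 1
  if (ext == "png") {
    if (image$bit_depth != 8L) {
      stop("PNG output supports 8-bit images only; use TIFF for 16-bit")
    }
    png::writePNG(image$pixels / maxval, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_minimal(image$pixels, path, bit_depth = image$bit_depth)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}
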