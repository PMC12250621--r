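# Cilia detection in ADCY3-channel images: contour extraction (Canny +
# morphology), contour filtering (length and aspect-ratio bounds), and
# length/width/angle measurement from the minimum-area rotated rectangle,
# with the base located at the brightest pixel and used to orient the
# base-to-tip direction.
#
# Coordinates: contours and record positions are 1-based (x = column,
# y = row, row 1 at the top).  Angles are reported in a y-up mathematical
# convention: 0 deg points to the image right, angles increase
# counter-clockwise.  For left-hemisphere images the final angle is
# mirrored across the vertical axis so that medial/lateral directions are
# comparable across hemispheres.

#' Cilia detection parameters
#'
#' Defaults follow the published pipeline: Canny lower threshold
#' `0.67 * median intensity` (the upper threshold, described only as
#' "slightly increased", defaults to the symmetric `1.33 * median`),
#' morphological closing with a 2x2 rectangle, erosion with a 1x1 rectangle
#' for one iteration (mathematically the identity, kept configurable),
#' retained lengths in (1, 15) micrometres and length/width ratio >= 1.5.
#'
#' @param canny_lower_factor,canny_upper_factor multiples of the median
#'   intensity used as Canny hysteresis thresholds.
#' @param close_kernel closing kernel size `c(rows, cols)`.
#' @param erode_kernel,erode_iterations erosion kernel and iteration count.
#' @param min_length_um,max_length_um length filter bounds (micrometres).
#' @param min_aspect minimum length/width ratio.
#' @param blur_kernel Gaussian blur kernel size (odd).
#' @param drop_border drop contours touching the image border (default
#'   keeps them).
#' @param base_search `"mask"` searches the brightest pixel within the
#'   filled contour mask; `"bbox"` within the axis-aligned bounding box.
#' @param length_mode `"min_area_rect"` (default) measures the rotated
#'   minimum-area rectangle; `"bounding_box"` the axis-aligned box.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(canny_lower_factor = 0.67,
                             canny_upper_factor = 1.33,
                             close_kernel = c(2L, 2L),
                             erode_kernel = c(1L, 1L),
                             erode_iterations = 1L,
                             min_length_um = 1,
                             max_length_um = 15,
                             min_aspect = 1.5,
                             blur_kernel = 3L,
                             drop_border = FALSE,
                             base_search = c("mask", "bbox"),
                             length_mode = c("min_area_rect", "bounding_box")) {
  stopifnot(canny_lower_factor > 0, canny_upper_factor > 0,
            min_length_um > 0, max_length_um > min_length_um,
            min_aspect >= 1, blur_kernel %% 2 == 1)
  structure(list(
    canny_lower_factor = canny_lower_factor,
    canny_upper_factor = canny_upper_factor,
    close_kernel = as.integer(close_kernel),
    erode_kernel = as.integer(erode_kernel),
    erode_iterations = as.integer(erode_iterations),
    min_length_um = min_length_um,
    max_length_um = max_length_um,
    min_aspect = min_aspect,
    blur_kernel = as.integer(blur_kernel),
    drop_border = isTRUE(drop_border),
    base_search = match.arg(base_search),
    length_mode = match.arg(length_mode)
  ), class = "detection_params")
}

#' Preprocess an image for edge detection
#'
#' Gaussian blur (default 3x3) on the grayscale intensities; dimensions are
#' preserved and total intensity is approximately conserved away from the
#' borders.
#'
#' @param image an [image2d()].
#' @param params [detection_params()].
#' @return blurred [image2d()].
#' @export
preprocess <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "image2d"))
  out <- image
  out$pixels <- gaussian_blur_matrix(image$pixels, params$blur_kernel)
  maxval <- 2^image$bit_depth - 1
  out$pixels[out$pixels < 0] <- 0
  out$pixels[out$pixels > maxval] <- maxval
  out
}

#' Extract candidate cilia contours
#'
#' Canny edge detection with thresholds tied to the median intensity
#' (lower = `canny_lower_factor * median`, upper = `canny_upper_factor *
#' median`), morphological closing (2x2) and erosion (1x1, one iteration),
#' then external contours of the resulting binary map.
#'
#' @param image preprocessed [image2d()].
#' @param params [detection_params()].
#' @return list of contours (`n x 2` matrices, columns `x`, `y`), with the
#'   post-morphology binary map attached as attribute `"binary"`.
#' @export
extract_cilia_contours <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "image2d"))
  m <- image$pixels
  med <- stats::median(m)
  edges <- canny_edges(m, lower = params$canny_lower_factor * med,
                       upper = params$canny_upper_factor * med)
  closed <- binary_close(edges, params$close_kernel)
  eroded <- binary_erode(closed, params$erode_kernel,
                         params$erode_iterations)
  contours <- extract_contours(eroded)
  attr(contours, "binary") <- eroded
  contours
}

contour_touches_border <- function(contour, dims) {
  any(contour[, 1] == 1L | contour[, 1] == dims[2] |
      contour[, 2] == 1L | contour[, 2] == dims[1])
}

#' Filter contours by physical length and aspect ratio
#'
#' Keeps contours whose minimum-area-rectangle length converted to
#' micrometres lies strictly within `(min_length_um, max_length_um)` and
#' whose length/width ratio is at least `min_aspect` (a zero-width
#' degenerate contour has infinite aspect).  Input order is preserved.
#'
#' @param contours list of contours from [extract_cilia_contours()].
#' @param image the source [image2d()] (supplies the pixel calibration and
#'   bounds for the border filter).
#' @param params [detection_params()].
#' @return filtered list of contours.
#' @export
filter_cilia_contours <- function(contours, image, params = detection_params()) {
  ps <- image$pixel_size_um
  keep <- vapply(contours, function(ct) {
    if (params$drop_border && contour_touches_border(ct, dim(image$pixels))) {
      return(FALSE)
    }
    meas <- measure_cilium(ct, ps, length_mode = params$length_mode)
    aspect <- if (meas$width_um > 0) meas$length_um / meas$width_um else Inf
    meas$length_um > params$min_length_um &&
      meas$length_um < params$max_length_um &&
      aspect >= params$min_aspect
  }, logical(1))
  contours[keep]
}

#' Measure length, width and raw orientation of one contour
#'
#' The minimum-area rotated rectangle of the contour points gives the
#' length (long side), width (short side) and the orientation of the long
#' axis, reported modulo 180 degrees in the y-up mathematical convention.
#' With `length_mode = "bounding_box"` the axis-aligned box is used instead
#' (angle 0 or 90).
#'
#' @param contour `n x 2` matrix (columns `x`, `y` in image coordinates).
#' @param pixel_size_um micrometres per pixel.
#' @param length_mode see [detection_params()].
#' @return list with `length_um`, `width_um`, `raw_angle_deg` in [0, 180),
#'   `center` (x, y image coordinates) and `degenerate` flag (zero width).
#' @export
measure_cilium <- function(contour, pixel_size_um,
                           length_mode = c("min_area_rect", "bounding_box")) {
  length_mode <- match.arg(length_mode)
  # flip to y-up so reported angles are in math convention
  pts <- cbind(contour[, 1], -contour[, 2])
  if (length_mode == "min_area_rect") {
    rect <- min_area_rect(pts)
  } else {
    dx <- diff(range(pts[, 1])); dy <- diff(range(pts[, 2]))
    rect <- list(length = max(dx, dy), width = min(dx, dy),
                 angle_deg = if (dx >= dy) 0 else 90,
                 center = c(mean(range(pts[, 1])), mean(range(pts[, 2]))))
  }
  list(length_um = rect$length * pixel_size_um,
       width_um = rect$width * pixel_size_um,
       raw_angle_deg = rect$angle_deg %% 180,
       center = c(rect$center[1], -rect$center[2]),
       degenerate = rect$width == 0)
}

#' Locate the cilium base (brightest pixel)
#'
#' The base (basal body) is assumed to be the most brightly stained part of
#' the cilium.  The contour is rasterised, interior holes are filled, and
#' the maximum-intensity pixel of the image within that mask is returned;
#' ties are broken deterministically (smallest row, then smallest column).
#'
#' @param contour `n x 2` matrix (columns `x`, `y`).
#' @param image [image2d()] supplying intensities (typically the original,
#'   unblurred grayscale).
#' @param search `"mask"` restricts the search to the filled contour mask,
#'   `"bbox"` to the axis-aligned bounding box of the contour.
#' @return numeric `c(x, y)` of the brightest pixel.
#' @export
locate_base <- function(contour, image, search = c("mask", "bbox")) {
  search <- match.arg(search)
  if (nrow(contour) == 0L) stop("empty contour")
  px <- image$pixels
  x0 <- max(1L, min(contour[, 1])); x1 <- min(ncol(px), max(contour[, 1]))
  y0 <- max(1L, min(contour[, 2])); y1 <- min(nrow(px), max(contour[, 2]))
  crop <- px[y0:y1, x0:x1, drop = FALSE]
  if (search == "mask") {
    mask <- matrix(0L, nrow(crop), ncol(crop))
    mask[cbind(contour[, 2] - y0 + 1L, contour[, 1] - x0 + 1L)] <- 1L
    mask <- fill_holes(mask)
    vals <- ifelse(mask != 0, crop, -Inf)
  } else {
    vals <- crop
  }
  best <- max(vals)
  if (!is.finite(best)) stop("empty mask")
  hits <- which(vals == best, arr.ind = TRUE)
  # raster-order tie-break: smallest row, then smallest column
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(x = unname(hits[1, 2] + x0 - 1L), y = unname(hits[1, 1] + y0 - 1L))
}

#' Resolve the base-to-tip orientation of a cilium
#'
#' The raw long-axis orientation is only defined modulo 180 degrees; the
#' relative position of the base and the rectangle centre picks the true
#' direction: if the axis unit vector points away from the centre as seen
#' from the base (negative dot product with centre - base in y-up
#' coordinates), 180 degrees is added.  For the left hemisphere the result
#' is mirrored across the vertical axis, `theta -> (180 - theta) mod 360`,
#' so angles from the two hemispheres share a medial/lateral convention.
#'
#' @param raw_angle_deg long-axis orientation in [0, 180).
#' @param base_xy,centroid_xy positions in image coordinates (x, y with y
#'   increasing downwards).
#' @param hemisphere `"right"` or `"left"`.
#' @return angle in degrees in [0, 360), or `NA` (with a warning) when base
#'   and centroid coincide.
#' @export
finalize_angle <- function(raw_angle_deg, base_xy, centroid_xy,
                           hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  v <- c(centroid_xy[1] - base_xy[1], -(centroid_xy[2] - base_xy[2]))
  if (sqrt(sum(v^2)) < .Machine$double.eps) {
    warning("base coincides with centroid; angle undefined")
    return(NA_real_)
  }
  rad <- raw_angle_deg * pi / 180
  u <- c(cos(rad), sin(rad))
  ang <- raw_angle_deg
  if (sum(u * v) < 0) ang <- ang + 180
  ang <- ang %% 360
  if (hemisphere == "left") ang <- (180 - ang) %% 360
  ang
}

#' Detect and measure cilia in an ADCY3-channel image
#'
#' Full pipeline: Gaussian preprocessing, Canny/morphology contour
#' extraction, length and aspect filtering, minimum-area-rectangle
#' measurement, brightest-pixel base location (on the blurred working
#' image, so single-pixel noise spikes cannot outshine the basal body) and
#' base-to-tip angle resolution.  Deterministic for fixed
#' input and parameters; contours whose angle is undefined (base at the
#' centroid) are skipped with a log message.
#'
#' @param image [image2d()] (ADCY3 channel).
#' @param params [detection_params()].
#' @param section_id,region_label,zt metadata copied into every record.
#' @return data.frame with columns `id, section_id, region_label,
#'   hemisphere, zt, length_um, width_um, angle_deg, base_x, base_y,
#'   centroid_x, centroid_y`.
#' @export
detect_cilia <- function(image, params = detection_params(),
                         section_id = NA, region_label = NA, zt = NA) {
  stopifnot(inherits(image, "image2d"))
  pre <- preprocess(image, params)
  contours <- extract_cilia_contours(pre, params)
  kept <- filter_cilia_contours(contours, image, params)
  rows <- list()
  skipped <- 0L
  for (ct in kept) {
    meas <- measure_cilium(ct, image$pixel_size_um,
                           length_mode = params$length_mode)
    base <- tryCatch(locate_base(ct, pre, search = params$base_search),
                     error = function(e) NULL)
    if (is.null(base)) { skipped <- skipped + 1L; next }
    ang <- suppressWarnings(
      finalize_angle(meas$raw_angle_deg, base, meas$center, image$hemisphere)
    )
    if (is.na(ang)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA_integer_, section_id = section_id, region_label = region_label,
      hemisphere = image$hemisphere, zt = zt,
      length_um = meas$length_um, width_um = meas$width_um, angle_deg = ang,
      base_x = base[["x"]], base_y = base[["y"]],
      centroid_x = meas$center[1], centroid_y = meas$center[2],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = integer(0), section_id = character(0), region_label = character(0),
    hemisphere = character(0), zt = numeric(0), length_um = numeric(0),
    width_um = numeric(0), angle_deg = numeric(0), base_x = numeric(0),
    base_y = numeric(0), centroid_x = numeric(0), centroid_y = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) out$id <- seq_len(nrow(out))
  cm_log("detect_cilia: %d contours, %d kept after filters, %d records (%d skipped)",
         length(contours), length(kept), nrow(out), skipped)
  out
}

# Structured logging to stderr, silenced unless options(ciliomorph.verbose)
cm_log <- function(fmt, ...) {
  if (isTRUE(getOption("ciliomorph.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
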