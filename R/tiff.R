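# Minimal baseline TIFF support (uncompressed, single image).
#
# Scope: what a microscope export or this package itself produces --
# grayscale 8/16-bit or RGB 8-bit, compression "none".  Anything fancier
# (LZW, tiles, planar RGB) is rejected with a clear error.  Little-endian
# and big-endian files are both read; files are always written
# little-endian, single strip.

read_tiff_minimal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (identical(as.integer(magic[1:2]), c(0x49L, 0x49L))) {
    endian <- "little"
  } else if (identical(as.integer(magic[1:2]), c(0x4DL, 0x4DL))) {
    endian <- "big"
  } else stop("not a TIFF file: ", path)
  rd <- function(n, size) {
    # sizes 1/2 are unsigned fields; size 4 must be read signed (R limit),
    # fine for any offset below 2^31
    readBin(con, "integer", n = n, size = size, signed = size == 4L,
            endian = endian)
  }
  ifd_offset <- rd(1L, 4L)
  seek(con, ifd_offset)
  n_entries <- rd(1L, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- rd(1L, 2L)
    typ <- rd(1L, 2L)
    cnt <- rd(1L, 4L)
    type_size <- c(1L, 1L, 2L, 4L, 8L)[typ]
    if (is.na(type_size)) type_size <- 4L
    here <- seek(con, NA)
    if (type_size * cnt <= 4L) {
      vals <- switch(as.character(typ),
        "1" = rd(cnt, 1L), "3" = rd(cnt, 2L), "4" = rd(cnt, 4L),
        rd(1L, 4L))
      seek(con, here + 4L)
    } else {
      off <- rd(1L, 4L)
      seek(con, off)
      vals <- switch(as.character(typ),
        "1" = rd(cnt, 1L), "3" = rd(cnt, 2L), "4" = rd(cnt, 4L),
        "5" = rd(2L * cnt, 4L),
        rd(cnt, 4L))
      seek(con, here + 4L)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 8L)[1]
  compression <- need(259, 1L)
  spp <- need(277, 1L)
  if (compression != 1L) stop("only uncompressed TIFF is supported")
  if (!bits %in% c(8L, 16L)) stop("only 8- or 16-bit TIFF is supported")
  if (spp == 3L && bits != 8L) stop("RGB TIFF must be 8-bit")
  planar <- need(284, 1L)
  if (planar != 1L) stop("planar TIFF not supported")
  offsets <- need(273)
  counts <- need(279, width * height * spp * (bits / 8L))
  bytes <- raw(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    bytes <- c(bytes, readBin(con, "raw", counts[i]))
  }
  if (bits == 8L) {
    vals <- as.integer(bytes)
  } else {
    vals <- readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                    signed = FALSE, endian = endian)
  }
  if (spp == 1L) {
    pixels <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    px <- array(0, dim = c(height, width, 3L))
    for (k in 1:3) {
      px[, , k] <- matrix(vals[seq(k, length(vals), by = 3L)],
                          nrow = height, ncol = width, byrow = TRUE)
    }
    pixels <- px
  }
  list(pixels = pixels, bit_depth = as.integer(bits))
}

write_tiff_minimal <- function(pixels, path, bit_depth = 8L) {
  stopifnot(is.matrix(pixels))
  height <- nrow(pixels); width <- ncol(pixels)
  nbytes <- as.integer(bit_depth / 8L)
  data_len <- width * height * nbytes
  # layout: 8-byte header, pixel data, IFD
  data_offset <- 8L
  ifd_offset <- data_offset + data_len
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_offset)
  vals <- as.integer(t(pixels)) # row-major
  if (bit_depth == 8L) {
    writeBin(as.raw(vals), con)
  } else {
    # writeBin size=2 rejects values >= 2^15 as signed; wrap manually
    vals[vals >= 32768L] <- vals[vals >= 32768L] - 65536L
    writeBin(vals, con, size = 2L, endian = "little")
  }
  entry <- function(tag, typ, cnt, val) { w2(tag); w2(typ); w4(cnt); w4(val) }
  n_entries <- 8L
  w2(n_entries)
  entry(256L, 4L, 1L, width)        # ImageWidth
  entry(257L, 4L, 1L, height)       # ImageLength
  entry(258L, 3L, 1L, bit_depth)    # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)  # StripOffsets
  entry(278L, 4L, 1L, height)       # RowsPerStrip
  entry(279L, 4L, 1L, data_len)     # StripByteCounts
  w4(0L)                            # no further IFD
  invisible(path)
}
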