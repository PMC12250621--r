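# Raster operations used by the detection pipelines.  All functions work on
# plain numeric matrices in screen convention (row 1 = top).  Heavy
# per-pixel passes (components, tracing, EDT, hysteresis, CLAHE) live in
# compiled code; everything here is vectorised R.

pad_replicate <- function(m, top, bottom = top, left = top, right = left) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, top), seq_len(nr), rep(nr, bottom))
  ci <- c(rep(1L, left), seq_len(nc), rep(nc, right))
  m[ri, ci, drop = FALSE]
}

# Direct 2D correlation with replicate border; kernel must have odd sides.
convolve2d_replicate <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1L) / 2L; pc <- (kc - 1L) / 2L
  p <- pad_replicate(m, pr, pr, pc, pc)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w == 0) next
      out <- out + w * p[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

gaussian_kernel_1d <- function(ksize, sigma = 0) {
  if (sigma <= 0) sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  x <- seq_len(ksize) - (ksize + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing, separable, replicate border.  With `round = TRUE`
# intensities are rounded back to integers (8-bit pipeline behaviour).
gaussian_blur_matrix <- function(m, ksize = 3L, sigma = 0, round = TRUE) {
  k <- gaussian_kernel_1d(ksize, sigma)
  out <- convolve2d_replicate(m, matrix(k, ncol = 1))
  out <- convolve2d_replicate(out, matrix(k, nrow = 1))
  if (round) round(out) else out
}

sobel_gradients <- function(m) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) # d/dx (cols)
  sy <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE) # d/drow
  list(gx = convolve2d_replicate(m, sx), gy = convolve2d_replicate(m, sy))
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr); cs <- seq_len(nc)
  rsrc <- rs - dr; csrc <- cs - dc
  rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

#' Canny edge detection
#'
#' Classical Canny on an already-smoothed image: Sobel gradients, L1
#' gradient magnitude, non-maximum suppression along the quantised gradient
#' direction, and double-threshold hysteresis (weak edges are kept only when
#' 8-connected to a strong edge).
#'
#' @param m numeric intensity matrix.
#' @param lower,upper hysteresis thresholds on the L1 gradient magnitude.
#' @return binary (0/1) integer matrix of edge pixels.
#' @export
canny_edges <- function(m, lower, upper) {
  g <- sobel_gradients(m)
  mag <- abs(g$gx) + abs(g$gy)
  # quantise gradient direction to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
            ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  # neighbours along the gradient direction (gx ~ columns, gy ~ rows)
  n1 <- matrix(0, nrow(m), ncol(m)); n2 <- n1
  pick <- function(dr, dc) shift_matrix(mag, dr, dc, fill = 0)
  s0 <- sector == 0L    # horizontal gradient -> compare left/right
  s90 <- sector == 90L  # vertical gradient -> compare up/down
  s45 <- sector == 45L
  s135 <- sector == 135L
  n1[s0] <- pick(0, 1)[s0];    n2[s0] <- pick(0, -1)[s0]
  n1[s90] <- pick(1, 0)[s90];  n2[s90] <- pick(-1, 0)[s90]
  n1[s45] <- pick(1, 1)[s45];  n2[s45] <- pick(-1, -1)[s45]
  n1[s135] <- pick(1, -1)[s135]; n2[s135] <- pick(-1, 1)[s135]
  keep <- mag >= n1 & mag > n2
  strong <- keep & (mag > upper)
  weak <- keep & (mag > lower)
  .hysteresis(matrix(as.integer(strong), nrow(m)),
              matrix(as.integer(weak), nrow(m)))
}

# Binary morphology with a rectangular kernel.  Offsets follow the OpenCV
# default anchor at floor(k/2); a (1,1) kernel is the identity.
kernel_offsets <- function(ksize) {
  kr <- ksize[1]; kc <- ksize[2]
  ar <- kr %/% 2L; ac <- kc %/% 2L
  expand.grid(dr = seq_len(kr) - 1L - ar, dc = seq_len(kc) - 1L - ac)
}

#' @rdname morphology
#' @export
binary_dilate <- function(mask, ksize = c(3L, 3L), iterations = 1L) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  off <- kernel_offsets(ksize)
  for (it in seq_len(iterations)) {
    acc <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_len(nrow(off))) {
      acc <- acc | shift_matrix(m, off$dr[i], off$dc[i], fill = 0)
    }
    m <- matrix(as.integer(acc), nrow(m))
  }
  m
}

#' Binary morphology with rectangular kernels
#'
#' `binary_dilate`, `binary_erode` and `binary_close` (dilation followed by
#' erosion) on 0/1 masks.  Pixels outside the image count as background, so
#' erosion shrinks objects touching the border.  A 1x1 kernel is the
#' identity for all three operations.
#'
#' @param mask binary matrix (anything non-zero is foreground).
#' @param ksize kernel size `c(rows, cols)`.
#' @param iterations number of applications.
#' @return binary (0/1) integer matrix.
#' @name morphology
#' @export
binary_erode <- function(mask, ksize = c(3L, 3L), iterations = 1L) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  off <- kernel_offsets(ksize)
  for (it in seq_len(iterations)) {
    acc <- matrix(TRUE, nrow(m), ncol(m))
    for (i in seq_len(nrow(off))) {
      # erosion mirrors the dilation offsets
      acc <- acc & (shift_matrix(m, -off$dr[i], -off$dc[i], fill = 0) != 0)
    }
    m <- matrix(as.integer(acc), nrow(m))
  }
  m
}

#' @rdname morphology
#' @export
binary_close <- function(mask, ksize = c(2L, 2L)) {
  binary_erode(binary_dilate(mask, ksize), ksize)
}

# Local mean over a block x block window (replicate border) via integral
# image; block must be odd.
box_mean <- function(m, block) {
  stopifnot(block %% 2 == 1)
  h <- (block - 1L) / 2L
  p <- pad_replicate(m, h, h, h, h)
  cs <- apply(p, 2, cumsum)      # cumulate down rows
  cs <- t(apply(cs, 1, cumsum))  # then across columns
  sat <- rbind(0, cbind(0, cs))  # sat[a+1, b+1] = sum p[1..a, 1..b]
  nr <- nrow(m); nc <- ncol(m)
  r1 <- seq_len(nr); r2 <- r1 + block
  c1 <- seq_len(nc); c2 <- c1 + block
  s <- sat[r2, c2] - sat[r1, c2] - sat[r2, c1] + sat[r1, c1]
  s / (block * block)
}

#' Adaptive mean threshold
#'
#' Binarises an image against its local mean: a pixel is foreground when
#' `value > local_mean(block) - C`.  This matches OpenCV's
#' `ADAPTIVE_THRESH_MEAN_C` / `THRESH_BINARY` semantics, where the local
#' mean is rounded to the nearest integer before comparison.
#'
#' @param m numeric intensity matrix.
#' @param block odd window size in pixels.
#' @param C offset subtracted from the local mean (negative values make the
#'   threshold stricter).
#' @return binary (0/1) integer matrix.
#' @export
adaptive_threshold_mean <- function(m, block = 41L, C = -10) {
  thr <- round(box_mean(m, block)) - C
  matrix(as.integer(m > thr), nrow(m))
}

#' Exact Euclidean distance transform
#'
#' Distance from every foreground pixel to the nearest background (zero)
#' pixel, computed with the exact two-pass lower-envelope algorithm.
#'
#' @param mask binary matrix.
#' @return numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) {
  .edt_l2(matrix(as.integer(mask != 0), nrow(mask)))
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' 8-bit CLAHE with a tile grid and clip limit, bilinear interpolation
#' between the per-tile mappings.
#'
#' @param m numeric matrix with values in 0..255.
#' @param clip_limit contrast clip limit (histogram clip threshold is
#'   `clip_limit * tile_area / 256`).
#' @param tiles `c(rows, cols)` tile grid.
#' @return integer matrix in 0..255.
#' @export
clahe <- function(m, clip_limit = 2.0, tiles = c(8L, 8L)) {
  .clahe8(matrix(as.integer(round(m)), nrow(m)), clip_limit,
          as.integer(tiles[1]), as.integer(tiles[2]))
}

#' Label connected components (8-connectivity)
#'
#' @param mask binary matrix.
#' @return integer matrix of labels (0 = background) with attribute `n`,
#'   the number of components.
#' @export
label_components <- function(mask) {
  .cc_label8(matrix(as.integer(mask != 0), nrow(mask)))
}

# External boundary of one labelled component as an ordered (x, y) matrix
# (x = column, y = row, both 1-based).
component_contour <- function(lab, id, start = NULL) {
  if (is.null(start)) start <- c(-1L, -1L)
  pts <- .trace_boundary(lab, as.integer(id), start[1] - 1L, start[2] - 1L)
  cbind(x = pts[, 2], y = pts[, 1])
}

#' Extract external contours from a binary mask
#'
#' Labels 8-connected foreground components and traces the outer boundary
#' of each with Moore neighbour tracing, mirroring contour retrieval with
#' external-only mode in mainstream image libraries.  Contours are returned
#' in raster order of their top-left pixel.
#'
#' @param mask binary matrix.
#' @return list of contours, each an `n x 2` matrix with columns `x`
#'   (column) and `y` (row), 1-based.
#' @export
extract_contours <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n")
  if (n == 0L) return(list())
  # first pixel of each component in scan order (column-major = C++ scan)
  idx <- which(lab != 0)
  labs <- lab[idx]
  firsts <- idx[!duplicated(labs)]
  fl <- labs[!duplicated(labs)]
  first_idx <- integer(n)
  first_idx[fl] <- firsts
  nr <- nrow(lab)
  lapply(seq_len(n), function(id) {
    i0 <- first_idx[id]
    component_contour(lab, id,
                      start = c((i0 - 1L) %% nr + 1L, (i0 - 1L) %/% nr + 1L))
  })
}

# Fill interior holes of a binary mask (4-connected background flood from
# the frame).
fill_holes <- function(mask) {
  .fill_holes(matrix(as.integer(mask != 0), nrow(mask)))
}
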