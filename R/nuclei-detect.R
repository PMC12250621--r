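# DAPI nuclei detection for cilia-density quantification: CLAHE contrast
# enhancement, adaptive mean thresholding, distance-transform refinement,
# external contour extraction, density-based centroid clustering with
# convex-hull merging, and area/circularity filtering.

#' Nuclei detection parameters
#'
#' Defaults follow the published density pipeline: CLAHE clip 2.0 with an
#' 8x8 tile grid; adaptive mean threshold with block size 41 and offset
#' C = -10; distance map normalised to [0, 1] by its maximum and
#' thresholded at 0.2; 3x3 dilation (1 iteration); DBSCAN on contour
#' centroids with eps = 30 px and min_samples = 1; area filter 20..1000
#' square pixels and minimum circularity 0.01.
#'
#' @param clahe_clip,clahe_tile CLAHE clip limit and tile grid.
#' @param adaptive_block,adaptive_C adaptive threshold window and offset.
#' @param dist_thresh threshold on the max-normalised distance map.
#' @param dilate_kernel,dilate_iterations dilation of the sure-foreground.
#' @param dbscan_eps_px,dbscan_min_samples centroid clustering radius and
#'   minimum cluster size (1 = no noise points).
#' @param min_area_px,max_area_px,min_circularity cell filters.
#' @return list of class `nuclei_params`.
#' @export
nuclei_params <- function(clahe_clip = 2.0, clahe_tile = c(8L, 8L),
                          adaptive_block = 41L, adaptive_C = -10,
                          dist_thresh = 0.2,
                          dilate_kernel = c(3L, 3L), dilate_iterations = 1L,
                          dbscan_eps_px = 30, dbscan_min_samples = 1L,
                          min_area_px = 20, max_area_px = 1000,
                          min_circularity = 0.01) {
  stopifnot(clahe_clip > 0, adaptive_block %% 2 == 1, dist_thresh > 0,
            dbscan_eps_px > 0, min_area_px < max_area_px)
  structure(list(
    clahe_clip = clahe_clip, clahe_tile = as.integer(clahe_tile),
    adaptive_block = as.integer(adaptive_block), adaptive_C = adaptive_C,
    dist_thresh = dist_thresh, dilate_kernel = as.integer(dilate_kernel),
    dilate_iterations = as.integer(dilate_iterations),
    dbscan_eps_px = dbscan_eps_px,
    dbscan_min_samples = as.integer(dbscan_min_samples),
    min_area_px = min_area_px, max_area_px = max_area_px,
    min_circularity = min_circularity
  ), class = "nuclei_params")
}

#' Segment the sure-foreground mask of a DAPI image
#'
#' CLAHE (clip 2.0, 8x8 tiles), adaptive local-mean binary threshold
#' (block 41, C = -10), exact Euclidean distance transform normalised to
#' [0, 1] by its global maximum and thresholded at 0.2, then one 3x3
#' dilation.  The sure-background and "unknown" regions of the classical
#' marker construction are derivable from this mask but are not used
#' downstream (contours are extracted directly from the sure foreground).
#'
#' @param image [image2d()] (DAPI channel, 8-bit).
#' @param params [nuclei_params()].
#' @return binary (0/1) integer matrix (sure foreground).
#' @export
segment_nuclei_foreground <- function(image, params = nuclei_params()) {
  stopifnot(inherits(image, "image2d"))
  m <- image$pixels
  if (image$bit_depth != 8L) m <- round(m / (2^image$bit_depth - 1) * 255)
  eq <- clahe(m, params$clahe_clip, params$clahe_tile)
  bin <- adaptive_threshold_mean(eq, params$adaptive_block, params$adaptive_C)
  d <- distance_transform(bin)
  dmax <- max(d)
  if (dmax > 0) d <- d / dmax
  fg <- matrix(as.integer(d > params$dist_thresh), nrow(d))
  binary_dilate(fg, params$dilate_kernel, params$dilate_iterations)
}

#' Extract external contours of foreground objects
#'
#' @param mask binary matrix (e.g. from [segment_nuclei_foreground()]).
#' @return list of contours (`n x 2` matrices, columns `x`, `y`).
#' @export
extract_cell_contours <- function(mask) {
  extract_contours(mask)
}

# union-find single-linkage clustering: DBSCAN with min_samples = 1 reduces
# to connected components of the eps-neighbourhood graph
dbscan_min1 <- function(xy, eps) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0, n - 1))) {
    di <- sqrt((xy[(i + 1):n, 1] - xy[i, 1])^2 +
               (xy[(i + 1):n, 2] - xy[i, 2])^2)
    for (j in which(di <= eps)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Cluster nearby contours and merge each cluster into a convex hull
#'
#' Contour centroids are clustered with DBSCAN (Euclidean, radius
#' `dbscan_eps_px`, `min_samples = 1`, so every contour belongs to exactly
#' one cluster and clustering is transitive).  Each cluster is replaced by
#' the convex hull of all member contour points, re-joining fragments of a
#' single nucleus.
#'
#' @param contours list of contours.
#' @param params [nuclei_params()].
#' @return list of convex-hull contours (ordered vertices), one per cluster.
#' @export
cluster_and_merge <- function(contours, params = nuclei_params()) {
  if (length(contours) == 0L) return(list())
  cents <- t(vapply(contours, function(ct) colMeans(ct), numeric(2)))
  cl <- dbscan_min1(cents, params$dbscan_eps_px)
  lapply(seq_len(max(cl)), function(k) {
    pts <- do.call(rbind, contours[cl == k])
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts[h, , drop = FALSE]
  })
}

#' Filter merged hulls into cell records
#'
#' Keeps hulls with area in `[min_area_px, max_area_px]` square pixels and
#' circularity `4 * pi * Area / Perimeter^2 >= min_circularity`.  Area and
#' perimeter are polygon (shoelace) measures of the convex hull;
#' zero-perimeter hulls are skipped with a log entry.
#'
#' @param hulls list of convex hull contours from [cluster_and_merge()].
#' @param params [nuclei_params()].
#' @return data.frame with columns `id, centroid_x, centroid_y, area_px2,
#'   perimeter_px, circularity`, plus the kept hulls as attribute `"hulls"`.
#' @export
filter_cells <- function(hulls, params = nuclei_params()) {
  rows <- list(); kept <- list()
  for (h in hulls) {
    a <- polygon_area(h)
    p <- polygon_perimeter(h)
    if (p <= 0) { cm_log("filter_cells: zero-perimeter hull skipped"); next }
    circ <- 4 * pi * a / p^2
    if (a < params$min_area_px || a > params$max_area_px) next
    if (circ < params$min_circularity) next
    kept[[length(kept) + 1L]] <- h
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA_integer_, centroid_x = mean(h[, 1]), centroid_y = mean(h[, 2]),
      area_px2 = a, perimeter_px = p, circularity = circ
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = integer(0), centroid_x = numeric(0), centroid_y = numeric(0),
    area_px2 = numeric(0), perimeter_px = numeric(0), circularity = numeric(0)
  )
  if (nrow(out)) out$id <- seq_len(nrow(out))
  attr(out, "hulls") <- kept
  out
}

#' Detect DAPI-stained cells
#'
#' Composition of [segment_nuclei_foreground()], [extract_cell_contours()],
#' [cluster_and_merge()] and [filter_cells()]; deterministic for fixed
#' input and parameters.
#'
#' @param image [image2d()] (DAPI channel).
#' @param params [nuclei_params()].
#' @return data.frame of cell records (see [filter_cells()]).
#' @export
detect_cells <- function(image, params = nuclei_params()) {
  fg <- segment_nuclei_foreground(image, params)
  contours <- extract_cell_contours(fg)
  hulls <- cluster_and_merge(contours, params)
  out <- filter_cells(hulls, params)
  cm_log("detect_cells: %d contours, %d clusters, %d cells",
         length(contours), length(hulls), nrow(out))
  out
}
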