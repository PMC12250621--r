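# Planar geometry helpers: minimum-area enclosing rectangle (rotating
# calipers over the convex hull), polygon area/perimeter, and segment
# distances used by the synthetic scene generator.

#' Minimum-area enclosing rectangle
#'
#' Rotating-calipers search over the convex hull: the minimum-area
#' rectangle has one side collinear with a hull edge, so all hull edge
#' directions are enumerated.  Degenerate inputs (all points collinear)
#' yield a zero-width rectangle along the principal extent.
#'
#' @param pts `n x 2` matrix of (x, y) coordinates.
#' @return list with `length` (long side), `width` (short side), `angle_deg`
#'   (orientation of the long side, in [0, 180), measured counter-clockwise
#'   from +x in the coordinate frame of `pts`), and `center` (x, y).
#' @export
min_area_rect <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1L) {
    return(list(length = 0, width = 0, angle_deg = 0,
                center = c(pts[1, 1], pts[1, 2])))
  }
  degenerate_rect <- function(p) {
    # all points collinear: span along the direction of maximal extent
    dm <- as.matrix(stats::dist(p))
    ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    a <- p[ij[1], ]; b <- p[ij[2], ]
    ang <- atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi
    list(length = unname(sqrt(sum((b - a)^2))), width = 0,
         angle_deg = unname(ang %% 180), center = unname((a + b) / 2))
  }
  if (n == 2L) return(degenerate_rect(pts))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3L) return(degenerate_rect(pts))
  best <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area - 1e-12) {
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(area = area, du = du, dv = dv, u = u, v = v,
                   center = cu * u + cv * v)
    }
  }
  if (is.null(best)) return(degenerate_rect(pts))
  if (best$du >= best$dv) {
    long <- best$du; short <- best$dv; axis <- best$u
  } else {
    long <- best$dv; short <- best$du; axis <- best$v
  }
  ang <- (atan2(axis[2], axis[1]) * 180 / pi) %% 180
  list(length = unname(long), width = unname(short), angle_deg = unname(ang),
       center = as.numeric(best$center))
}

# Shoelace area of a simple polygon given as ordered vertices.
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((pts[j, 1] - pts[, 1])^2 + (pts[j, 2] - pts[, 2])^2))
}

# Distance from points (px, py) to segment a-b (vectorised over points).
point_segment_distance <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  ab2 <- abx^2 + aby^2
  if (ab2 < .Machine$double.eps) {
    return(sqrt((px - a[1])^2 + (py - a[2])^2))
  }
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / ab2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * abx; qy <- a[2] + t * aby
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Minimum distance between two segments (used for scene placement).
segment_segment_distance <- function(a1, b1, a2, b2) {
  # if they intersect, distance is zero
  orient <- function(p, q, r) (q[1]-p[1])*(r[2]-p[2]) - (q[2]-p[2])*(r[1]-p[1])
  d1 <- orient(a2, b2, a1); d2 <- orient(a2, b2, b1)
  d3 <- orient(a1, b1, a2); d4 <- orient(a1, b1, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(0)
  min(point_segment_distance(a1[1], a1[2], a2, b2),
      point_segment_distance(b1[1], b1[2], a2, b2),
      point_segment_distance(a2[1], a2[2], a1, b1),
      point_segment_distance(b2[1], b2[2], a1, b1))
}
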