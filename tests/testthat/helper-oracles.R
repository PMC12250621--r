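# Independent oracle implementations used to check the package's
# operations.  These deliberately use brute-force or closed-form
# alternatives to the production code paths.

# direct O(n^2 k^2) correlation with replicate border
oracle_conv2 <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1) / 2; pc <- (kc - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (i in seq_len(kr)) {
        for (j in seq_len(kc)) {
          rr <- min(max(r + i - 1 - pr, 1), nr)
          cc <- min(max(c + j - 1 - pc, 1), nc)
          acc <- acc + kernel[i, j] * m[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# connected-component count by BFS flood fill (8-connectivity)
oracle_cc_count <- function(mask) {
  mask <- mask != 0
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (!mask[r, c] || seen[r, c]) next
      count <- count + 1L
      queue <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1] + dr; c2 <- p[2] + dc
          if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
          if (mask[r2, c2] && !seen[r2, c2]) {
            seen[r2, c2] <- TRUE
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  count
}

# minimum-area rectangle by dense rotation search
oracle_min_rect <- function(pts, step_deg = 0.1) {
  best <- NULL
  for (th in seq(0, 90 - step_deg, by = step_deg)) {
    rad <- th * pi / 180
    u <- c(cos(rad), sin(rad)); v <- c(-sin(rad), cos(rad))
    pu <- pts %*% u; pv <- pts %*% v
    du <- diff(range(pu)); dv <- diff(range(pv))
    if (is.null(best) || du * dv < best$area) {
      best <- list(area = du * dv, length = max(du, dv),
                   width = min(du, dv),
                   angle = if (du >= dv) th else (th + 90) %% 180)
    }
  }
  best
}

# circular mean via the complex resultant
oracle_circular_mean <- function(deg) {
  z <- sum(exp(1i * deg * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

# brute-force distance to the nearest zero pixel
oracle_distance_transform <- function(mask) {
  mask <- mask != 0
  zr <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (!mask[r, c]) next
      out[r, c] <- if (nrow(zr) == 0) 1e10 else
        sqrt(min((zr[, 1] - r)^2 + (zr[, 2] - c)^2))
    }
  }
  out
}

# literal transcription of the two-stage step-up definition
oracle_bky <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh_reject <- function(p, level) {
    o <- order(p); ps <- p[o]
    r <- 0
    for (k in m:1) if (ps[k] <= k * level / m) { r <- k; break }
    rej <- logical(m)
    if (r > 0) rej[o[1:r]] <- TRUE
    rej
  }
  r1 <- sum(bh_reject(p, qp))
  if (r1 == 0) return(logical(m))
  if (r1 == m) return(rep(TRUE, m))
  bh_reject(p, qp * m / (m - r1))
}

# plain Benjamini-Hochberg rejections via p.adjust
oracle_bh <- function(p, q = 0.05) stats::p.adjust(p, "BH") <= q

# optimal assignment within a radius by exhaustive enumeration (<= 6 objects)
oracle_max_matching <- function(truth, det, max_dist) {
  nt <- nrow(truth); nd <- nrow(det)
  if (nt == 0 || nd == 0) return(0)
  # enumerate assignments from the smaller side so nothing is missed
  if (nt > nd) return(oracle_max_matching(det, truth, max_dist))
  d <- sqrt(outer(truth$base_x, det$base_x, "-")^2 +
            outer(truth$base_y, det$base_y, "-")^2)
  ok <- d <= max_dist
  best <- 0
  idx <- seq_len(nd)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(idx)) {
    cnt <- 0
    for (t in seq_len(min(nt, nd))) if (ok[t, p[t]]) cnt <- cnt + 1
    best <- max(best, cnt)
  }
  best
}

# rectangle-outline contour (possibly fractional coordinates), centred at
# (cx, cy), axis-aligned, length along x
rect_contour <- function(len_px, wid_px, cx = 50, cy = 50) {
  xs <- seq(cx - len_px / 2, cx + len_px / 2, length.out = max(2, ceiling(len_px) + 1))
  ys <- seq(cy - wid_px / 2, cy + wid_px / 2, length.out = max(2, ceiling(wid_px) + 1))
  rbind(
    cbind(x = xs, y = min(ys)), cbind(x = xs, y = max(ys)),
    cbind(x = min(xs), y = ys), cbind(x = max(xs), y = ys)
  )
}

# bright axis-aligned bar on dark background
bar_image <- function(nr = 64, nc = 64, r0 = 30, r1 = 33, c0 = 15, c1 = 45,
                      fg = 200, bg = 0, pixel_size_um = 0.5,
                      hemisphere = "right") {
  m <- matrix(bg, nr, nc)
  m[r0:r1, c0:c1] <- fg
  image2d(m, pixel_size_um, hemisphere = hemisphere, channel = "ADCY3")
}

# binary disk mask
disk_mask <- function(nr, nc, cy, cx, r) {
  xs <- matrix(rep(seq_len(nc), each = nr), nr)
  ys <- matrix(rep(seq_len(nr), nc), nr)
  matrix(as.integer((xs - cx)^2 + (ys - cy)^2 <= r^2), nr)
}
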