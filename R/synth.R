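# Synthetic micrographs, time series and connectivity matrices with known
# ground truth.  All generators are pure functions of (parameters, seed).
#
# The default cilia scene emulates ADCY3 staining: bright elongated
# capsules (width ~2-4 px) with a brighter basal-body blob near the base,
# a Gaussian point-spread blur, and additive Gaussian background noise.
# SNR is defined as shaft amplitude over background noise SD.  The
# rendered structure spans exactly the base-to-tip segment: the capsule
# caps are inset by half the width and the basal blob (radius 2 px) is
# centred 1 px inside the base, so the ground-truth length corresponds to
# the visible length of the stained structure.

render_additive <- function(canvas, rows, cols, values) {
  sub <- canvas[rows, cols, drop = FALSE]
  canvas[rows, cols] <- pmax(sub, values)
  canvas
}

#' Generate a synthetic cilia micrograph with ground truth
#'
#' @param n number of cilia.
#' @param shape image dimensions `c(rows, cols)`.
#' @param pixel_size_um calibration (micrometres per pixel).
#' @param length_range_um cilium length range (uniform draw).
#' @param width_range_px shaft width range in pixels (uniform draw, capped
#'   at `length_px / 1.75` so generated structures respect the detector's
#'   aspect filter, as the benchmark intends well-posed targets).
#' @param snr shaft amplitude divided by background noise SD.
#' @param bg_mean,shaft_amplitude background level and shaft amplitude
#'   (8-bit scale); noise SD is `shaft_amplitude / snr`.  The default
#'   background sits well above the noise floor (median ~7.5x noise SD),
#'   as in real tissue autofluorescence -- the median-derived Canny
#'   thresholds presuppose exactly this regime.
#' @param base_gain basal blob brightness relative to the shaft (>= 1.5
#'   keeps brightest-pixel base location well-posed).
#' @param base_radius_px,base_offset_px blob radius and inset of its centre
#'   from the base end, along the axis.
#' @param psf_sigma_px Gaussian point-spread sigma.
#' @param min_sep_px minimum distance between the axial segments of any two
#'   cilia (touching/crossing cilia are out of scope for the detector).
#' @param intensity_jitter per-cilium multiplicative brightness jitter
#'   (uniform in `1 +- intensity_jitter`).
#' @param hemisphere hemisphere label attached to the image.
#' @param seed RNG seed.
#' @return list with `image` ([image2d()]) and `truth` (data.frame: `id,
#'   base_x, base_y, tip_x, tip_y, length_um, width_px, angle_deg`), plus
#'   the generation parameters as attribute `"params"`.  `angle_deg` is the
#'   base-to-tip direction in the y-up counter-clockwise convention.
#' @export
synth_cilia_image <- function(n = 25, shape = c(1024L, 1024L),
                              pixel_size_um = 0.5,
                              length_range_um = c(2, 12),
                              width_range_px = c(2, 4),
                              snr = 5, bg_mean = 60, shaft_amplitude = 40,
                              base_gain = 1.6, base_radius_px = 2,
                              base_offset_px = 1, psf_sigma_px = 0.8,
                              min_sep_px = 20, intensity_jitter = 0.1,
                              hemisphere = "right", seed = 1L) {
  stopifnot(n >= 0, min_sep_px >= 0, snr > 0)
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  max_len_px <- length_range_um[2] / pixel_size_um
  margin <- ceiling(max_len_px + base_radius_px + 6)
  if (n > 0 && (nr <= 2 * margin || nc <= 2 * margin)) {
    stop("image too small for the requested cilium lengths")
  }
  placed <- list()
  attempts <- 0L
  while (length(placed) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(1L, n)) {
      stop("could not place ", n, " cilia at the requested separation")
    }
    len_um <- runif(1, length_range_um[1], length_range_um[2])
    len_px <- len_um / pixel_size_um
    ang <- runif(1, 0, 360)
    w <- runif(1, width_range_px[1], width_range_px[2])
    w <- min(w, len_px / 1.75)
    # benchmark scenes contain cilia within the detector filter bounds: the
    # rendered structure (shaft or basal blob, whichever is wider) must be
    # unambiguously elongated, so that recall measures detection, not
    # filter-boundary effects
    eff_w <- max(w, 2 * base_radius_px + 1)
    if (len_px < 1.75 * eff_w) next
    bx <- runif(1, margin, nc - margin)
    by <- runif(1, margin, nr - margin)
    u <- c(cos(ang * pi / 180), -sin(ang * pi / 180)) # image coords, y down
    tip <- c(bx, by) + len_px * u
    ok <- TRUE
    for (p in placed) {
      d <- segment_segment_distance(c(bx, by), tip, p$base, p$tip)
      if (d < min_sep_px) { ok <- FALSE; break }
    }
    if (!ok) next
    placed[[length(placed) + 1L]] <- list(
      base = c(bx, by), tip = tip, length_um = len_um, angle_deg = ang,
      width_px = w, jitter = runif(1, 1 - intensity_jitter, 1 + intensity_jitter)
    )
  }
  canvas <- matrix(0, nr, nc)
  for (p in placed) {
    u <- (p$tip - p$base) / sqrt(sum((p$tip - p$base)^2))
    hw <- p$width_px / 2
    a <- p$base + hw * u            # capsule caps inset: extent = base..tip
    b <- p$tip - hw * u
    blob_c <- p$base + base_offset_px * u
    r0 <- max(1L, floor(min(p$base[2], p$tip[2]) - hw - base_radius_px - 2))
    r1 <- min(nr, ceiling(max(p$base[2], p$tip[2]) + hw + base_radius_px + 2))
    c0 <- max(1L, floor(min(p$base[1], p$tip[1]) - hw - base_radius_px - 2))
    c1 <- min(nc, ceiling(max(p$base[1], p$tip[1]) + hw + base_radius_px + 2))
    rows <- r0:r1; cols <- c0:c1
    gx <- matrix(rep(cols, each = length(rows)), length(rows))
    gy <- matrix(rep(rows, times = length(cols)), length(rows))
    d_shaft <- point_segment_distance(gx, gy, a, b)
    cov_shaft <- pmin(1, pmax(0, hw - d_shaft + 0.5))
    d_blob <- sqrt((gx - blob_c[1])^2 + (gy - blob_c[2])^2)
    cov_blob <- pmin(1, pmax(0, base_radius_px - d_blob + 0.5))
    amp <- shaft_amplitude * p$jitter
    vals <- pmax(amp * cov_shaft, amp * base_gain * cov_blob)
    canvas <- render_additive(canvas, rows, cols, matrix(vals, length(rows)))
  }
  if (any(canvas > 0)) {
    ks <- 2L * ceiling(2 * psf_sigma_px) + 1L
    canvas <- gaussian_blur_matrix(canvas, ks, psf_sigma_px, round = FALSE)
  }
  noise_sd <- shaft_amplitude / snr
  img <- bg_mean + canvas + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  img <- matrix(round(pmin(255, pmax(img, 0))), nr, nc)
  truth <- if (length(placed)) data.frame(
    id = seq_along(placed),
    base_x = vapply(placed, function(p) p$base[1], numeric(1)),
    base_y = vapply(placed, function(p) p$base[2], numeric(1)),
    tip_x = vapply(placed, function(p) p$tip[1], numeric(1)),
    tip_y = vapply(placed, function(p) p$tip[2], numeric(1)),
    length_um = vapply(placed, function(p) p$length_um, numeric(1)),
    width_px = vapply(placed, function(p) p$width_px, numeric(1)),
    angle_deg = vapply(placed, function(p) p$angle_deg, numeric(1))
  ) else data.frame(
    id = integer(0), base_x = numeric(0), base_y = numeric(0),
    tip_x = numeric(0), tip_y = numeric(0), length_um = numeric(0),
    width_px = numeric(0), angle_deg = numeric(0)
  )
  out <- list(
    image = image2d(img, pixel_size_um, hemisphere = hemisphere,
                    channel = "ADCY3", bit_depth = 8L),
    truth = truth
  )
  attr(out, "params") <- list(n = n, shape = shape,
                              pixel_size_um = pixel_size_um,
                              snr = snr, min_sep_px = min_sep_px, seed = seed)
  out
}

#' Generate a synthetic DAPI nuclei image with ground truth
#'
#' Non-overlapping anti-aliased disks with a gentle radial intensity
#' falloff on a dim noisy background.
#'
#' @param n number of nuclei.
#' @param shape image dimensions `c(rows, cols)`.
#' @param radius_range_px disk radius range (uniform draw).
#' @param min_sep_px minimum centre-to-centre separation; the default
#'   (40 px) exceeds both twice the maximal radius and the detector's
#'   30 px centroid-clustering radius, so distinct nuclei are never merged.
#' @param bg_mean,bg_sd background level and noise SD (8-bit scale).
#' @param intensity_range peak disk amplitude above background (uniform).
#' @param psf_sigma_px Gaussian point-spread sigma.
#' @param pixel_size_um calibration attached to the image.
#' @param seed RNG seed.
#' @return list with `image` ([image2d()], DAPI channel) and `truth`
#'   (data.frame: `id, center_x, center_y, radius_px`).
#' @export
synth_nuclei_image <- function(n = 50, shape = c(1024L, 1024L),
                               radius_range_px = c(4, 10), min_sep_px = 40,
                               bg_mean = 12, bg_sd = 2,
                               intensity_range = c(100, 180),
                               psf_sigma_px = 1, pixel_size_um = 0.5,
                               seed = 1L) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  margin <- ceiling(radius_range_px[2] + 5)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(1L, n)) {
      stop("could not place ", n, " nuclei at the requested separation")
    }
    cx <- runif(1, margin, nc - margin)
    cy <- runif(1, margin, nr - margin)
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (min(d) < min_sep_px) next
    }
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, runif(1, radius_range_px[1], radius_range_px[2]))
  }
  canvas <- matrix(0, nr, nc)
  amps <- runif(max(n, 0), intensity_range[1], intensity_range[2])
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    r0 <- max(1L, floor(centers[i, 2] - r - 2))
    r1 <- min(nr, ceiling(centers[i, 2] + r + 2))
    c0 <- max(1L, floor(centers[i, 1] - r - 2))
    c1 <- min(nc, ceiling(centers[i, 1] + r + 2))
    rows <- r0:r1; cols <- c0:c1
    gx <- matrix(rep(cols, each = length(rows)), length(rows))
    gy <- matrix(rep(rows, times = length(cols)), length(rows))
    d <- sqrt((gx - centers[i, 1])^2 + (gy - centers[i, 2])^2)
    cov <- pmin(1, pmax(0, r - d + 0.5))
    falloff <- 1 - 0.25 * pmin(1, (d / r)^2)
    vals <- amps[i] * cov * falloff
    canvas <- render_additive(canvas, rows, cols, matrix(vals, length(rows)))
  }
  if (any(canvas > 0)) {
    ks <- 2L * ceiling(2 * psf_sigma_px) + 1L
    canvas <- gaussian_blur_matrix(canvas, ks, psf_sigma_px, round = FALSE)
  }
  img <- bg_mean + canvas + matrix(rnorm(nr * nc, 0, bg_sd), nr, nc)
  img <- matrix(round(pmin(255, pmax(img, 0))), nr, nc)
  truth <- data.frame(id = seq_len(nrow(centers)),
                      center_x = centers[, 1], center_y = centers[, 2],
                      radius_px = radii)
  list(image = image2d(img, pixel_size_um, hemisphere = "right",
                       channel = "DAPI", bit_depth = 8L),
       truth = truth)
}

#' Generate synthetic section-level rhythm time series
#'
#' Per region and zeitgeber time, section values follow
#' `mesor + amplitude * cos(2 pi (t - phase) / 24) + N(0, noise_sd)`.
#' Defaults emulate the structure of a diurnal sampling design: 12 ZT
#' points 2 h apart and 12 sections per ZT (4 animals x 3 sections).
#'
#' @param rhythm_params data.frame with columns `region_label, mesor,
#'   amplitude, phase, noise_sd` (one row per region).
#' @param zt_grid time points in hours.
#' @param sections_per_zt sections per region and time point.
#' @param seed RNG seed.
#' @return data.frame `region_label, zt, section_id, value` with the truth
#'   parameters attached as attribute `"truth"`.
#' @export
synth_timeseries <- function(rhythm_params,
                             zt_grid = seq(0, 22, by = 2),
                             sections_per_zt = 12L, seed = 1L) {
  rp <- as.data.frame(rhythm_params)
  stopifnot(all(c("region_label", "mesor", "amplitude", "phase",
                  "noise_sd") %in% names(rp)))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(rp))) {
    for (t in zt_grid) {
      mu <- rp$mesor[i] + rp$amplitude[i] * cos(2 * pi * (t - rp$phase[i]) / 24)
      vals <- mu + rnorm(sections_per_zt, 0, rp$noise_sd[i])
      rows[[length(rows) + 1L]] <- data.frame(
        region_label = rp$region_label[i], zt = t,
        section_id = sprintf("%s_ZT%02d_s%02d", rp$region_label[i], t,
                             seq_len(sections_per_zt)),
        value = vals, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- rp
  out
}

#' Generate a planted-partition connectivity matrix with correlation flags
#'
#' Region-pair weights are `w_in` within a community and `w_out` between
#' communities, with multiplicative log-normal noise.  Optionally, pair
#' significance flags are planted with a base rate and an enriched rate for
#' chosen community pairs.
#'
#' @param communities named vector of community labels (names = regions).
#' @param w_in,w_out within/between weights (`w_in > w_out >= 0`).
#' @param noise_sd SD of the log-normal multiplicative noise.
#' @param sig_base base probability that a region pair is flagged
#'   significant; `NULL` skips flag generation.
#' @param sig_enrich optional list of `list(pair = c(c1, c2), rate = r)`
#'   entries overriding the base rate for specific community pairs.
#' @param seed RNG seed.
#' @return list with `W` (symmetric weight matrix), `communities`, and
#'   `sig` (symmetric logical matrix or `NULL`).
#' @export
synth_connectivity <- function(communities, w_in = 1, w_out = 0.05,
                               noise_sd = 0.1, sig_base = NULL,
                               sig_enrich = NULL, seed = 1L) {
  stopifnot(w_in > w_out, w_out >= 0)
  set.seed(seed)
  regs <- names(communities)
  nR <- length(regs)
  W <- matrix(0, nR, nR, dimnames = list(regs, regs))
  sig <- if (!is.null(sig_base)) {
    matrix(FALSE, nR, nR, dimnames = list(regs, regs))
  } else NULL
  rate_for <- function(ci, cj) {
    r <- sig_base
    if (!is.null(sig_enrich)) {
      for (e in sig_enrich) {
        if ((ci == e$pair[1] && cj == e$pair[2]) ||
            (ci == e$pair[2] && cj == e$pair[1])) r <- e$rate
      }
    }
    r
  }
  for (i in seq_len(max(0, nR - 1))) {
    for (j in (i + 1):nR) {
      base <- if (communities[i] == communities[j]) w_in else w_out
      w <- base * exp(rnorm(1, 0, noise_sd))
      if (base == 0) w <- 0
      W[i, j] <- W[j, i] <- w
      if (!is.null(sig)) {
        s <- runif(1) < rate_for(communities[i], communities[j])
        sig[i, j] <- sig[j, i] <- s
      }
    }
  }
  list(W = W, communities = communities, sig = sig)
}

#' Default synthetic detection benchmark ("bench-v1")
#'
#' 20 images of 1024 x 1024 px at 0.5 micrometres per pixel, ~25
#' well-separated cilia each (lengths 2-12 um, widths 2-4 px, SNR ~5,
#' minimum segment separation 20 px), seed 42.  Image `i` uses seed
#' `seed + i` so scenes are independent and the whole benchmark is
#' reproducible from one seed.
#'
#' @param n_images number of images.
#' @param seed benchmark seed.
#' @param ... overrides passed to [synth_cilia_image()].
#' @return list of scenes (each a list with `image` and `truth`).
#' @export
bench_v1 <- function(n_images = 20L, seed = 42L, ...) {
  lapply(seq_len(n_images), function(i) {
    synth_cilia_image(seed = seed + i, ...)
  })
}
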