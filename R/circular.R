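# Circular statistics for orientation data in degrees on [0, 360).

#' Circular (angular) mean
#'
#' Angles are transformed to sines and cosines, averaged, and the mean
#' direction recovered with `atan2(mean_sin, mean_cos)`; negative results
#' are wrapped into [0, 360) by adding 360.  The mean is undefined when the
#' resultant vector is (numerically) zero, e.g. for perfectly antipodal
#' sets, in which case an error is thrown.
#'
#' @param angles_deg numeric vector of angles in degrees, each in [0, 360).
#' @param eps resultant-length tolerance below which the mean is declared
#'   undefined.
#' @return mean direction in degrees, in [0, 360).
#' @export
circular_mean <- function(angles_deg, eps = 1e-12) {
  if (length(angles_deg) == 0L) stop("circular mean of an empty set")
  if (anyNA(angles_deg)) stop("angles contain NA")
  if (any(angles_deg < 0 | angles_deg >= 360)) {
    stop("angles must lie in [0, 360)")
  }
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < eps) {
    stop("circular mean undefined: resultant vector length below tolerance")
  }
  deg <- atan2(s, c) * 180 / pi
  if (deg < 0) deg <- deg + 360
  # a tiny negative mean direction can round up to exactly 360
  deg %% 360
}

#' Wrapped angular difference
#'
#' Shortest arc between two directions: `min(|a - b|, 360 - |a - b|)`,
#' always in [0, 180].
#'
#' @param a_deg,b_deg angles in degrees (vectorised).
#' @return absolute wrapped difference in degrees.
#' @export
circular_diff <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 360
  pmin(d, 360 - d)
}

#' Orientation histogram (rose plot counts)
#'
#' Counts per fixed-width angular bin `[0, w), [w, 2w), ...`; `360` must be
#' divisible by the bin width.
#'
#' @param angles_deg angles in degrees in [0, 360).
#' @param bin_deg bin width in degrees (divisor of 360).
#' @return named integer vector of counts, one per bin, summing to
#'   `length(angles_deg)`.
#' @export
rose_histogram <- function(angles_deg, bin_deg = 30) {
  if (360 %% bin_deg != 0) stop("bin_deg must divide 360")
  if (length(angles_deg) &&
      any(angles_deg < 0 | angles_deg >= 360, na.rm = TRUE)) {
    stop("angles must lie in [0, 360)")
  }
  nb <- 360 %/% bin_deg
  idx <- floor(angles_deg / bin_deg) + 1L
  counts <- tabulate(idx, nbins = nb)
  names(counts) <- sprintf("[%d,%d)", bin_deg * (seq_len(nb) - 1L),
                           bin_deg * seq_len(nb))
  counts
}
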