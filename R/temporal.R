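# Time-of-day statistics on section-level summaries: one-way ANOVA across
# zeitgeber times, two-stage Benjamini-Krieger-Yekutieli FDR control,
# region-pair Pearson correlation matrices, and a fixed-period cosinor fit
# used as a transparent stand-in for external rhythm-detection tools.

#' One-way ANOVA for a time-of-day effect
#'
#' Classical one-way ANOVA of section summaries grouped by zeitgeber time.
#' Angles are treated as linear quantities of the section circular means
#' (the circular-statistics caveat is documented, not corrected).
#'
#' @param values numeric vector of section-level summaries.
#' @param zt grouping variable (zeitgeber time of each section).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_time_effect <- function(values, zt) {
  g <- factor(zt)
  if (nlevels(g) < 2L) stop("need at least 2 ZT groups")
  if (length(values) != length(g)) stop("values and zt lengths differ")
  if (stats::var(values) == 0) {
    # all values identical: no effect by definition (avoids 0/0 noise)
    return(list(F = 0, p = 1, df_between = nlevels(g) - 1L,
                df_within = length(values) - nlevels(g)))
  }
  fit <- stats::lm(values ~ g)
  tab <- stats::anova(fit)
  Fv <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.nan(Fv) || is.na(Fv)) { Fv <- 0; p <- 1 }
  list(F = Fv, p = p, df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Two-stage linear step-up FDR procedure (Benjamini, Krieger & Yekutieli)
#'
#' Stage 1 applies the linear step-up (BH) procedure at level
#' `q' = q / (1 + q)` and counts rejections `r1` to estimate the number of
#' true nulls `m0 = m - r1`.  If `r1 = 0` nothing is rejected; if `r1 = m`
#' everything is.  Otherwise stage 2 applies the linear step-up procedure
#' at level `q' * m / m0`.  Rejections are monotone in the p-values.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param alpha target FDR level `q` (default 0.05).
#' @return list with logical `reject`, `r1` (stage-1 rejections), `m0`
#'   (estimated true nulls) and `stage2_level`.
#' @export
fdr_bky <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(list(reject = logical(0), r1 = 0L, m0 = 0L,
                           stage2_level = NA_real_))
  step_up <- function(p, q) {
    # largest k with p_(k) <= k*q/m; reject the k smallest
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    r <- if (length(k)) max(k) else 0L
    rej <- logical(m)
    if (r > 0L) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  q1 <- alpha / (1 + alpha)
  rej1 <- step_up(p, q1)
  r1 <- sum(rej1)
  if (r1 == 0L) {
    return(list(reject = logical(m), r1 = 0L, m0 = m, stage2_level = q1))
  }
  if (r1 == m) {
    return(list(reject = rep(TRUE, m), r1 = r1, m0 = 0L, stage2_level = NA_real_))
  }
  m0 <- m - r1
  q2 <- q1 * m / m0
  list(reject = step_up(p, q2), r1 = r1, m0 = m0, stage2_level = q2)
}

#' Pearson correlation matrices between regional time profiles
#'
#' Each region's profile is its per-ZT mean of section summaries on a
#' shared ZT grid; Pearson r and two-sided p-values are computed for every
#' region pair.  Zero-variance profiles yield `NA` with a warning.
#'
#' @param sections data.frame with columns `region_label`, `zt` and a value
#'   column.
#' @param value name of the value column (e.g. `"mean_length_um"`).
#' @return list of symmetric matrices `r` (unit diagonal) and `p`.
#' @export
region_pair_correlations <- function(sections, value = "mean_length_um") {
  df <- as.data.frame(sections)
  stopifnot(all(c("region_label", "zt", value) %in% names(df)))
  regions <- sort(unique(df$region_label))
  zts <- sort(unique(df$zt))
  prof <- sapply(regions, function(rg) {
    sub <- df[df$region_label == rg, ]
    vapply(zts, function(t) mean(sub[[value]][sub$zt == t]), numeric(1))
  })
  prof <- as.matrix(prof)
  nR <- length(regions)
  r <- matrix(NA_real_, nR, nR, dimnames = list(regions, regions))
  pm <- r
  diag(r) <- 1; diag(pm) <- 0
  nz <- apply(prof, 2, stats::sd)
  if (any(is.na(nz) | nz == 0)) warning("zero-variance profile; correlations NA")
  n <- length(zts)
  for (i in seq_len(nR - 1L)) {
    for (j in (i + 1L):nR) {
      if (nz[i] == 0 || nz[j] == 0 || anyNA(prof[, i]) || anyNA(prof[, j])) next
      rij <- stats::cor(prof[, i], prof[, j])
      r[i, j] <- r[j, i] <- rij
      tstat <- rij * sqrt((n - 2) / max(1e-300, 1 - rij^2))
      pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(r = r, p = pm, profiles = prof, zt = zts)
}

#' Fixed-period cosinor fit
#'
#' Least-squares fit of `y = M + A cos(2 pi (t - phi) / period)` via the
#' linear harmonic regression `y ~ cos + sin`; the p-value is the F-test of
#' the two harmonic terms against the intercept-only model.  This is a
#' deliberately simple, transparent stand-in for external deep-learning
#' rhythm classifiers: it fits period-24 sinusoids only.
#'
#' @param t time points (hours).
#' @param y observations.
#' @param period fixed period in hours (default 24).
#' @return list with `mesor`, `amplitude` (>= 0), `phase` (acrophase in
#'   [0, period)), `p`, and the fitted `lm` object.
#' @export
cosinor_fit <- function(t, y, period = 24) {
  if (length(unique(t)) < 3L) stop("need at least 3 distinct time points")
  w <- 2 * pi / period
  cc <- cos(w * t); ss <- sin(w * t)
  fit <- stats::lm(y ~ cc + ss)
  b <- stats::coef(fit)
  amp <- sqrt(b[["cc"]]^2 + b[["ss"]]^2)
  phase <- (atan2(b[["ss"]], b[["cc"]]) / w) %% period
  if (stats::var(y) == 0) {
    p <- 1 # constant series carries no rhythm evidence
  } else {
    null <- stats::lm(y ~ 1)
    a <- stats::anova(null, fit)
    p <- a$`Pr(>F)`[2]
    if (is.na(p)) p <- 1
  }
  list(mesor = unname(b[["(Intercept)"]]), amplitude = unname(amp),
       phase = unname(phase), period = period, p = p, fit = fit)
}
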