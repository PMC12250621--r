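# Density, section-level aggregation, the two region-averaging schemes and
# length/angle frequency distributions.  The brain section is the unit of
# all downstream statistics: each section contributes one mean length and
# one circular-mean angle.

#' Cilia density
#'
#' Percentage of stained cilia relative to the number of DAPI-stained cells
#' in the same region: `100 * n_cilia / n_cells`.  Scale-free: multiplying
#' both counts by a constant leaves the density unchanged.
#'
#' @param n_cilia,n_cells non-negative counts; `n_cells` must be positive.
#' @return density in percent.
#' @export
cilia_density <- function(n_cilia, n_cells) {
  if (any(n_cells <= 0)) stop("n_cells must be positive")
  if (any(n_cilia < 0)) stop("counts must be non-negative")
  100 * n_cilia / n_cells
}

#' Summarise one brain section
#'
#' Arithmetic mean of cilium lengths and circular mean of cilium angles for
#' all records of a single section.
#'
#' @param records data.frame of cilium records (single section).
#' @return one-row data.frame: `section_id, region_label, hemisphere, zt,
#'   n_cilia, mean_length_um, circ_mean_angle_deg`.
#' @export
summarize_section <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty section")
  sid <- unique(records$section_id)
  if (length(sid) > 1L) stop("records span multiple sections")
  data.frame(
    section_id = sid,
    region_label = records$region_label[1],
    hemisphere = records$hemisphere[1],
    zt = records$zt[1],
    n_cilia = nrow(records),
    mean_length_um = mean(records$length_um),
    circ_mean_angle_deg = circular_mean(records$angle_deg),
    stringsAsFactors = FALSE
  )
}

#' Summarise all sections in a record table
#'
#' @param records data.frame of cilium records with a `section_id` column.
#' @return data.frame with one row per section (see [summarize_section()]).
#' @export
summarize_sections <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records")
  parts <- split(records, records$section_id)
  out <- do.call(rbind, lapply(parts, summarize_section))
  rownames(out) <- NULL
  out
}

#' Regional average by the direct or section-based scheme
#'
#' `direct`: unweighted mean over all individual cilia (every cilium counts
#' once).  `section_based`: each section's mean is treated as a single
#' observation; the regional mean and SEM are computed over sections.  The
#' two methods agree exactly when all sections contain the same number of
#' cilia.
#'
#' @param records data.frame of cilium records (one region).
#' @param method `"direct"` or `"section_based"`.
#' @param measure `"length"` (uses `length_um`, arithmetic means) or
#'   `"angle"` (uses `angle_deg`, circular means; SEM is computed on the
#'   section means treated linearly, matching common practice for these
#'   data).
#' @return list with `mean`, `sem` and `n` (number of cilia or sections).
#' @export
region_average <- function(records, method = c("direct", "section_based"),
                           measure = c("length", "angle")) {
  method <- match.arg(method)
  measure <- match.arg(measure)
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("empty input")
  if (method == "direct") {
    vals <- if (measure == "length") records$length_um else records$angle_deg
    m <- if (measure == "length") mean(vals) else circular_mean(vals)
    s <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
    return(list(mean = m, sem = s, n = length(vals)))
  }
  sect <- summarize_sections(records)
  vals <- if (measure == "length") sect$mean_length_um else sect$circ_mean_angle_deg
  m <- if (measure == "length") mean(vals) else circular_mean(vals)
  s <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
  list(mean = m, sem = s, n = nrow(sect))
}

#' Length frequency distribution
#'
#' Percent frequency per fixed-width bin anchored at `origin` (default bins
#' `[0, 0.6), [0.6, 1.2), ...`, chosen so that one bin spans the
#' 4.8-5.4 um range).  Frequencies sum to 100 over the occupied range.
#'
#' @param lengths_um numeric vector of lengths.
#' @param bin_width_um bin width (micrometres).
#' @param origin left edge of the first bin.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `percent`.
#' @export
length_histogram <- function(lengths_um, bin_width_um = 0.6, origin = 0) {
  stopifnot(bin_width_um > 0)
  if (length(lengths_um) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0), percent = numeric(0)))
  }
  idx <- floor((lengths_um - origin) / bin_width_um)
  rng <- range(idx)
  bins <- rng[1]:rng[2]
  counts <- tabulate(idx - rng[1] + 1L, nbins = length(bins))
  data.frame(
    bin_lo = origin + bins * bin_width_um,
    bin_hi = origin + (bins + 1) * bin_width_um,
    count = counts,
    percent = 100 * counts / sum(counts)
  )
}
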