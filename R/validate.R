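# Scoring of detections against ground truth: greedy base-position
# matching, recall + mean-absolute-error report, the 2D-projection error
# estimate, and the full synthetic benchmark runner.

#' Match detections to ground truth by base position
#'
#' Greedy nearest-neighbour matching: candidate (truth, detection) pairs
#' within `max_dist_px` are sorted by distance (ties broken by truth then
#' detection index) and accepted while both members are unused.  Each truth
#' and each detection is used at most once.
#'
#' @param detected data.frame with `base_x`, `base_y`.
#' @param truth data.frame with `base_x`, `base_y`.
#' @param max_dist_px maximum matching radius in pixels.
#' @return data.frame with `truth_idx`, `det_idx`, `dist_px`.
#' @export
match_detections <- function(detected, truth, max_dist_px = 5) {
  nd <- nrow(detected); nt <- nrow(truth)
  empty <- data.frame(truth_idx = integer(0), det_idx = integer(0),
                      dist_px = numeric(0))
  if (nd == 0L || nt == 0L) return(empty)
  dmat <- outer(truth$base_x, detected$base_x, "-")^2 +
          outer(truth$base_y, detected$base_y, "-")^2
  dmat <- sqrt(dmat)
  cand <- which(dmat <= max_dist_px, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  dd <- dmat[cand]
  o <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]; dd <- dd[o]
  used_t <- logical(nt); used_d <- logical(nd)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ti <- cand[k, 1]; di <- cand[k, 2]
    if (!used_t[ti] && !used_d[di]) {
      keep[k] <- TRUE; used_t[ti] <- TRUE; used_d[di] <- TRUE
    }
  }
  data.frame(truth_idx = cand[keep, 1], det_idx = cand[keep, 2],
             dist_px = dd[keep])
}

#' Score matched detections
#'
#' Recall (`matched / |truth|`), mean absolute length error (micrometres)
#' and mean absolute angular error (wrapped circular difference, degrees)
#' over the matched pairs.
#'
#' @param matched output of [match_detections()].
#' @param detected,truth the tables passed to [match_detections()]; both
#'   need `length_um` and `angle_deg` columns for the MAE components.
#' @return list of class `validation_report`: `n_truth, n_detected,
#'   n_matched, recall, mae_length_um, mae_angle_deg, mean_match_dist_px`.
#' @export
score_detections <- function(matched, detected, truth) {
  if (nrow(truth) == 0L) stop("empty truth")
  nm <- nrow(matched)
  mae_len <- mae_ang <- NA_real_
  if (nm > 0L) {
    mae_len <- mean(abs(detected$length_um[matched$det_idx] -
                        truth$length_um[matched$truth_idx]))
    mae_ang <- mean(circular_diff(detected$angle_deg[matched$det_idx],
                                  truth$angle_deg[matched$truth_idx]))
  }
  structure(list(
    n_truth = nrow(truth), n_detected = nrow(detected), n_matched = nm,
    recall = nm / nrow(truth), mae_length_um = mae_len,
    mae_angle_deg = mae_ang,
    mean_match_dist_px = if (nm) mean(matched$dist_px) else NA_real_
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation: %d/%d matched (recall %.2f%%), MAE length %.3f um, MAE angle %.3f deg\n",
    x$n_matched, x$n_truth, 100 * x$recall, x$mae_length_um, x$mae_angle_deg))
  invisible(x)
}

#' 2D projection length of a tilted 3D structure
#'
#' A structure of true length L spanning an axial (depth) extent dz appears
#' in a 2D projection with length `sqrt(L^2 - dz^2)` (Pythagorean theorem);
#' the projection never exceeds the true length.
#'
#' @param true_length_um true 3D length.
#' @param depth_extent_um axial extent (0 <= dz <= L).
#' @return projected length in micrometres.
#' @export
projection_error <- function(true_length_um, depth_extent_um) {
  if (any(depth_extent_um < 0)) stop("depth extent must be non-negative")
  if (any(depth_extent_um > true_length_um)) {
    stop("depth extent cannot exceed the true length")
  }
  sqrt(true_length_um^2 - depth_extent_um^2)
}

#' Run the full detection pipeline on a synthetic benchmark
#'
#' Generates (or accepts) a list of synthetic scenes, runs [detect_cilia()]
#' with the given parameters on each image, matches detections to ground
#' truth by base position and pools the matches into one validation report.
#'
#' @param scenes list of scenes from [bench_v1()] / [synth_cilia_image()];
#'   if `NULL`, `bench_v1(seed = seed)` is generated.
#' @param params [detection_params()].
#' @param max_dist_px matching radius.
#' @param seed benchmark seed used when `scenes` is `NULL`.
#' @return `validation_report` (see [score_detections()]) with per-image
#'   reports attached as attribute `"per_image"`.
#' @export
benchmark_cilia_detection <- function(scenes = NULL,
                                      params = detection_params(),
                                      max_dist_px = 5, seed = 42L) {
  if (is.null(scenes)) scenes <- bench_v1(seed = seed)
  tot_truth <- 0L; tot_det <- 0L; tot_match <- 0L
  abs_len <- numeric(0); ang_err <- numeric(0); dists <- numeric(0)
  per_image <- list()
  for (sc in scenes) {
    det <- detect_cilia(sc$image, params)
    m <- match_detections(det, sc$truth, max_dist_px)
    rep_i <- score_detections(m, det, sc$truth)
    per_image[[length(per_image) + 1L]] <- rep_i
    tot_truth <- tot_truth + nrow(sc$truth)
    tot_det <- tot_det + nrow(det)
    tot_match <- tot_match + nrow(m)
    if (nrow(m)) {
      abs_len <- c(abs_len, abs(det$length_um[m$det_idx] -
                                sc$truth$length_um[m$truth_idx]))
      ang_err <- c(ang_err, circular_diff(det$angle_deg[m$det_idx],
                                          sc$truth$angle_deg[m$truth_idx]))
      dists <- c(dists, m$dist_px)
    }
  }
  out <- structure(list(
    n_truth = tot_truth, n_detected = tot_det, n_matched = tot_match,
    recall = tot_match / tot_truth,
    mae_length_um = if (length(abs_len)) mean(abs_len) else NA_real_,
    mae_angle_deg = if (length(ang_err)) mean(ang_err) else NA_real_,
    mean_match_dist_px = if (length(dists)) mean(dists) else NA_real_
  ), class = "validation_report")
  attr(out, "per_image") <- per_image
  out
}
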