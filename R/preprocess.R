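# Preprocessing: direction-averaged, normalized shell signals and the
# voxel-stability quality filter applied to each serial session.

#' Direction-averaged, normalized shell signals
#'
#' For one scan: `s0` is the arithmetic mean over the b ~ 0 volumes; `s_lb`
#' (resp. `s_hb`) is the arithmetic mean of the direction volumes at the key
#' shell divided by `s0`. Voxels whose `s0` does not exceed `noise_floor`
#' (or whose shell means are non-positive) are masked out rather than
#' producing errors. The output is invariant under global intensity
#' rescaling of the scan.
#'
#' @param scan a [dwi_series()].
#' @param noise_floor absolute `s0` floor below which a voxel is masked.
#' @return object of class `shell_signal_maps` with fields `s_lb`, `s_hb`,
#'   `s0` (3-D arrays), `mask` (logical array) and `grid`.
#' @export
normalize_and_average <- function(scan, noise_floor = 1e-12) {
  if (!inherits(scan, "dwi_series")) stop_validation("'scan' must be a dwi_series")
  sch <- scan$scheme
  g <- scan$grid
  m <- matrix(scan$intensities, prod(g), sch$n_volumes)
  s0 <- rowMeans(m[, sch$b0_volumes, drop = FALSE])
  lb <- rowMeans(m[, sch$lb_volumes, drop = FALSE])
  hb <- rowMeans(m[, sch$hb_volumes, drop = FALSE])
  mask <- is.finite(s0) & s0 > noise_floor & lb > 0 & hb > 0
  if (!any(mask))
    warning("normalize_and_average: all voxels masked (s0 at or below noise floor)")
  s_lb <- ifelse(mask, lb / s0, NA_real_)
  s_hb <- ifelse(mask, hb / s0, NA_real_)
  structure(list(
    s_lb = array(s_lb, g), s_hb = array(s_hb, g),
    s0 = array(s0, g), mask = array(mask, g), grid = g,
    scan_index = scan$scan_index, subject_id = scan$subject_id,
    acquisition_time = scan$acquisition_time,
    lb = sch$key_low_b, hb = sch$key_high_b
  ), class = "shell_signal_maps")
}

#' Flag temporally unstable voxels in a session
#'
#' For each shell (b0, Lb, Hb), each scan's shell map is Gaussian-smoothed
#' spatially, then the temporal coefficient of variation (sd / mean, %) is
#' computed across the session. A voxel is flagged when its CV strictly
#' exceeds `threshold_pct` in at least one shell. Voxels with a zero or
#' undefined temporal mean are flagged as degenerate.
#'
#' @param session list of [normalize_and_average()] outputs (>= 3 scans, one
#'   subject, identical grids).
#' @param threshold_pct CV threshold in percent (default 4).
#' @param smoothing_fwhm_vox FWHM of the spatial Gaussian pre-filter, voxels
#'   (default 2; 0 disables smoothing).
#' @return object of class `stability_report`: `flagged` (logical array),
#'   `cv` (list of per-shell CV arrays, %), `threshold_pct`, `n_scans`,
#'   `n_degenerate`.
#' @export
flag_unstable_voxels <- function(session, threshold_pct = 4, smoothing_fwhm_vox = 2) {
  if (!is.list(session) || length(session) < 3L)
    stop_validation("'session' must be a list of at least 3 shell_signal_maps")
  if (!all(vapply(session, inherits, TRUE, "shell_signal_maps")))
    stop_validation("'session' elements must be shell_signal_maps")
  assert_scalar_number(threshold_pct, "threshold_pct", positive = TRUE)
  g <- session[[1]]$grid
  if (!all(vapply(session, function(s) identical(s$grid, g), TRUE)))
    stop_validation("all scans in a session must share one grid")

  cv <- list()
  for (shell in c("s0", "s_lb", "s_hb")) {
    stacked <- vapply(session, function(s) {
      as.vector(gaussian_smooth_3d(s[[shell]], smoothing_fwhm_vox))
    }, numeric(prod(g)))
    mu <- rowMeans(stacked)
    sdv <- sqrt(rowSums((stacked - mu)^2) / (ncol(stacked) - 1))
    v <- 100 * sdv / mu
    v[!is.finite(mu) | mu == 0] <- Inf  # degenerate: flag
    cv[[shell]] <- array(v, g)
  }
  flagged <- array(FALSE, g)
  for (shell in names(cv)) {
    v <- cv[[shell]]
    v[is.na(v)] <- Inf
    flagged <- flagged | v > threshold_pct
  }
  structure(list(flagged = flagged, cv = cv,
                 threshold_pct = threshold_pct,
                 smoothing_fwhm_vox = smoothing_fwhm_vox,
                 n_scans = length(session),
                 n_degenerate = sum(!is.finite(cv$s0) | !is.finite(cv$s_lb) |
                                      !is.finite(cv$s_hb)),
                 subject_id = session[[1]]$subject_id),
            class = "stability_report")
}

#' Discard sessions with flagged voxels inside analysis ROIs
#'
#' Subjects whose session contains at least one flagged voxel inside any of
#' the analysis ROIs are removed from the manifest. The temporal-stability
#' statistic is a session-level quantity, so the discard unit is the whole
#' subject session. Removals are logged in the `"discard_log"` attribute.
#'
#' @param reports named list of [flag_unstable_voxels()] reports, one per
#'   subject (names are subject ids). Subjects absent from `reports` are
#'   kept.
#' @param labels a [label_volume()] on the same grid.
#' @param manifest a [study_manifest()].
#' @param rois ROI names checked (default: all dictionary entries).
#' @return the filtered `study_manifest` with a `discard_log` attribute
#'   (data frame: subject_id, roi, n_flagged).
#' @export
apply_discard_rule <- function(reports, labels, manifest,
                               rois = names(labels$dictionary)) {
  if (!inherits(labels, "label_volume")) stop_validation("'labels' must be a label_volume")
  masks <- lapply(rois, function(r) roi_mask(labels, r))
  names(masks) <- rois
  log <- data.frame(subject_id = character(0), roi = character(0),
                    n_flagged = integer(0), stringsAsFactors = FALSE)
  drop <- character(0)
  for (s in intersect(unique(manifest$subject_id), names(reports))) {
    rep <- reports[[s]]
    if (!identical(dim(rep$flagged), labels$grid))
      stop_validation("stability report and label volume are on different grids")
    for (r in rois) {
      n <- sum(rep$flagged & masks[[r]])
      if (n > 0) {
        log <- rbind(log, data.frame(subject_id = s, roi = r, n_flagged = n,
                                     stringsAsFactors = FALSE))
      }
    }
    if (s %in% log$subject_id) drop <- c(drop, s)
  }
  out <- manifest[!(manifest$subject_id %in% drop), , drop = FALSE]
  if (nrow(out) == 0L && nrow(manifest) > 0L)
    warning("apply_discard_rule: all subjects discarded")
  class(out) <- class(manifest)
  attr(out, "discard_log") <- log
  out
}
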