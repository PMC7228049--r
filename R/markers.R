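# The two microstructure markers: shifted ADC (sADC) and signature index
# (Sindex), computed voxelwise and at ROI level from normalized two-shell
# signals.

#' Shifted apparent diffusion coefficient (sADC)
#'
#' \deqn{sADC = \ln(S_{Lb} / S_{Hb}) / (Hb - Lb)}
#' computed from the direction-averaged, normalized signals at the two key
#' shells. Using two non-zero b-values captures Gaussian and non-Gaussian
#' diffusion jointly while keeping perfusion (IVIM) effects out.
#'
#' @param s_lb,s_hb normalized signals at the two key shells (vectorised).
#'   Non-positive or non-finite signals yield `NA`.
#' @param lb,hb key b-values, s/mm^2 (`hb > lb`).
#' @return sADC in mm^2/s.
#' @export
sadc <- function(s_lb, s_hb, lb = 250, hb = 1750) {
  if (hb <= lb) stop_validation("'hb' must exceed 'lb'")
  out <- suppressWarnings(log(s_lb / s_hb) / (hb - lb))
  out[!is.finite(s_lb) | !is.finite(s_hb) | s_lb <= 0 | s_hb <= 0] <- NA_real_
  out
}

#' Signature index (Sindex)
#'
#' Locates the voxel signal pair between the library's two reference
#' signatures as an algebraic relative distance. With
#' \eqn{dS_X(b) = (S_X(b) - S_N(b)) / S_N(b)} and
#' \eqn{\Delta_X = dS_X(Hb) - dS_X(Lb)}, the unscaled index is
#' \deqn{SI = \max(\Delta_V / \Delta_A, 0) - \max(\Delta_V / \Delta_B, 0),}
#' linearly scaled as \eqn{Sindex = (SI + 1) \cdot 25 + 25}: a tissue
#' matching signature A scores 75, one matching B scores 25, and the
#' intermediate signal S_N scores 50. Values are not clamped: regional
#' values outside [25, 75] are meaningful (Sindex varies widely across
#' brain regions).
#'
#' @param s_lb,s_hb normalized voxel signals at the key shells (vectorised).
#' @param library a [signature_library()].
#' @return scaled Sindex (dimensionless).
#' @export
sindex <- function(s_lb, s_hb, library = default_signature_library()) {
  if (!inherits(library, "signature_library"))
    stop_validation("'library' must be a signature_library")
  dv <- (s_hb - library$s_n_hb) / library$s_n_hb -
    (s_lb - library$s_n_lb) / library$s_n_lb
  si <- pmax(dv / library$delta_a, 0) - pmax(dv / library$delta_b, 0)
  out <- (si + 1) * 25 + 25
  out[!is.finite(s_lb) | !is.finite(s_hb) | s_lb <= 0 | s_hb <= 0] <- NA_real_
  out
}

#' Voxelwise marker maps
#'
#' Applies [sadc()] and [sindex()] per valid voxel of a shell-signal map.
#' Voxels masked upstream (or with non-positive signals) stay masked.
#'
#' @param shells a [normalize_and_average()] result.
#' @param library a [signature_library()].
#' @return object of class `marker_map` with fields `sadc`, `sindex`
#'   (3-D arrays, `NA` outside the mask), `mask`, and scan metadata.
#' @export
marker_maps <- function(shells, library = default_signature_library()) {
  if (!inherits(shells, "shell_signal_maps"))
    stop_validation("'shells' must be shell_signal_maps")
  a <- sadc(shells$s_lb, shells$s_hb, shells$lb, shells$hb)
  s <- sindex(shells$s_lb, shells$s_hb, library)
  mask <- shells$mask & is.finite(a) & is.finite(s)
  a[!mask] <- NA_real_
  s[!mask] <- NA_real_
  structure(list(sadc = array(a, shells$grid), sindex = array(s, shells$grid),
                 mask = mask, grid = shells$grid,
                 scan_index = shells$scan_index, subject_id = shells$subject_id,
                 acquisition_time = shells$acquisition_time),
            class = "marker_map")
}

#' ROI-level markers
#'
#' Signals are averaged over all valid voxels of the ROI first, and the
#' markers are then computed from the mean signals (signal-averaging
#' convention) -- not as the mean of voxelwise markers. Set
#' `voxel_mean = TRUE` to obtain the mean-of-voxelwise-markers diagnostic
#' instead; it is never used by the pipeline.
#'
#' @param shells a [normalize_and_average()] result.
#' @param labels a [label_volume()] on the same grid.
#' @param roi ROI name.
#' @param library a [signature_library()].
#' @param voxel_mean if `TRUE`, average voxelwise markers instead of signals.
#' @return one-row data frame: `subject_id`, `scan_index`,
#'   `acquisition_time`, `roi`, `n_voxels`, `s_lb`, `s_hb`, `sadc`,
#'   `sindex`.
#' @export
roi_markers <- function(shells, labels, roi,
                        library = default_signature_library(),
                        voxel_mean = FALSE) {
  if (!inherits(shells, "shell_signal_maps"))
    stop_validation("'shells' must be shell_signal_maps")
  if (!inherits(labels, "label_volume"))
    stop_validation("'labels' must be a label_volume")
  if (!identical(labels$grid, shells$grid))
    stop_validation("shell maps and label volume are on different grids")
  sel <- roi_mask(labels, roi) & shells$mask
  n <- sum(sel)
  if (n == 0L)
    stop_dwim(sprintf("ROI '%s' contains no valid voxels", roi),
              "dwimarkers_empty_roi_error")
  if (voxel_mean) {
    a <- mean(sadc(shells$s_lb[sel], shells$s_hb[sel], shells$lb, shells$hb))
    s <- mean(sindex(shells$s_lb[sel], shells$s_hb[sel], library))
    m_lb <- mean(shells$s_lb[sel]); m_hb <- mean(shells$s_hb[sel])
  } else {
    m_lb <- mean(shells$s_lb[sel])
    m_hb <- mean(shells$s_hb[sel])
    a <- sadc(m_lb, m_hb, shells$lb, shells$hb)
    s <- sindex(m_lb, m_hb, library)
  }
  data.frame(subject_id = shells$subject_id, scan_index = shells$scan_index,
             acquisition_time = shells$acquisition_time, roi = roi,
             n_voxels = n, s_lb = m_lb, s_hb = m_hb, sadc = a, sindex = s,
             stringsAsFactors = FALSE)
}

#' ROI marker table for a whole session
#'
#' Convenience wrapper: normalizes each scan of a subject's session and
#' computes [roi_markers()] for each requested ROI.
#'
#' @param series list of [dwi_series()] (one subject's session).
#' @param labels a [label_volume()].
#' @param library a [signature_library()].
#' @param rois ROI names (default: all dictionary entries).
#' @param group optional group label added as a column.
#' @return data frame, one row per (scan, roi).
#' @export
subject_roi_markers <- function(series, labels,
                                library = default_signature_library(),
                                rois = names(labels$dictionary),
                                group = NA_character_) {
  rows <- lapply(series, function(scan) {
    sh <- normalize_and_average(scan)
    do.call(rbind, lapply(rois, function(r) roi_markers(sh, labels, r, library)))
  })
  out <- do.call(rbind, rows)
  out$group <- group
  out[, c("subject_id", "group", setdiff(names(out), c("subject_id", "group")))]
}
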