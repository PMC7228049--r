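# Seeded synthetic multi-shell DWI cohorts: a deterministic atlas with the
# study's five ROIs, per-ROI kurtosis baselines, a post-injection hindrance
# decrease confined to cortex and hippocampus, Rician noise, and optional
# injected temporal instability for QC testing. All signals are isotropic
# (identical across directions): the pipeline only ever consumes
# direction-averaged signals, so the phantom deliberately carries no
# anisotropy.

#' Phantom cohort specification
#'
#' Bundles every choice the generator needs: grid, acquisition scheme,
#' serial-session layout, per-ROI baseline kurtosis parameters, the
#' post-injection effect model, noise, and instability injection. The
#' defaults emulate a serial mouse-brain study: 13-volume three-shell
#' scheme (b = 0, 250, 1750 s/mm^2, 6 directions), 18 five-minute scans
#' per subject (6 pre-injection), Rician noise at SNR 40 on b0, and an
#' active-group hindrance decrease that is calibrated to a -9% noiseless
#' cortical Sindex change, scaled 1.3x in the hippocampus (and its CA3/DG
#' subregions) and absent in the striatum.
#'
#' The effect moves the kurtosis parameters from the baseline along the
#' negated B-to-A signature direction (a hindrance *decrease*), with a
#' linear ramp over `ramp_scans` post-injection scans to a plateau.
#'
#' @param seed master seed for the cohort (mandatory; sub-seeds per subject
#'   are derived deterministically).
#' @param grid integer vector of 3 voxel dimensions (default 32 x 32 x 8).
#' @param key_low_b,key_high_b key shells, s/mm^2.
#' @param n_scans,n_pre scans per session and pre-injection count.
#' @param scan_interval_min scan duration/spacing, minutes.
#' @param s0 reference b = 0 intensity (arbitrary units).
#' @param snr signal-to-noise ratio at b0 (`Inf` for noiseless).
#' @param noise `"rician"` (magnitude MRI standard), `"gaussian"` (for
#'   analytic checks) or `"none"`.
#' @param baseline named list of [kurtosis_params()] per ROI (plus
#'   `background`); default: the two-point fit of signature B for cortex
#'   and background, with small kurtosis offsets for the other ROIs so maps
#'   show regional contrast.
#' @param target_pct_sindex noiseless cortical Sindex percent change the
#'   default plateau is calibrated to (default -9; 0 disables the effect).
#' @param effect_plateau optional `c(dd, dk)` plateau overriding the
#'   calibration.
#' @param effect_scale named multipliers applied to the plateau per ROI.
#' @param ramp_scans post-injection scans over which the effect ramps
#'   linearly to the plateau.
#' @param instability optional data frame (`x`, `y`, `z`, `amplitude_pct`)
#'   of unstable loci: a sinusoidal temporal modulation is applied to the
#'   diffusion-weighted volumes around each locus, at full amplitude at the
#'   locus and Gaussian-tapered with spatial scale `instability_radius`
#'   (zero beyond three radii), completing `instability_cycles` cycles over
#'   the session. Instability is regional, as motion artifacts are, so it
#'   survives the QC filter's spatial smoothing.
#' @param instability_radius,instability_cycles see `instability`.
#' @param library the [signature_library()] used for calibration.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed,
                         grid = c(32L, 32L, 8L),
                         key_low_b = 250, key_high_b = 1750,
                         n_scans = 18L, n_pre = 6L,
                         scan_interval_min = 5,
                         s0 = 1000,
                         snr = 40,
                         noise = c("rician", "gaussian", "none"),
                         baseline = NULL,
                         target_pct_sindex = -9,
                         effect_plateau = NULL,
                         effect_scale = c(cortex = 1, striatum = 0,
                                          hippocampus = 1.3, CA3 = 1.3,
                                          DG = 1.3, background = 0),
                         ramp_scans = 3L,
                         instability = NULL,
                         instability_radius = 2,
                         instability_cycles = 2,
                         library = default_signature_library()) {
  if (missing(seed)) stop_validation("'seed' is mandatory for a phantom_spec")
  assert_scalar_number(seed, "seed")
  noise <- match.arg(noise)
  if (length(grid) != 3L || any(grid < 1))
    stop_validation("'grid' must be three positive integers")
  if (n_pre >= n_scans) stop_validation("'n_pre' must be smaller than 'n_scans'")
  if (!is.infinite(snr)) assert_scalar_number(snr, "snr", positive = TRUE)

  scheme <- default_scheme(key_low_b, key_high_b)
  if (is.null(baseline)) {
    pb <- fit_two_point(library$s_b_lb, library$s_b_hb, library$lb, library$hb)
    baseline <- list(
      background = pb,
      cortex = pb,
      striatum = kurtosis_params(pb$d * 0.98, pb$k + 0.15),
      hippocampus = kurtosis_params(pb$d * 1.02, pb$k + 0.10),
      CA3 = kurtosis_params(pb$d * 1.02, pb$k + 0.18),
      DG = kurtosis_params(pb$d * 1.02, pb$k + 0.05))
  }
  for (p in baseline) {
    if (!inherits(p, "kurtosis_params"))
      stop_validation("'baseline' entries must be kurtosis_params")
    if (!params_decreasing(p, key_high_b))
      stop_validation("baseline parameters must give a decreasing signal over the b-range")
  }
  miss <- setdiff(c("background", "cortex", "striatum", "hippocampus", "CA3", "DG"),
                  names(baseline))
  if (length(miss) > 0)
    stop_validation(sprintf("'baseline' missing ROIs: %s", paste(miss, collapse = ", ")))

  spec <- structure(list(
    seed = as.integer(seed), grid = as.integer(grid),
    scheme = scheme, n_scans = as.integer(n_scans), n_pre = as.integer(n_pre),
    scan_interval_min = scan_interval_min, s0 = s0, snr = snr, noise = noise,
    baseline = baseline, target_pct_sindex = target_pct_sindex,
    effect_plateau = effect_plateau, effect_scale = effect_scale,
    ramp_scans = as.integer(ramp_scans),
    instability = instability, instability_radius = instability_radius,
    instability_cycles = instability_cycles,
    library = library), class = "phantom_spec")

  if (is.null(spec$effect_plateau)) {
    spec$effect_plateau <- if (target_pct_sindex == 0) c(dd = 0, dk = 0)
      else calibrate_effect(target_pct_sindex, spec, roi = "cortex")$plateau
  }
  # plateau validity at the largest ROI scale
  smax <- max(spec$effect_scale)
  pk <- baseline$cortex
  shifted <- kurtosis_params(pk$d + smax * spec$effect_plateau[["dd"]],
                             pk$k + smax * spec$effect_plateau[["dk"]])
  if (!params_decreasing(shifted, key_high_b))
    stop_validation("effect plateau drives parameters outside validity")
  spec
}

#' Deterministic five-ROI atlas
#'
#' Lays out the five study ROIs on the phantom grid: a cortical band along
#' the slice perimeter, a striatal block and a hippocampal block in the
#' interior, with CA3 and DG carved out of the hippocampal block. Voxel
#' counts are strictly ordered DG < CA3 < hippocampus < striatum < cortex,
#' echoing the real atlas size ordering. The layout is purely a function of
#' the grid, hence identical across calls.
#'
#' @param spec a [phantom_spec()] (or a bare 3-vector grid).
#' @return a [label_volume()] with labels cortex = 1, striatum = 2,
#'   hippocampus = 3, CA3 = 4, DG = 5 (CA3 and DG are hippocampal
#'   subregions).
#' @export
make_atlas <- function(spec) {
  grid <- if (inherits(spec, "phantom_spec")) spec$grid else as.integer(spec)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  n <- min(nx, ny)
  c1 <- max(1L, as.integer(round(n / 16)))
  c2 <- as.integer(round(3 * n / 16))
  x <- slice.index(array(0L, grid), 1)
  y <- slice.index(array(0L, grid), 2)
  dedge <- pmin(x - 1L, nx - x, y - 1L, ny - y)
  labels <- array(0L, grid)

  cortex <- dedge >= c1 & dedge < c2
  x0 <- c2 + 1L; y0 <- c2 + 1L
  iw <- n - 2L * c2
  box <- function(xa, xb, ya, yb) x >= xa & x <= xb & y >= ya & y <= yb
  st_x1 <- x0 + as.integer(ceiling(0.7 * iw)) - 1L
  st_y1 <- y0 + as.integer(ceiling(0.6 * iw)) - 1L
  striatum <- box(x0, st_x1, y0, st_y1)
  hx0 <- x0; hx1 <- x0 + as.integer(ceiling(0.8 * iw)) - 1L
  hy0 <- y0 + as.integer(ceiling(0.65 * iw))
  hy1 <- y0 + as.integer(ceiling(0.95 * iw)) - 1L
  hippo <- box(hx0, hx1, hy0, hy1)
  hw <- hx1 - hx0 + 1L; hh <- hy1 - hy0 + 1L
  ca3 <- box(hx0 + 1L, hx0 + max(1L, as.integer(floor(0.3 * hw))),
             hy0, hy0 + max(1L, as.integer(floor(0.7 * hh))) - 1L) & hippo
  dg <- box(hx0 + as.integer(floor(0.55 * hw)),
            hx0 + as.integer(floor(0.55 * hw)) + max(1L, as.integer(floor(0.2 * hw))) - 1L,
            hy0, hy0 + max(1L, as.integer(floor(0.5 * hh))) - 1L) & hippo

  feasible <- c2 > c1 && iw >= 4L &&
    any(cortex) && any(striatum) && any(hippo) && any(ca3) && any(dg) &&
    !any(ca3 & dg) && !any(cortex & (striatum | hippo)) && !any(striatum & hippo) &&
    hy1 <= n - c2
  if (!feasible)
    stop_dwim(sprintf("grid %s is too small for the five-ROI atlas geometry",
                      paste(grid, collapse = "x")),
              "dwimarkers_geometry_error")

  labels[cortex] <- 1L
  labels[striatum] <- 2L
  labels[hippo] <- 3L
  labels[ca3] <- 4L
  labels[dg] <- 5L
  counts <- c(sum(dg), sum(ca3), sum(hippo), sum(striatum), sum(cortex))
  if (any(diff(counts) <= 0))
    stop_dwim("atlas voxel counts are not strictly ordered DG < CA3 < hippocampus < striatum < cortex",
              "dwimarkers_geometry_error")
  label_volume(labels, c(cortex = 1L, striatum = 2L, hippocampus = 3L,
                         CA3 = 4L, DG = 5L))
}

# Effect ramp fraction for scan i: 0 before injection, then a linear ramp
# over ramp_scans to the plateau (held until the end of the session).
effect_fraction <- function(i, n_pre, ramp_scans) {
  ifelse(i <= n_pre, 0, pmin(1, (i - n_pre) / ramp_scans))
}

# Hindrance-decrease direction in (d, k) space: the B-to-A signature
# direction, negated (A is the hindrance-increase reference).
effect_direction <- function(library) {
  pa <- fit_two_point(library$s_a_lb, library$s_a_hb, library$lb, library$hb)
  pb <- fit_two_point(library$s_b_lb, library$s_b_hb, library$lb, library$hb)
  c(dd = pb$d - pa$d, dk = pb$k - pa$k)
}

# Noiseless ROI Sindex for baseline params shifted by t * direction.
noiseless_sindex_at <- function(base, u, t, library) {
  p <- kurtosis_params(base$d + t * u[["dd"]], base$k + t * u[["dk"]])
  sindex(kurtosis_signal(p, library$lb), kurtosis_signal(p, library$hb), library)
}

#' Calibrate the effect plateau to a target Sindex change
#'
#' One-dimensional search along the hindrance-decrease direction (the
#' negated B-to-A signature direction) for the plateau `(dd, dk)` whose
#' noiseless ROI-level Sindex percent change in `roi` equals `target_pct`.
#' The search domain is bounded by parameter validity (`k > -3`, decreasing
#' signal) and by the nominal Sindex floor of 0, beyond which the linear
#' scaling loses meaning; targets outside the reachable range raise a typed
#' error.
#'
#' @param target_pct target percent change of the noiseless ROI Sindex
#'   (negative = decrease). `0` returns a zero plateau.
#' @param spec a [phantom_spec()] (its baseline and library are used).
#' @param roi ROI whose baseline the calibration uses (default cortex).
#' @param tol convergence tolerance on the percent change.
#' @return list with `plateau` (`c(dd, dk)`), `t` (step along the
#'   direction) and `achieved_pct`.
#' @export
calibrate_effect <- function(target_pct, spec, roi = "cortex", tol = 1e-6) {
  assert_scalar_number(target_pct, "target_pct")
  lib <- spec$library
  base <- spec$baseline[[roi]]
  if (is.null(base)) stop_validation(sprintf("no baseline parameters for ROI '%s'", roi))
  u <- effect_direction(lib)
  if (target_pct == 0)
    return(list(plateau = c(dd = 0, dk = 0), t = 0, achieved_pct = 0))

  s_base <- noiseless_sindex_at(base, u, 0, lib)
  pct <- function(t) 100 * (noiseless_sindex_at(base, u, t, lib) - s_base) / s_base

  # upper bound: k > -3 (with margin), decreasing signal, Sindex >= 0
  t_hi <- Inf
  if (u[["dk"]] < 0) t_hi <- min(t_hi, (base$k - (-3 + 1e-9)) / (-u[["dk"]]))
  if (u[["dd"]] < 0) t_hi <- min(t_hi, (base$d - 1e-12) / (-u[["dd"]]))
  if (!is.finite(t_hi)) t_hi <- 10
  f_floor <- function(t) noiseless_sindex_at(base, u, t, lib)
  if (f_floor(t_hi) < 0)
    t_hi <- stats::uniroot(f_floor, c(0, t_hi), tol = 1e-12)$root
  reach <- pct(t_hi)
  if ((target_pct < 0 && target_pct < reach) || target_pct > 0)
    stop_dwim(sprintf(
      "target %.3g%% unreachable: the hindrance-decrease calibration spans [%.3g%%, 0%%]",
      target_pct, reach), "dwimarkers_calibration_error")
  root <- stats::uniroot(function(t) pct(t) - target_pct, c(0, t_hi),
                         tol = 1e-12)$root
  list(plateau = c(dd = unname(u[["dd"]] * root), dk = unname(u[["dk"]] * root)),
       t = root, achieved_pct = pct(root))
}

# Amplitude field (fractional, per voxel) for injected instability: each
# locus carries a Gaussian-tapered regional modulation (full amplitude at
# the locus, scale `instability_radius`, zero beyond three radii), the way
# motion artifacts affect neighbourhoods rather than single voxels.
instability_field <- function(spec) {
  inst <- spec$instability
  if (is.null(inst) || nrow(inst) == 0L) return(NULL)
  g <- spec$grid
  x <- slice.index(array(0L, g), 1)
  y <- slice.index(array(0L, g), 2)
  z <- slice.index(array(0L, g), 3)
  amp <- array(0, g)
  r <- spec$instability_radius
  for (i in seq_len(nrow(inst))) {
    d2 <- (x - inst$x[i])^2 + (y - inst$y[i])^2 + (z - inst$z[i])^2
    a <- (inst$amplitude_pct[i] / 100) * exp(-d2 / (2 * r^2))
    a[d2 > (3 * r)^2] <- 0
    amp <- pmax(amp, a)
  }
  amp
}

#' Simulate one subject's serial session
#'
#' Per scan and voxel the noiseless signal is
#' `s0 * kurtosis_signal(params(roi, group, t), b)`, identical across the
#' six directions (isotropy by design). For the active group the
#' parameters move along the effect direction with the ramp-to-plateau time
#' profile; the vehicle group and unaffected ROIs stay at baseline. Rician
#' noise is applied as the magnitude of the noiseless signal plus complex
#' Gaussian noise with per-channel sd `s0 / snr`. Fully reproducible from
#' `subject_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param group `"vehicle"` or `"tgn020"`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param atlas optional precomputed [make_atlas()] result for `spec`.
#' @return list with `series` (list of `n_scans` [dwi_series()]) and
#'   `manifest` (data frame rows without file paths).
#' @export
simulate_subject <- function(spec, group = c("vehicle", "tgn020"),
                             subject_seed, subject_id = "subject",
                             atlas = NULL) {
  group <- match.arg(group)
  if (!inherits(spec, "phantom_spec")) stop_validation("'spec' must be a phantom_spec")
  atlas <- atlas %||% make_atlas(spec)
  sch <- spec$scheme
  g <- spec$grid
  nvox <- prod(g)
  set.seed(as.integer(subject_seed))

  # label index (1-based into the parameter table: background + dictionary)
  roi_names <- c("background", names(atlas$dictionary))
  lab_idx <- as.vector(atlas$labels) + 1L
  dw_cols <- which(sch$bvalues > sch$shell_tolerance)
  amp <- instability_field(spec)
  sigma <- if (is.infinite(spec$snr)) 0 else spec$s0 / spec$snr

  series <- vector("list", spec$n_scans)
  times <- spec$scan_interval_min * (seq_len(spec$n_scans) - 1) -
    spec$scan_interval_min * spec$n_pre
  for (i in seq_len(spec$n_scans)) {
    e <- effect_fraction(i, spec$n_pre, spec$ramp_scans)
    vals <- matrix(0, length(roi_names), sch$n_volumes)
    for (j in seq_along(roi_names)) {
      p0 <- spec$baseline[[roi_names[j]]]
      sc <- if (group == "tgn020" && roi_names[j] %in% names(spec$effect_scale))
        unname(spec$effect_scale[[roi_names[j]]]) else 0
      p <- if (sc * e != 0)
        kurtosis_params(p0$d + sc * e * spec$effect_plateau[["dd"]],
                        p0$k + sc * e * spec$effect_plateau[["dk"]])
      else p0
      vals[j, ] <- spec$s0 * kurtosis_signal(p, sch$bvalues)
    }
    arr <- vals[lab_idx, , drop = FALSE]
    if (!is.null(amp)) {
      f <- sin(2 * pi * spec$instability_cycles * (i - 1) / spec$n_scans)
      mod <- 1 + as.vector(amp) * f
      arr[, dw_cols] <- arr[, dw_cols] * mod
    }
    if (sigma > 0) {
      if (spec$noise == "rician") {
        arr <- sqrt((arr + stats::rnorm(length(arr), sd = sigma))^2 +
                      stats::rnorm(length(arr), sd = sigma)^2)
      } else {
        arr <- pmax(arr + stats::rnorm(length(arr), sd = sigma), 0)
      }
    }
    series[[i]] <- dwi_series(array(arr, c(g, sch$n_volumes)), sch,
                              scan_index = i, subject_id = subject_id,
                              acquisition_time = times[i])
  }
  manifest <- data.frame(subject_id = subject_id, group = group,
                         scan_index = seq_len(spec$n_scans), path = NA_character_,
                         time_min = times, stringsAsFactors = FALSE)
  list(series = series, manifest = manifest)
}

#' Simulate a two-group cohort
#'
#' Derives one seed per subject deterministically from the master seed and
#' simulates `n_per_group` subjects per group. With `dir` set, every
#' artefact the readers consume is written to disk (NIfTI scans, bval/bvec,
#' label volume + dictionary, manifest) and the manifest references the
#' files; with `dir = NULL` the scans are returned in memory (only
#' advisable for small cohorts).
#'
#' @param spec a [phantom_spec()].
#' @param n_per_group subjects per group (>= 2 for downstream statistics).
#' @param master_seed cohort seed; defaults to `spec$seed`.
#' @param dir output directory, or `NULL` for in-memory.
#' @return list with `manifest` (a [study_manifest()]), `labels`, and --
#'   in-memory mode -- `subjects` (named list of [simulate_subject()]
#'   results).
#' @export
simulate_cohort <- function(spec, n_per_group = 16L, master_seed = spec$seed,
                            dir = NULL) {
  if (n_per_group < 1L) stop_validation("'n_per_group' must be >= 1")
  atlas <- make_atlas(spec)
  write_out <- !is.null(dir)
  if (write_out) {
    if (dir.exists(dir) && length(list.files(dir)) > 0)
      stop_io(sprintf("output directory '%s' is not empty (outputs are write-once)", dir))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_scheme(spec$scheme, file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
    write_labels(atlas, file.path(dir, "labels.nii.gz"), file.path(dir, "labels.json"))
  }
  groups <- c(rep("vehicle", n_per_group), rep("tgn020", n_per_group))
  ids <- c(sprintf("veh%02d", seq_len(n_per_group)),
           sprintf("tgn%02d", seq_len(n_per_group)))
  subjects <- list()
  manifest <- list()
  for (i in seq_along(ids)) {
    sub <- simulate_subject(spec, groups[i], derive_seed(master_seed, i),
                            subject_id = ids[i], atlas = atlas)
    if (write_out) {
      for (s in sub$series) {
        fn <- sprintf("%s_scan%02d.nii.gz", ids[i], s$scan_index)
        write_dwi(s, file.path(dir, fn))
        # manifests store paths relative to their own directory, so runs
        # are byte-identical across run directories
        sub$manifest$path[sub$manifest$scan_index == s$scan_index] <- fn
      }
    } else {
      subjects[[ids[i]]] <- sub
    }
    manifest[[i]] <- sub$manifest
  }
  manifest <- study_manifest(do.call(rbind, manifest),
                             n_scans = spec$n_scans, n_pre = spec$n_pre)
  if (write_out) {
    write_table(manifest, file.path(dir, "manifest.tsv"))
    list(manifest = manifest, labels = atlas, dir = dir)
  } else {
    list(manifest = manifest, labels = atlas, subjects = subjects)
  }
}

#' Simulate and analyse a cohort end to end, streaming subjects
#'
#' Memory-light driver used for cohort-scale experiments: each subject is
#' simulated, reduced to its ROI marker rows, and discarded before the next
#' one is generated. Returns the ROI marker table together with the
#' pre/post summary, time course and statistics report.
#'
#' @inheritParams simulate_cohort
#' @param rois analysis ROIs.
#' @return list with `table`, `prepost`, `course`, `stats`.
#' @export
simulate_and_analyze <- function(spec, n_per_group = 16L,
                                 master_seed = spec$seed,
                                 rois = c("cortex", "striatum", "hippocampus")) {
  atlas <- make_atlas(spec)
  groups <- c(rep("vehicle", n_per_group), rep("tgn020", n_per_group))
  ids <- c(sprintf("veh%02d", seq_len(n_per_group)),
           sprintf("tgn%02d", seq_len(n_per_group)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- simulate_subject(spec, groups[i], derive_seed(master_seed, i),
                            subject_id = ids[i], atlas = atlas)
    rows[[i]] <- subject_roi_markers(sub$series, atlas, spec$library,
                                     rois = rois, group = groups[i])
  }
  table <- do.call(rbind, rows)
  prepost <- prepost_average(table, n_window = spec$n_pre)
  course <- build_timecourse(table)
  stats <- run_stats(prepost, course)
  list(table = table, prepost = prepost, course = course, stats = stats)
}
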