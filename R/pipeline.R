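# File-based pipeline stages. Each stage reads its inputs from disk and
# writes its outputs (plus a provenance record) into its own subdirectory of
# the run's output directory, so stages are independently re-runnable and a
# rerun with the same configuration and seed is byte-identical. A thin
# command-line wrapper over these functions ships in
# `inst/scripts/dwi-pipeline.R`.

#' Validate a run configuration
#'
#' Accepts a YAML/JSON file path or a list. Recognised keys (all optional
#' unless noted):
#' \describe{
#'   \item{seed}{integer master seed (required).}
#'   \item{output_dir}{run directory (required).}
#'   \item{simulation}{`n_per_group`, `grid` (3 ints), `snr`,
#'     `target_pct_sindex`.}
#'   \item{qc}{`threshold_pct` (> 0), `smoothing_fwhm_vox` (>= 0),
#'     `enabled`.}
#'   \item{markers}{`write_maps` (logical), `rois` (character).}
#'   \item{stats}{`posthoc` (a [stats::p.adjust()] method), `z_cutoff`
#'     (> 0).}
#' }
#' @param config list or path.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_io(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_validation("'config' must be a list or a file path")
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop_validation("config field 'seed' is required and must be numeric")
  if (is.null(config$output_dir) || !is.character(config$output_dir))
    stop_validation("config field 'output_dir' is required")
  defaults <- list(
    simulation = list(n_per_group = 4L, grid = c(32L, 32L, 8L), snr = 40,
                      target_pct_sindex = -9),
    qc = list(enabled = TRUE, threshold_pct = 4, smoothing_fwhm_vox = 2),
    markers = list(write_maps = FALSE,
                   rois = c("cortex", "striatum", "hippocampus", "CA3", "DG")),
    stats = list(posthoc = "holm", z_cutoff = 3))
  for (sec in names(defaults)) {
    config[[sec]] <- utils::modifyList(defaults[[sec]], config[[sec]] %||% list())
  }
  if (config$qc$threshold_pct <= 0)
    stop_validation("config field 'qc.threshold_pct' must be positive")
  if (config$qc$smoothing_fwhm_vox < 0)
    stop_validation("config field 'qc.smoothing_fwhm_vox' must be non-negative")
  if (config$stats$z_cutoff <= 0)
    stop_validation("config field 'stats.z_cutoff' must be positive")
  if (!config$stats$posthoc %in% stats::p.adjust.methods)
    stop_validation("config field 'stats.posthoc' is not a p.adjust method")
  if (length(config$simulation$grid) != 3L)
    stop_validation("config field 'simulation.grid' must have three elements")
  config$seed <- as.integer(config$seed)
  class(config) <- c("run_config", "list")
  config
}

write_provenance <- function(dir, stage, config) {
  keep <- config[setdiff(names(config), NULL)]
  class(keep) <- "list"
  jsonlite::write_json(
    list(stage = stage, seed = config$seed, config = keep,
         package = "dwimarkers",
         version = as.character(utils::packageVersion("dwimarkers"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}

stage_dir <- function(config, stage) {
  d <- file.path(config$output_dir, stage)
  if (dir.exists(d) && length(list.files(d)) > 0)
    stop_io(sprintf("stage directory '%s' is not empty (outputs are write-once per run)", d))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

#' Pipeline stage: simulate a cohort to disk
#'
#' @param config a [run_config()] (or something coercible by it).
#' @return the data directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- run_config(config)
  d <- file.path(config$output_dir, "data")
  sim <- config$simulation
  spec <- phantom_spec(seed = config$seed, grid = as.integer(sim$grid),
                       snr = sim$snr, target_pct_sindex = sim$target_pct_sindex)
  simulate_cohort(spec, n_per_group = as.integer(sim$n_per_group), dir = d)
  write_provenance(d, "simulate", config)
  invisible(d)
}

load_inputs <- function(config) {
  d <- file.path(config$output_dir, "data")
  scheme <- read_scheme(file.path(d, "dwi.bval"), file.path(d, "dwi.bvec"))
  labels <- read_labels(file.path(d, "labels.nii.gz"), file.path(d, "labels.json"))
  manifest <- read_manifest(file.path(d, "manifest.tsv"))
  list(scheme = scheme, labels = labels, manifest = manifest)
}

# Manifest paths may be relative to the data directory they were written in.
resolve_path <- function(path, base) {
  ifelse(grepl("^(/|[A-Za-z]:)", path), path, file.path(base, path))
}

subject_session_maps <- function(manifest, subject, scheme, base) {
  rows <- manifest[manifest$subject_id == subject, ]
  rows <- rows[order(rows$scan_index), ]
  lapply(seq_len(nrow(rows)), function(i) {
    normalize_and_average(read_dwi(resolve_path(rows$path[i], base), scheme,
                                   scan_index = rows$scan_index[i],
                                   subject_id = subject,
                                   acquisition_time = rows$time_min[i]))
  })
}

#' Pipeline stage: voxel-stability QC and session discard
#'
#' Writes `manifest_filtered.tsv` plus a per-subject/ROI flag summary.
#'
#' @inheritParams run_simulate
#' @export
run_qc <- function(config) {
  config <- run_config(config)
  inp <- load_inputs(config)
  d <- stage_dir(config, "qc")
  reports <- list()
  for (s in unique(inp$manifest$subject_id)) {
    maps <- subject_session_maps(inp$manifest, s, inp$scheme,
                                 file.path(config$output_dir, "data"))
    reports[[s]] <- flag_unstable_voxels(
      maps, threshold_pct = config$qc$threshold_pct,
      smoothing_fwhm_vox = config$qc$smoothing_fwhm_vox)
  }
  filtered <- apply_discard_rule(reports, inp$labels, inp$manifest)
  write_table(filtered, file.path(d, "manifest_filtered.tsv"))
  log <- attr(filtered, "discard_log")
  flag_counts <- data.frame(
    subject_id = names(reports),
    n_flagged = vapply(reports, function(r) sum(r$flagged), 1L),
    discarded = names(reports) %in% log$subject_id,
    stringsAsFactors = FALSE)
  write_table(flag_counts, file.path(d, "stability_summary.tsv"))
  if (nrow(log) > 0) write_table(log, file.path(d, "discard_log.tsv"))
  write_provenance(d, "qc", config)
  invisible(d)
}

#' Pipeline stage: marker maps and the ROI marker table
#'
#' Consumes the QC-filtered manifest when present, the raw one otherwise.
#' Writes `roi_markers.tsv` and, with `markers.write_maps`, per-scan sADC
#' and Sindex NIfTI maps.
#'
#' @inheritParams run_simulate
#' @export
run_markers <- function(config) {
  config <- run_config(config)
  inp <- load_inputs(config)
  fm <- file.path(config$output_dir, "qc", "manifest_filtered.tsv")
  manifest <- if (file.exists(fm)) read_manifest(fm) else inp$manifest
  d <- stage_dir(config, "markers")
  library <- default_signature_library()
  rois <- config$markers$rois
  rows <- list()
  for (s in unique(manifest$subject_id)) {
    maps <- subject_session_maps(manifest, s, inp$scheme,
                                 file.path(config$output_dir, "data"))
    grp <- manifest$group[manifest$subject_id == s][1]
    for (sh in maps) {
      rows[[length(rows) + 1L]] <- cbind(
        do.call(rbind, lapply(rois, function(r)
          roi_markers(sh, inp$labels, r, library))),
        group = grp, stringsAsFactors = FALSE)
      if (isTRUE(config$markers$write_maps)) {
        mm <- marker_maps(sh, library)
        write_marker_map(mm, file.path(d, "maps"),
                         prefix = sprintf("%s_scan%02d", s, sh$scan_index))
      }
    }
  }
  table <- do.call(rbind, rows)
  write_table(table, file.path(d, "roi_markers.tsv"))
  write_provenance(d, "markers", config)
  invisible(d)
}

#' Pipeline stage: cohort aggregation and statistics
#'
#' Writes subject and group pre/post tables, the time course and the
#' statistics report (between-group and per-time-point tests).
#'
#' @inheritParams run_simulate
#' @export
run_cohort <- function(config) {
  config <- run_config(config)
  table <- read_table(file.path(config$output_dir, "markers", "roi_markers.tsv"))
  d <- stage_dir(config, "cohort")
  prepost <- prepost_average(table)
  course <- build_timecourse(table)
  stats <- run_stats(prepost, course, posthoc = config$stats$posthoc,
                     z_cutoff = config$stats$z_cutoff)
  write_table(prepost$subjects, file.path(d, "prepost_subjects.tsv"))
  write_table(prepost$groups, file.path(d, "prepost_groups.tsv"))
  write_table(course, file.path(d, "timecourse.tsv"))
  write_table(stats$between, file.path(d, "stats_between.tsv"))
  write_table(stats$timepoint, file.path(d, "stats_timepoint.tsv"))
  write_provenance(d, "cohort", config)
  invisible(d)
}

#' Run the full pipeline: simulate, QC, markers, cohort
#'
#' @inheritParams run_simulate
#' @return the run's output directory, invisibly.
#' @export
run_all <- function(config) {
  config <- run_config(config)
  run_simulate(config)
  if (isTRUE(config$qc$enabled)) run_qc(config)
  run_markers(config)
  run_cohort(config)
  invisible(config$output_dir)
}
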