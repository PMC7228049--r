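# Readers and writers for every external format the pipeline touches:
# NIfTI-1 volumes, label dictionaries, study manifests and marker tables.
# All readers validate into the domain types and raise typed conditions;
# nothing is silently coerced.

#' Construct a DWI series
#'
#' One 4-D diffusion-weighted scan tied to an acquisition scheme and its
#' position within a serial session.
#'
#' @param intensities 4-D numeric array (x, y, z, volume), non-negative.
#' @param scheme an [acquisition_scheme()]; its length must equal the 4th
#'   dimension.
#' @param scan_index 1-based position of the scan within the session.
#' @param subject_id subject identifier.
#' @param acquisition_time scan start time in minutes relative to injection
#'   (negative = pre-injection).
#' @return an object of class `dwi_series`.
#' @export
dwi_series <- function(intensities, scheme, scan_index = 1L,
                       subject_id = "subject", acquisition_time = NA_real_) {
  if (!inherits(scheme, "acquisition_scheme"))
    stop_validation("'scheme' must be an acquisition_scheme")
  d <- dim(intensities)
  if (length(d) != 4L)
    stop_validation("'intensities' must be a 4-D array (x, y, z, volume)")
  if (d[4] != scheme$n_volumes)
    stop_validation(sprintf(
      "volume count mismatch: data has %d volumes, scheme expects %d",
      d[4], scheme$n_volumes))
  if (any(!is.finite(intensities)))
    stop_validation("'intensities' contains non-finite voxels")
  if (any(intensities < 0))
    stop_validation("'intensities' must be non-negative")
  structure(list(
    intensities = intensities,
    scheme = scheme,
    scan_index = as.integer(scan_index),
    subject_id = as.character(subject_id),
    acquisition_time = as.double(acquisition_time),
    grid = d[1:3]
  ), class = "dwi_series")
}

#' Read a 4-D DWI volume from NIfTI-1
#'
#' @param path NIfTI-1 file (optionally gzipped).
#' @inheritParams dwi_series
#' @return a `dwi_series`.
#' @export
read_dwi <- function(path, scheme, scan_index = 1L, subject_id = "subject",
                     acquisition_time = NA_real_) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.double(img), dim = dim(img))
  dwi_series(arr, scheme, scan_index = scan_index, subject_id = subject_id,
             acquisition_time = acquisition_time)
}

#' Write a DWI series to NIfTI-1
#'
#' Stored as float64 so that a write/read round trip is bit-identical.
#'
#' @param series a `dwi_series`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_dwi <- function(series, path) {
  RNifti::writeNifti(series$intensities, path, datatype = "double")
  invisible(path)
}

#' Construct a label volume
#'
#' Integer ROI labels over the same spatial grid as the DWI data. Label 0 is
#' background. `hierarchy` maps subregion names to their parent ROI (by
#' default CA3 and DG are subregions of the hippocampus when present), so
#' that a parent ROI resolves to the union of its own label and those of its
#' subregions.
#'
#' @param labels 3-D integer array.
#' @param dictionary named integer vector mapping ROI name -> label id.
#' @param hierarchy named character vector mapping subregion name -> parent
#'   ROI name.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, dictionary,
                         hierarchy = c(CA3 = "hippocampus", DG = "hippocampus")) {
  if (length(dim(labels)) != 3L)
    stop_validation("'labels' must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (is.null(names(dictionary)) || any(!nzchar(names(dictionary))))
    stop_validation("'dictionary' must be a named integer vector (name -> id)")
  dictionary <- stats::setNames(as.integer(dictionary), names(dictionary))
  if (anyDuplicated(dictionary) || anyDuplicated(names(dictionary)))
    stop_validation("'dictionary' ids and names must be unique")
  ids <- sort(unique(as.vector(labels)))
  unknown <- setdiff(ids, c(0L, unname(dictionary)))
  if (length(unknown) > 0)
    stop_validation(sprintf("label grid contains ids absent from dictionary: %s",
                            paste(unknown, collapse = ", ")))
  hierarchy <- hierarchy[names(hierarchy) %in% names(dictionary) &
                           hierarchy %in% names(dictionary)]
  structure(list(labels = labels, dictionary = dictionary,
                 hierarchy = hierarchy, grid = dim(labels)),
            class = "label_volume")
}

#' Logical mask of an ROI (including its subregions)
#'
#' @param labels a `label_volume`.
#' @param roi ROI name present in the dictionary.
#' @return logical 3-D array.
#' @export
roi_mask <- function(labels, roi) {
  if (!roi %in% names(labels$dictionary))
    stop_validation(sprintf("unknown ROI '%s'", roi))
  ids <- labels$dictionary[[roi]]
  kids <- names(labels$hierarchy)[labels$hierarchy == roi]
  ids <- c(ids, unname(labels$dictionary[kids]))
  array(labels$labels %in% ids, dim = labels$grid)
}

#' Read a label volume and its dictionary
#'
#' The dictionary is either two-column delimited text (id, name; with
#' header) or a JSON object mapping name -> id, selected by file extension.
#'
#' @param path NIfTI-1 integer label image.
#' @param dict_path dictionary file (`.json` or delimited text).
#' @inheritParams label_volume
#' @return a `label_volume`.
#' @export
read_labels <- function(path, dict_path,
                        hierarchy = c(CA3 = "hippocampus", DG = "hippocampus")) {
  for (p in c(path, dict_path))
    if (!file.exists(p)) stop_io(sprintf("file not found: %s", p))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # NIfTI drops trailing singleton dims
  arr <- array(as.integer(round(as.double(img))), dim = d)
  if (grepl("\\.json$", dict_path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(dict_path, simplifyVector = TRUE)
    dict <- stats::setNames(as.integer(unlist(lst)), names(lst))
  } else {
    df <- utils::read.delim(dict_path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_io("label dictionary must have two columns: id, name")
    dict <- stats::setNames(as.integer(df[[1]]), as.character(df[[2]]))
  }
  label_volume(arr, dict, hierarchy = hierarchy)
}

#' Write a label volume and its dictionary
#'
#' @param labels a `label_volume`.
#' @param path output NIfTI path.
#' @param dict_path output dictionary path (JSON).
#' @export
write_labels <- function(labels, path, dict_path) {
  RNifti::writeNifti(labels$labels, path, datatype = "int16")
  jsonlite::write_json(as.list(labels$dictionary), dict_path, auto_unbox = TRUE)
  invisible(path)
}

#' Construct a study manifest
#'
#' One row per (subject, scan): subject id, group (vehicle / tgn020), scan
#' index, file path and acquisition time in minutes relative to injection.
#' Each subject is expected to contribute 18 scans, exactly 6 of them
#' pre-injection (negative time); both groups must be represented unless the
#' manifest is empty (which is allowed, with a warning, as the result of the
#' quality-control discard rule).
#'
#' @param df data frame with columns `subject_id`, `group`, `scan_index`,
#'   `path`, `time_min`.
#' @param n_scans,n_pre expected scans per subject and pre-injection count.
#' @return a `study_manifest` (a validated data frame).
#' @export
study_manifest <- function(df, n_scans = 18L, n_pre = 6L) {
  req <- c("subject_id", "group", "scan_index", "path", "time_min")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_validation(sprintf("manifest missing columns: %s", paste(miss, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[req]
  df$scan_index <- as.integer(df$scan_index)
  df$time_min <- as.double(df$time_min)
  if (nrow(df) == 0L) {
    warning("empty study manifest")
  } else {
    if (!all(df$group %in% c("vehicle", "tgn020")))
      stop_validation("manifest 'group' must be 'vehicle' or 'tgn020'")
    for (s in unique(df$subject_id)) {
      rows <- df[df$subject_id == s, ]
      if (nrow(rows) != n_scans)
        stop_validation(sprintf("subject '%s' has %d rows, expected %d", s, nrow(rows), n_scans))
      if (anyDuplicated(rows$scan_index))
        stop_validation(sprintf("subject '%s' has duplicated scan_index", s))
      if (sum(rows$time_min < 0) != n_pre)
        stop_validation(sprintf("subject '%s' must have exactly %d pre-injection scans", s, n_pre))
    }
  }
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' Read a study manifest from delimited text
#'
#' @param path tab-delimited file with header
#'   `subject_id group scan_index path time_min`.
#' @inheritParams study_manifest
#' @return a `study_manifest`.
#' @export
read_manifest <- function(path, n_scans = 18L, n_pre = 6L) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  study_manifest(df, n_scans = n_scans, n_pre = n_pre)
}

#' Write a data frame as full-precision delimited text
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read round trip reproduces doubles exactly (well within 1e-12).
#'
#' @param table data frame.
#' @param path output path (tab-delimited, with header).
#' @export
write_table <- function(table, path) {
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited table written by [write_table()]
#'
#' @param path tab-delimited file with header.
#' @return data frame with numeric columns restored.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      suppressWarnings(num <- as.numeric(df[[j]]))
      failed <- is.na(num) & !(df[[j]] %in% c("NA", ""))
      if (!any(failed) && !all(is.na(num))) df[[j]] <- num
    }
  }
  df
}

#' Write voxelwise marker maps to NIfTI-1
#'
#' Writes the sADC map, the Sindex map and the validity mask of a
#' [marker_maps()] result as three NIfTI files `<prefix>_sadc.nii.gz`,
#' `<prefix>_sindex.nii.gz`, `<prefix>_mask.nii.gz`. Invalid voxels are
#' written as 0 in the marker maps (the mask disambiguates).
#'
#' @param map a `marker_map`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths.
#' @export
write_marker_map <- function(map, dir, prefix = "markers") {
  if (!inherits(map, "marker_map")) stop_validation("'map' must be a marker_map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- function(a) { a[!map$mask] <- 0; a }
  paths <- c(
    sadc = file.path(dir, paste0(prefix, "_sadc.nii.gz")),
    sindex = file.path(dir, paste0(prefix, "_sindex.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  RNifti::writeNifti(z(map$sadc), paths[["sadc"]], datatype = "double")
  RNifti::writeNifti(z(map$sindex), paths[["sindex"]], datatype = "double")
  RNifti::writeNifti(array(as.integer(map$mask), dim = dim(map$mask)),
                     paths[["mask"]], datatype = "int16")
  invisible(paths)
}
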