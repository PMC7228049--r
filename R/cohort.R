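# Cohort-level aggregation and statistics: pre/post window means, 6-point
# time courses, z-score outlier filtering, and the group tests.

marker_cols <- c("sadc", "sindex")

check_roi_table <- function(table) {
  req <- c("subject_id", "group", "scan_index", "acquisition_time", "roi",
           marker_cols)
  miss <- setdiff(req, names(table))
  if (length(miss) > 0)
    stop_validation(sprintf("ROI marker table missing columns: %s",
                            paste(miss, collapse = ", ")))
  invisible(table)
}

# Long format: one row per (subject, group, roi, marker, scan).
roi_table_long <- function(table) {
  check_roi_table(table)
  do.call(rbind, lapply(marker_cols, function(m) {
    data.frame(subject_id = table$subject_id, group = table$group,
               roi = table$roi, marker = m, scan_index = table$scan_index,
               acquisition_time = table$acquisition_time,
               value = table[[m]], stringsAsFactors = FALSE)
  }))
}

#' Pre/post window averages and paired tests
#'
#' Per subject, ROI and marker: the pre window is the mean over the scans
#' with negative acquisition time (expected `n_window` of them) and the post
#' window is the mean over the session's final `n_window` scans (the last 6
#' of the 12 post-injection scans, read literally). Subjects with an
#' incomplete window are excluded and logged. Group-level rows carry the
#' paired two-sided t-test p-value, the mean change and the percent change
#' (100 x mean change / mean pre).
#'
#' Window selection is order-based on `scan_index`; permuting the row order
#' of the input table does not change any output.
#'
#' @param table ROI marker table (see [subject_roi_markers()]).
#' @param n_window scans per window (default 6).
#' @return object of class `prepost_summary`: list with `subjects` (subject
#'   x roi x marker data frame with `pre`, `post`), `groups` (group x roi x
#'   marker with `n`, `p_paired`, `mean_change`, `pct_change`) and
#'   `excluded` (character vector of subject ids).
#' @export
prepost_average <- function(table, n_window = 6L) {
  long <- roi_table_long(table)
  excluded <- character(0)
  subjects <- list()
  for (key in split(long, list(long$subject_id, long$roi, long$marker), drop = TRUE)) {
    key <- key[order(key$scan_index), ]
    pre_rows <- key[key$acquisition_time < 0, ]
    post_rows <- utils::tail(key, n_window)
    if (nrow(pre_rows) != n_window || nrow(post_rows) != n_window ||
        any(post_rows$acquisition_time < 0)) {
      excluded <- c(excluded, key$subject_id[1])
      next
    }
    subjects[[length(subjects) + 1L]] <- data.frame(
      subject_id = key$subject_id[1], group = key$group[1],
      roi = key$roi[1], marker = key$marker[1],
      pre = mean(pre_rows$value), post = mean(post_rows$value),
      stringsAsFactors = FALSE)
  }
  excluded <- sort(unique(excluded))
  if (length(excluded) > 0)
    warning(sprintf("prepost_average: excluded subjects with incomplete windows: %s",
                    paste(excluded, collapse = ", ")))
  subjects <- do.call(rbind, subjects)
  subjects <- subjects[!(subjects$subject_id %in% excluded), , drop = FALSE]

  groups <- list()
  for (g in split(subjects, list(subjects$group, subjects$roi, subjects$marker),
                  drop = TRUE)) {
    groups[[length(groups) + 1L]] <- data.frame(
      group = g$group[1], roi = g$roi[1], marker = g$marker[1],
      n = nrow(g),
      p_paired = paired_p(g$pre, g$post),
      mean_change = mean(g$post - g$pre),
      pct_change = 100 * mean(g$post - g$pre) / mean(g$pre),
      stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, groups)
  ord <- order(groups$marker, groups$roi, groups$group)
  structure(list(subjects = subjects[order(subjects$subject_id, subjects$roi,
                                           subjects$marker), ],
                 groups = groups[ord, ], excluded = excluded,
                 n_window = n_window),
            class = "prepost_summary")
}

#' Six-point marker time courses
#'
#' Partitions each subject's session, in acquisition order, into consecutive
#' triples of scans and averages them, yielding six time points at 15-minute
#' resolution; time stamps are the mean acquisition time of each triple.
#'
#' @param table ROI marker table.
#' @param scans_per_point scans averaged per time point (default 3).
#' @param drop_partial if `TRUE`, trailing scans that do not complete a
#'   triple are dropped with a warning instead of raising an error.
#' @return data frame of class `marker_timecourse`: one row per (subject,
#'   roi, marker, point) with `time_min` and `value`.
#' @export
build_timecourse <- function(table, scans_per_point = 3L, drop_partial = FALSE) {
  long <- roi_table_long(table)
  rows <- lapply(split(long, list(long$subject_id, long$roi, long$marker),
                       drop = TRUE), function(key) {
    key <- key[order(key$scan_index), ]
    n <- nrow(key)
    rem <- n %% scans_per_point
    if (rem != 0) {
      if (!drop_partial)
        stop_validation(sprintf(
          "subject '%s': %d scans is not a multiple of %d (set drop_partial = TRUE to truncate)",
          key$subject_id[1], n, scans_per_point))
      warning(sprintf("build_timecourse: dropping %d trailing scan(s) for subject '%s'",
                      rem, key$subject_id[1]))
      key <- key[seq_len(n - rem), ]
    }
    np <- nrow(key) %/% scans_per_point
    vals <- colMeans(matrix(key$value, scans_per_point, np))
    tmin <- colMeans(matrix(key$acquisition_time, scans_per_point, np))
    data.frame(subject_id = key$subject_id[1], group = key$group[1],
               roi = key$roi[1], marker = key$marker[1],
               point = seq_len(np), time_min = tmin, value = vals,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$subject_id, out$roi, out$marker, out$point), ]
  class(out) <- c("marker_timecourse", "data.frame")
  out
}

#' Z-score outlier filter
#'
#' Single-pass filter over one group's values at one time point: |z| is
#' computed against the sample mean and sd (candidate included) and values
#' with |z| > `z_cutoff` are excluded. With zero sd the z-score is treated
#' as 0 (no exclusions); with fewer than 3 values the filter is skipped with
#' a warning.
#'
#' @param values numeric vector (one subject each).
#' @param z_cutoff exclusion threshold (default 3).
#' @return list with `values` (kept), `excluded` (logical flags, same length
#'   as input).
#' @export
exclude_outliers <- function(values, z_cutoff = 3) {
  assert_scalar_number(z_cutoff, "z_cutoff", positive = TRUE)
  if (length(values) < 3L) {
    if (length(values) == 2L)
      warning("exclude_outliers: fewer than 3 values, filter skipped")
    return(list(values = values, excluded = rep(FALSE, length(values))))
  }
  s <- stats::sd(values)
  z <- if (is.na(s) || s == 0) rep(0, length(values)) else (values - mean(values)) / s
  excl <- abs(z) > z_cutoff
  list(values = values[!excl], excluded = excl)
}

#' Group statistics for a pre/post summary and time course
#'
#' Produces (a) the paired pre-vs-post two-sided t-tests per group, ROI and
#' marker; (b) between-group Welch tests on the pre and the post window
#' means, with a step-down multiplicity correction applied within each
#' marker's comparison family (all ROI x window comparisons of that
#' marker); and (c) per-time-point between-group Welch tests, uncorrected,
#' after z-score outlier exclusion within each group at each time point.
#'
#' @param summary a [prepost_average()] result.
#' @param course a [build_timecourse()] result.
#' @param posthoc multiplicity method for the between-group family, any
#'   method of [stats::p.adjust()] (default `"holm"`).
#' @param z_cutoff outlier threshold for the time-point tests.
#' @return object of class `stats_report`: `paired`, `between`, `timepoint`
#'   data frames, plus the method names used.
#' @export
run_stats <- function(summary, course, posthoc = "holm", z_cutoff = 3) {
  if (!inherits(summary, "prepost_summary"))
    stop_validation("'summary' must be a prepost_summary")
  if (!posthoc %in% stats::p.adjust.methods)
    stop_validation(sprintf("unknown posthoc method '%s'", posthoc))

  paired <- summary$groups

  subj <- summary$subjects
  between <- list()
  for (key in split(subj, list(subj$roi, subj$marker), drop = TRUE)) {
    for (win in c("pre", "post")) {
      x <- key[[win]][key$group == "vehicle"]
      y <- key[[win]][key$group == "tgn020"]
      between[[length(between) + 1L]] <- data.frame(
        roi = key$roi[1], marker = key$marker[1], window = win,
        n_vehicle = length(x), n_tgn020 = length(y),
        p = welch_p(x, y), stringsAsFactors = FALSE)
    }
  }
  between <- do.call(rbind, between)
  between$p_adj <- NA_real_
  for (m in unique(between$marker)) {
    i <- between$marker == m
    between$p_adj[i] <- stats::p.adjust(between$p[i], method = posthoc)
  }

  tp <- list()
  for (key in split(course, list(course$roi, course$marker, course$point),
                    drop = TRUE)) {
    vals <- list()
    n_excl <- 0L
    for (g in c("vehicle", "tgn020")) {
      v <- key$value[key$group == g]
      f <- exclude_outliers(v[is.finite(v)], z_cutoff)
      vals[[g]] <- f$values
      n_excl <- n_excl + sum(f$excluded)
    }
    tp[[length(tp) + 1L]] <- data.frame(
      roi = key$roi[1], marker = key$marker[1], point = key$point[1],
      time_min = key$time_min[1],
      n_vehicle = length(vals$vehicle), n_tgn020 = length(vals$tgn020),
      n_excluded = n_excl,
      p = welch_p(vals$vehicle, vals$tgn020), stringsAsFactors = FALSE)
  }
  timepoint <- do.call(rbind, tp)
  timepoint <- timepoint[order(timepoint$marker, timepoint$roi, timepoint$point), ]
  rownames(timepoint) <- NULL

  structure(list(paired = paired, between = between, timepoint = timepoint,
                 posthoc = posthoc, z_cutoff = z_cutoff,
                 excluded_subjects = summary$excluded),
            class = "stats_report")
}

#' Plot group time courses
#'
#' Group mean with +-1 sd error bars for one ROI and marker, vehicle in
#' blue and TGN-020 in orange; the dashed vertical line marks the
#' injection.
#'
#' @param course a [build_timecourse()] result.
#' @param roi,marker which curve to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot_timecourse <- function(course, roi, marker, ...) {
  key <- course[course$roi == roi & course$marker == marker, ]
  if (nrow(key) == 0L) stop_validation("no rows for the requested roi/marker")
  agg <- stats::aggregate(value ~ group + time_min, key,
                          function(v) c(m = mean(v), s = stats::sd(v)))
  agg <- cbind(agg[c("group", "time_min")], as.data.frame(agg$value))
  cols <- c(vehicle = "#4477CC", tgn020 = "#EE7722")
  ylim <- range(agg$m - agg$s, agg$m + agg$s, na.rm = TRUE)
  graphics::plot(NA, xlim = range(agg$time_min), ylim = ylim,
                 xlab = "time relative to injection (min)", ylab = marker,
                 main = roi, ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  for (g in names(cols)) {
    a <- agg[agg$group == g, ]
    a <- a[order(a$time_min), ]
    graphics::lines(a$time_min, a$m, col = cols[[g]], lwd = 2)
    graphics::points(a$time_min, a$m, col = cols[[g]], pch = 16)
    graphics::arrows(a$time_min, a$m - a$s, a$time_min, a$m + a$s,
                     angle = 90, code = 3, length = 0.03, col = cols[[g]])
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(agg)
}
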