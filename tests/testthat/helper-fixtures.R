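# Shared fixtures, all generated in code.

# Small, fast phantom for unit tests.
tiny_spec <- function(seed = 1, ...) {
  phantom_spec(seed = seed, grid = c(16L, 16L, 4L), ...)
}

# A scan with one constant value per shell (b0, Lb, Hb) at every voxel.
uniform_series <- function(v0, v_lb, v_hb, grid = c(4L, 4L, 2L),
                           scheme = default_scheme(), ...) {
  shell_val <- c(v0, v_lb, v_hb)
  arr <- array(0, c(grid, scheme$n_volumes))
  for (j in seq_len(scheme$n_volumes)) {
    arr[, , , j] <- shell_val[scheme$shell_of[j]]
  }
  dwi_series(arr, scheme, ...)
}

# ROI marker table for hand-built per-scan values: `value_fun(subject,
# scan_index)` gives the marker value used for both sadc and sindex columns
# unless separate functions are supplied.
toy_roi_table <- function(subjects, groups, n_scans = 18L, roi = "cortex",
                          sindex_fun = function(s, i) 50,
                          sadc_fun = function(s, i) 7e-4) {
  rows <- list()
  for (j in seq_along(subjects)) {
    for (i in seq_len(n_scans)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects[j], group = groups[j], scan_index = i,
        acquisition_time = 5 * (i - 1) - 30, roi = roi, n_voxels = 10L,
        s_lb = 0.85, s_hb = 0.33,
        sadc = sadc_fun(subjects[j], i), sindex = sindex_fun(subjects[j], i),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Brute-force two-stage grid-search oracle for the two-point kurtosis fit:
# minimises the squared signal error over (d, k), zooming in iteratively.
grid_search_fit <- function(s_lb, s_hb, lb, hb,
                            d_range = c(1e-4, 2e-3), k_range = c(-2.5, 2.5),
                            n = 101L, zooms = 5L) {
  for (it in seq_len(zooms)) {
    ds <- seq(d_range[1], d_range[2], length.out = n)
    ks <- seq(k_range[1], k_range[2], length.out = n)
    err <- outer(ds, ks, function(d, k) {
      (exp(-lb * d + (lb * d)^2 * k / 6) - s_lb)^2 +
        (exp(-hb * d + (hb * d)^2 * k / 6) - s_hb)^2
    })
    i <- arrayInd(which.min(err), dim(err))
    dw <- diff(d_range) / (n - 1); kw <- diff(k_range) / (n - 1)
    d_best <- ds[i[1]]; k_best <- ks[i[2]]
    d_range <- c(d_best - 2 * dw, d_best + 2 * dw)
    k_range <- c(k_best - 2 * kw, k_best + 2 * kw)
  }
  list(d = d_best, k = k_best)
}
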