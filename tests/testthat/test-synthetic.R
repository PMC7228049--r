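# The phantom cohort generator: atlas, signal model, effect, noise, seeds.

test_that("the atlas orders ROI sizes and is deterministic", {
  atlas <- make_atlas(c(32L, 32L, 8L))
  counts <- vapply(c("DG", "CA3", "hippocampus", "striatum", "cortex"),
                   function(r) sum(atlas$labels == atlas$dictionary[[r]]), 1L)
  # hierarchical hippocampus count (proper + subregions)
  counts["hippocampus"] <- sum(roi_mask(atlas, "hippocampus"))
  expect_true(all(diff(counts) > 0))
  expect_identical(make_atlas(c(32L, 32L, 8L))$labels, atlas$labels)
  # subregions sit inside the hippocampus
  hip <- roi_mask(atlas, "hippocampus")
  expect_true(all(hip[atlas$labels %in% c(4L, 5L)]))
})

test_that("infeasibly small grids are rejected", {
  expect_error(make_atlas(c(4L, 4L, 1L)), class = "dwimarkers_geometry_error")
})

test_that("noiseless vehicle scans reproduce the baseline signals", {
  spec <- tiny_spec(seed = 8, snr = Inf, noise = "none")
  atlas <- make_atlas(spec)
  sub <- simulate_subject(spec, "vehicle", 3, "v1", atlas)
  lib <- spec$library
  for (scan in sub$series[c(1, 9, 18)]) {
    sh <- normalize_and_average(scan)
    m <- atlas$labels == 1L  # cortex baseline is the signature-B fit
    expect_equal(unique(as.vector(sh$s_lb[m])), lib$s_b_lb, tolerance = 1e-10)
    expect_equal(unique(as.vector(sh$s_hb[m])), lib$s_b_hb, tolerance = 1e-10)
  }
})

test_that("the noiseless active-group plateau matches the shifted model", {
  spec <- tiny_spec(seed = 8, snr = Inf, noise = "none")
  atlas <- make_atlas(spec)
  sub <- simulate_subject(spec, "tgn020", 3, "t1", atlas)
  lib <- spec$library
  sh_pre <- normalize_and_average(sub$series[[1]])
  sh_plateau <- normalize_and_average(sub$series[[18]])
  base <- spec$baseline$cortex
  shifted <- kurtosis_params(base$d + spec$effect_plateau[["dd"]],
                             base$k + spec$effect_plateau[["dk"]])
  row <- roi_markers(sh_plateau, atlas, "cortex", lib)
  expected <- sindex(kurtosis_signal(shifted, lib$lb),
                     kurtosis_signal(shifted, lib$hb), lib)
  expect_equal(row$sindex, expected, tolerance = 1e-9)
  row_pre <- roi_markers(sh_pre, atlas, "cortex", lib)
  expect_lt(row$sindex, row_pre$sindex)
  # striatum carries no effect
  st_pre <- roi_markers(sh_pre, atlas, "striatum", lib)
  st_post <- roi_markers(sh_plateau, atlas, "striatum", lib)
  expect_equal(st_post$sindex, st_pre$sindex, tolerance = 1e-10)
})

test_that("identical seeds reproduce identical data", {
  spec <- tiny_spec(seed = 12)
  a <- simulate_subject(spec, "tgn020", 55, "t1")
  b <- simulate_subject(spec, "tgn020", 55, "t1")
  expect_identical(a$series[[7]]$intensities, b$series[[7]]$intensities)
  ca <- simulate_cohort(spec, n_per_group = 2)
  cb <- simulate_cohort(spec, n_per_group = 2)
  expect_identical(ca$manifest, cb$manifest)
  expect_identical(ca$subjects$veh02$series[[3]]$intensities,
                   cb$subjects$veh02$series[[3]]$intensities)
})

test_that("cohort layout matches the study arithmetic", {
  spec <- tiny_spec(seed = 14)
  co <- simulate_cohort(spec, n_per_group = 2)
  expect_equal(nrow(co$manifest), 2 * 2 * 18)
  expect_equal(sort(unique(co$manifest$group)), c("tgn020", "vehicle"))
  expect_equal(sum(co$manifest$time_min < 0), 4 * 6)
  # n = 1 per group still yields valid data
  co1 <- simulate_cohort(spec, n_per_group = 1)
  expect_equal(nrow(co1$manifest), 36L)
})

test_that("Rician bias at SNR 40 is below half a percent on b0", {
  spec <- phantom_spec(seed = 15, snr = 40)
  sub <- simulate_subject(spec, "vehicle", 61, "v1")
  # pool the b0 volumes of two scans: > 10^4 voxels
  vals <- c(sub$series[[1]]$intensities[, , , 1],
            sub$series[[2]]$intensities[, , , 1])
  expect_gt(length(vals), 1e4)
  expect_lt(abs(mean(vals) - spec$s0) / spec$s0, 0.005)
})

test_that("calibration hits the requested noiseless Sindex change", {
  spec <- tiny_spec(seed = 16)
  cal0 <- calibrate_effect(0, spec)
  expect_equal(unname(cal0$plateau), c(0, 0))
  cal <- calibrate_effect(-9, spec)
  expect_equal(cal$achieved_pct, -9, tolerance = 0.1)
  # forward verification through an actual noiseless simulation
  spec_nl <- tiny_spec(seed = 16, snr = Inf, noise = "none")
  atlas <- make_atlas(spec_nl)
  sub <- simulate_subject(spec_nl, "tgn020", 9, "t1", atlas)
  pre <- roi_markers(normalize_and_average(sub$series[[1]]), atlas, "cortex")
  post <- roi_markers(normalize_and_average(sub$series[[18]]), atlas, "cortex")
  expect_equal(100 * (post$sindex - pre$sindex) / pre$sindex, -9,
               tolerance = 0.1)
  expect_error(calibrate_effect(-200, spec),
               class = "dwimarkers_calibration_error")
})

test_that("a zero-effect noiseless cohort is flat and silent end to end", {
  spec <- tiny_spec(seed = 17, snr = Inf, noise = "none",
                    target_pct_sindex = 0)
  res <- simulate_and_analyze(spec, n_per_group = 3, master_seed = 5)
  tc <- res$course
  for (key in split(tc, list(tc$subject_id, tc$roi, tc$marker), drop = TRUE)) {
    expect_equal(diff(range(key$value)), 0, tolerance = 1e-12)
  }
  expect_true(all(res$prepost$groups$p_paired == 1))
  expect_true(all(res$stats$timepoint$p == 1))
})

test_that("the effect ramp reaches plateau after three post scans", {
  expect_equal(dwimarkers:::effect_fraction(1:18, 6, 3),
               c(rep(0, 6), 1/3, 2/3, rep(1, 10)))
})
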