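# The sADC and Sindex markers, voxelwise and at ROI level.

test_that("sadc has the closed form and its algebraic identities", {
  expect_equal(sadc(0.7, 0.7), 0)
  # frozen from a 30-digit arbitrary-precision evaluation of
  # ln(0.855/0.317)/1500
  expect_equal(sadc(0.855, 0.317), 6.61466463372986e-4, tolerance = 1e-12)
  # halving the high-b signal adds ln(2)/(hb - lb)
  expect_equal(sadc(0.855, 0.317 / 2) - sadc(0.855, 0.317), log(2) / 1500,
               tolerance = 1e-15)
  # exact inversion of an imposed decay rate, for any scale
  for (s in c(0.2, 0.9, 5)) {
    expect_equal(sadc(s, s * exp(-8e-4 * 1500)), 8e-4, tolerance = 1e-15)
  }
  expect_true(is.na(sadc(0, 0.3)))
  expect_true(is.na(sadc(0.8, -1)))
})

test_that("sindex maps the reference signatures to 75, 25 and 50", {
  lib <- default_signature_library()
  expect_equal(sindex(0.858, 0.370, lib), 75, tolerance = 1e-9)
  expect_equal(sindex(0.855, 0.317, lib), 25, tolerance = 1e-9)
  expect_equal(sindex(lib$s_n_lb, lib$s_n_hb, lib), 50, tolerance = 1e-9)
  expect_true(is.na(sindex(-0.1, 0.3, lib)))
})

test_that("sindex rises and sadc falls with kurtosis along the model family", {
  lib <- default_signature_library()
  for (d in c(5e-4, 6.2e-4, 8e-4)) {
    ks <- seq(-0.6, 1.2, by = 0.2)
    s <- vapply(ks, function(k) {
      p <- kurtosis_params(d, k)
      c(sindex(kurtosis_signal(p, 250), kurtosis_signal(p, 1750), lib),
        sadc(kurtosis_signal(p, 250), kurtosis_signal(p, 1750)))
    }, numeric(2))
    expect_true(all(diff(s[1, ]) > 0))  # sindex strictly increasing in k
    expect_true(all(diff(s[2, ]) < 0))  # sadc strictly decreasing in k
  }
})

test_that("sindex is not invariant under scaling the voxel signal alone", {
  lib <- default_signature_library()
  expect_false(isTRUE(all.equal(sindex(0.858 * 1.1, 0.370 * 1.1, lib),
                                sindex(0.858, 0.370, lib))))
})

test_that("marker maps equal the voxelwise scalar operations", {
  spec <- tiny_spec(seed = 6, snr = 20)
  sub <- simulate_subject(spec, "vehicle", 17, "v1")
  sh <- normalize_and_average(sub$series[[1]])
  lib <- default_signature_library()
  mm <- marker_maps(sh, lib)
  # brute-force per-voxel loop oracle on a sample of voxels
  idx <- seq(1, prod(spec$grid), by = 37)
  for (i in idx) {
    if (!sh$mask[i]) next
    expect_equal(mm$sadc[i], sadc(sh$s_lb[i], sh$s_hb[i], 250, 1750))
    expect_equal(mm$sindex[i], sindex(sh$s_lb[i], sh$s_hb[i], lib))
  }
})

test_that("uniform signature-B phantoms give constant marker maps", {
  scan <- uniform_series(1000, 855, 317)
  mm <- marker_maps(normalize_and_average(scan))
  expect_equal(unique(as.vector(mm$sindex)), 25, tolerance = 1e-9)
  expect_equal(unique(as.vector(mm$sadc)), 6.61466463372986e-4,
               tolerance = 1e-12)
})

test_that("fully masked input yields fully masked output", {
  scan <- uniform_series(0, 0, 0)
  expect_warning(sh <- normalize_and_average(scan), "masked")
  mm <- marker_maps(sh)
  expect_false(any(mm$mask))
  expect_true(all(is.na(mm$sadc)))
})

test_that("ROI markers average signals before computing markers", {
  grid <- c(2L, 1L, 1L)
  scan <- uniform_series(1000, 858, 370, grid = grid)
  scan$intensities[2, 1, 1, 2:7] <- 855
  scan$intensities[2, 1, 1, 8:13] <- 317
  sh <- normalize_and_average(scan)
  labels <- label_volume(array(1L, grid), c(cortex = 1L), hierarchy = c())
  lib <- default_signature_library()
  row <- roi_markers(sh, labels, "cortex", lib)
  m_lb <- mean(c(0.858, 0.855)); m_hb <- mean(c(0.370, 0.317))
  expect_equal(row$sindex, sindex(m_lb, m_hb, lib))
  expect_equal(row$sadc, sadc(m_lb, m_hb))
  # sADC is nonlinear in the signals, so the averaging order matters
  vox_mean <- roi_markers(sh, labels, "cortex", lib, voxel_mean = TRUE)
  expect_equal(vox_mean$sadc, mean(sadc(c(0.858, 0.855), c(0.370, 0.317))))
  expect_false(isTRUE(all.equal(row$sadc, vox_mean$sadc)))
  # (with the symmetric mean S_N rule the scaled index is linear in the
  # signals, so its two conventions coincide there by construction)
  expect_equal(vox_mean$sindex, mean(c(75, 25)), tolerance = 1e-9)
})

test_that("uniform ROIs reproduce the voxel value and empty ROIs error", {
  grid <- c(2L, 2L, 1L)
  scan <- uniform_series(1000, 855, 317, grid = grid)
  sh <- normalize_and_average(scan)
  labels <- label_volume(array(c(1L, 1L, 0L, 2L), grid),
                         c(cortex = 1L, striatum = 2L), hierarchy = c())
  row <- roi_markers(sh, labels, "cortex")
  expect_equal(row$n_voxels, 2L)
  expect_equal(row$sindex, 25, tolerance = 1e-9)

  # all voxels of an ROI masked: typed error
  scan2 <- uniform_series(1000, 855, 317, grid = grid)
  scan2$intensities[2, 2, 1, ] <- 0
  sh2 <- normalize_and_average(scan2)
  expect_error(roi_markers(sh2, labels, "striatum"),
               class = "dwimarkers_empty_roi_error")
})

test_that("marker maps write to NIfTI and preserve values", {
  scan <- uniform_series(1000, 855, 317)
  mm <- marker_maps(normalize_and_average(scan))
  d <- file.path(tempdir(), "mapout")
  paths <- write_marker_map(mm, d, prefix = "t")
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[["sindex"]])
  expect_equal(as.vector(back), as.vector(mm$sindex), tolerance = 1e-12)
})
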