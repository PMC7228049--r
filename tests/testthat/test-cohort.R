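# Pre/post aggregation, time courses, outlier filtering and group tests.

test_that("constant sessions give pre = post and zero change", {
  tab <- toy_roi_table(c("v1", "v2", "t1", "t2"),
                       c("vehicle", "vehicle", "tgn020", "tgn020"),
                       sindex_fun = function(s, i) 48)
  pp <- prepost_average(tab)
  si <- pp$subjects[pp$subjects$marker == "sindex", ]
  expect_true(all(si$pre == 48 & si$post == 48))
  expect_true(all(pp$groups$mean_change == 0))
  expect_true(all(pp$groups$pct_change == 0))
  # zero paired differences: no evidence of change
  expect_true(all(pp$groups$p_paired[pp$groups$marker == "sindex"] == 1))
})

test_that("pre uses the negative-time scans and post the final six", {
  # scans 1..18 valued by scan index: pre mean = mean(1:6), post = mean(13:18)
  tab <- toy_roi_table("s1", "vehicle", sindex_fun = function(s, i) i)
  pp <- suppressWarnings(prepost_average(tab))
  r <- pp$subjects[pp$subjects$marker == "sindex", ]
  expect_equal(r$pre, mean(1:6))
  expect_equal(r$post, mean(13:18))
})

test_that("row order of the marker table does not affect the outputs", {
  set.seed(42)
  tab <- toy_roi_table(c("v1", "v2", "v3", "t1", "t2", "t3"),
                       rep(c("vehicle", "tgn020"), each = 3),
                       sindex_fun = function(s, i) 50 + stats::rnorm(1))
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(prepost_average(shuf)$groups, prepost_average(tab)$groups)
  expect_equal(build_timecourse(shuf), build_timecourse(tab))
})

test_that("subjects with incomplete windows are excluded with a warning", {
  tab <- toy_roi_table(c("s1", "s2"), c("vehicle", "vehicle"))
  tab <- tab[!(tab$subject_id == "s2" & tab$scan_index > 10), ]
  expect_warning(pp <- prepost_average(tab), "incomplete")
  expect_identical(pp$excluded, "s2")
  expect_false("s2" %in% pp$subjects$subject_id)
})

test_that("single-subject groups are reported as not computable, no crash", {
  tab <- toy_roi_table("t1", "tgn020", sindex_fun = function(s, i) i)
  pp <- prepost_average(tab)
  expect_true(all(is.na(pp$groups$p_paired)))
})

test_that("time courses are consecutive triple means with centred stamps", {
  tab <- toy_roi_table("s1", "vehicle", sindex_fun = function(s, i) i,
                       sadc_fun = function(s, i) i)
  tc <- build_timecourse(tab)
  r <- tc[tc$marker == "sindex", ]
  expect_equal(r$value, c(2, 5, 8, 11, 14, 17))
  # 5-minute scans starting at -30 min: triple centres at these times
  expect_equal(r$time_min, c(-25, -10, 5, 20, 35, 50))
  # constant sessions give constant courses
  tabc <- toy_roi_table("s1", "vehicle")
  tcc <- build_timecourse(tabc)
  expect_true(all(tcc$value[tcc$marker == "sindex"] == 50))
})

test_that("scan counts that do not fill triples error unless dropped", {
  tab <- toy_roi_table("s1", "vehicle")
  tab <- tab[tab$scan_index <= 17, ]
  expect_error(build_timecourse(tab), class = "dwimarkers_validation_error")
  w <- capture_warnings(tc <- build_timecourse(tab, drop_partial = TRUE))
  expect_match(w, "dropping", all = TRUE)
  expect_equal(max(tc$point), 5L)
})

test_that("the z-score filter excludes constructed extremes only", {
  # 15 values at 50 plus jitter, one gross outlier: |z| > 3 by construction
  base <- 50 + c(-7:7) * 0.1
  x <- c(base, 80)
  f <- exclude_outliers(x, 3)
  expect_equal(sum(f$excluded), 1L)
  expect_true(f$excluded[16])
  # identical values: zero sd, no exclusions
  f2 <- exclude_outliers(rep(5, 10))
  expect_equal(sum(f2$excluded), 0L)
  # n = 2: filter skipped with a warning
  expect_warning(f3 <- exclude_outliers(c(1, 100)), "skipped")
  expect_equal(sum(f3$excluded), 0L)
})

test_that("excluding an outlier moves the group mean toward the centre", {
  set.seed(7)
  for (i in 1:20) {
    x <- stats::rnorm(12)
    x[1] <- x[1] + sample(c(-1, 1), 1) * 25
    f <- exclude_outliers(x, 3)
    if (sum(f$excluded) == 0) next
    med <- stats::median(f$values)
    expect_lte(abs(mean(f$values) - med), abs(mean(x) - med))
  }
})

test_that("identical groups yield p near 1 and Holm with m = 1 is identity", {
  tab <- toy_roi_table(c("v1", "v2", "v3", "t1", "t2", "t3"),
                       rep(c("vehicle", "tgn020"), each = 3))
  pp <- prepost_average(tab)
  st <- run_stats(pp, build_timecourse(tab))
  expect_true(all(st$between$p == 1))
  expect_true(all(st$timepoint$p == 1))
  # corrected p never below raw p
  expect_true(all(st$between$p_adj >= st$between$p))
})

test_that("an injected group effect is detected by the stats report", {
  set.seed(11)
  subjects <- c(sprintf("v%d", 1:8), sprintf("t%d", 1:8))
  groups <- rep(c("vehicle", "tgn020"), each = 8)
  tab <- toy_roi_table(subjects, groups,
                       sindex_fun = function(s, i) {
                         drop <- if (grepl("^t", s) && i > 6) -5 else 0
                         50 + drop + stats::rnorm(1, sd = 0.5)
                       })
  pp <- prepost_average(tab)
  st <- run_stats(pp, build_timecourse(tab))
  p_tgn <- pp$groups$p_paired[pp$groups$group == "tgn020" &
                                pp$groups$marker == "sindex"]
  p_veh <- pp$groups$p_paired[pp$groups$group == "vehicle" &
                                pp$groups$marker == "sindex"]
  expect_lt(p_tgn, 0.05)
  expect_gt(p_veh, 0.05)
  post_p <- st$between$p_adj[st$between$marker == "sindex" &
                               st$between$window == "post"]
  expect_lt(post_p, 0.05)
})
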