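test_that("group summary reproduces the study's exponential group rows", {
  ind <- study_individuals_exponential()
  gs <- group_summary(ind)
  expect_equal(attr(gs, "n_subjects"), 27)
  expect_lt(abs(gs["mean", "A"] - 27.76), 0.01)
  expect_lt(abs(gs["mean", "b"] - 0.01805), 5e-5)
  expect_lt(abs(gs["mean", "C"] - 0.49), 0.01)
  expect_lt(abs(gs["mean", "f_tmin"] - 26.49), 0.01)
  expect_lt(abs(gs["mean", "f_tmax"] - 1.99), 0.01)
  expect_lt(abs(gs["mean", "T"] - 85), 1)
  expect_lt(abs(gs["sd", "T"] - 62), 1)
  expect_lt(abs(gs["median", "A"] - 22.39), 0.05)
  expect_lt(abs(gs["sd", "A"] - 15.18), 0.02)
  expect_lt(abs(gs["sd", "C"] - 6.10), 0.01)
})

test_that("group summary degenerate and error cases", {
  ind <- study_individuals_exponential()
  same <- ind[rep(1, 5), ]
  same$subject_id <- paste0("s", 1:5)
  gs <- group_summary(same)
  expect_equal(gs["sd", "A"], 0)
  expect_equal(gs["mean", "A"], gs["median", "A"])
  dup <- ind[c(1, 1), ]
  expect_error(group_summary(dup), "duplicate subjects")
})

test_that("model contest reproduces the study's RMS comparison", {
  ct <- contest_from_rms(study_rms())
  expect_equal(ct$n_runs_total, 44)
  expect_equal(ct$n_runs_power_wins, 4)
  expect_lt(abs(ct$mean_rms[["exponential"]] - 2.416), 5e-4)
  expect_lt(abs(ct$mean_rms[["power"]] - 3.160), 5e-4)
  expect_lt(abs(ct$percent_excess - 31), 1)
  expect_equal(ct$paired_t$df, 26)
  expect_lt(ct$paired_t$p.value, 1e-4)
  expect_lt(abs(stats::median(ct$individuals$rms_exponential) - 2.136), 5e-4)
  expect_lt(abs(stats::median(ct$individuals$rms_power) - 3.074), 5e-4)
})

test_that("contest handles identical RMS columns", {
  runs <- study_rms()
  runs$rms_power <- runs$rms_exponential
  ct <- contest_from_rms(runs)
  expect_equal(ct$n_runs_power_wins, 0)
  expect_equal(ct$percent_excess, 0)
  expect_true(is.na(ct$paired_t$statistic))
  expect_equal(ct$paired_t$p.value, 1)
})

test_that("binned pooling conserves settings and has the right structure", {
  coh <- sample_cohort(cohort_config(seed = 5))
  total <- sum(vapply(coh$series, function(s) length(s$t), numeric(1)))
  for (k in c(15, 5)) {
    pb <- pool_binned(coh$series, k)
    expect_equal(sum(pb$points$n_settings), total)
    expect_equal(nrow(pb$points), k)  # every bin populated under the schedule
    expect_true(all(diff(pb$points$t) > 0))
    expect_s3_class(pb$fits$exponential, "decay_fit")
    expect_s3_class(pb$fits$power, "decay_fit")
  }
  ap <- pool_all_points(coh$series)
  expect_equal(nrow(ap$points), total)
})

test_that("a group of one pools to its own bin means", {
  s <- make_series(30, 0.01, 1, n = 20, noise_sd = 1, seed = 3)
  pb <- pool_binned(list(s), 5)
  breaks <- seq(0, 360, length.out = 6)
  bins <- cut(s$t, breaks, include.lowest = TRUE, labels = FALSE)
  own_t <- tapply(s$t, bins, mean)
  own_y <- tapply(s$svh, bins, mean)
  expect_equal(pb$points$t, as.vector(own_t))
  expect_equal(pb$points$svh, as.vector(own_y))
})

test_that("pooling refuses too-sparse input", {
  s <- setting_series("a", 1, c(100, 200, 300), c(3, 2, 1))
  expect_error(pool_binned(list(s), 2), "fewer than 4")
})

test_that("homogeneous noiseless cohorts leave the exponential unbeaten everywhere", {
  cfg <- cohort_config(n_subjects = 8, n_two_run = 0, A_sd = 0, b_sd = 0,
                       C_sd = 0, noise_mean = 0, noise_sd = 0, noise_floor = 0,
                       seed = 31)
  coh <- sample_cohort(cfg)
  fits <- fit_cohort(coh$series, "exponential")
  expect_true(all(vapply(fits, `[[`, numeric(1), "rms") < 1e-7))
  pb <- pool_binned(coh$series, 15)
  ap <- pool_all_points(coh$series)
  # binned group means carry a small Jensen bias (within-bin time averaging
  # of a convex curve), bounded well below the setting-noise scale
  expect_lt(pb$fits$exponential$rms, 0.05)
  expect_lt(ap$fits$exponential$rms, 1e-6)
  expect_gt(ap$rms_gap_ratio, 1)  # power cannot match a pure exponential cloud
})

test_that("discriminability criteria flag sparse runs and pass conformant ones", {
  short <- setting_series("s", 1, c(4, 100, 360), c(10, 5, 1))
  rep3 <- discriminability_check(list(short))
  expect_false(rep3$crit1)
  expect_false(rep3$crit6)
  expect_equal(rep3$time_ratio, 90)
  expect_true(rep3$crit3)
  coh <- sample_cohort(cohort_config(seed = 8))
  rep_all <- discriminability_check(coh$series)
  expect_true(all(rep_all$crit1))
  expect_true(all(rep_all$crit6))
  expect_true(all(rep_all$n_settings >= 14))
  # change-to-noise ratio appears when RMS errors are supplied
  fits <- fit_cohort(coh$series[1:2], "exponential")
  rep2 <- discriminability_check(coh$series[1:2],
                                 rms = vapply(fits, `[[`, numeric(1), "rms"))
  expect_true(all(is.finite(rep2$change_to_rms)))
})
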