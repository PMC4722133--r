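test_that("SSE is an equal-weight sum of squared residuals", {
  # series lying exactly on the generating curve
  p <- decay_params("exponential", A = 25, b = 0.02, C = 1)
  s <- make_series(25, 0.02, 1, n = 12)
  expect_equal(decay_sse(p, s), 0)
  # constant series against the flat model
  flat <- setting_series("c", 1, c(5, 10, 20, 40), rep(3.5, 4))
  expect_equal(decay_sse(decay_params("exponential", A = 0, b = 1, C = 3.5), flat), 0)
  # five-point hand series: term-by-term arithmetic
  tt <- c(5, 30, 90, 180, 300)
  y <- c(20.1, 14.2, 7.9, 3.3, 1.6)
  h <- decay_params("exponential", A = 22, b = 0.012, C = 0.8)
  m <- 22 * exp(-0.012 * tt) + 0.8
  expected <- (y[1] - m[1])^2 + (y[2] - m[2])^2 + (y[3] - m[3])^2 +
    (y[4] - m[4])^2 + (y[5] - m[5])^2
  expect_equal(decay_sse(h, setting_series("h", 1, tt, y)), expected)
})

test_that("noiseless series are recovered to high precision", {
  s <- make_series(30, 0.01, 2, n = 20)
  f <- fit_decay(s, "exponential")
  expect_equal(f$params$A, 30, tolerance = 1e-6)
  expect_equal(f$params$b, 0.01, tolerance = 1e-6)
  expect_equal(f$params$C, 2, tolerance = 1e-6)
  expect_lt(f$rms, 1e-8)
  expect_true(f$converged)
  sp <- make_series(22.4, 0.4738, 0.7, n = 20, family = "power")
  fp <- fit_decay(sp, "power")
  expect_equal(fp$params$b, 0.4738, tolerance = 1e-6)
  expect_lt(fp$rms, 1e-8)
})

test_that("multistart fit matches the independent grid oracle", {
  for (seed in 1:10) {
    s <- make_series(A = 20 + seed, b = 0.004 * seed, C = seed - 5,
                     n = 18, noise_sd = 2.5, seed = seed)
    for (fam in c("exponential", "power")) {
      f <- fit_decay(s, fam)
      oracle <- grid_oracle_sse(s$t, s$svh, fam)
      expect_lt(abs(f$sse - oracle) / oracle, 1e-6)
    }
  }
})

test_that("fit is optimal against an independent local optimizer", {
  # Levenberg-Marquardt from several starts never beats the multistart SSE
  s <- make_series(28, 0.015, 1.5, n = 22, noise_sd = 2, seed = 99)
  f <- fit_decay(s, "exponential")
  dat <- data.frame(t = s$t, y = s$svh)
  for (b0 in c(0.001, 0.01, 0.1)) {
    lm_fit <- try(minpack.lm::nlsLM(y ~ A * exp(-b * t) + C, dat,
                                    start = list(A = 25, b = b0, C = 0)),
                  silent = TRUE)
    if (!inherits(lm_fit, "try-error"))
      expect_gte(sum(stats::resid(lm_fit)^2), f$sse - 1e-8)
  }
})

test_that("fitted SSE never exceeds any start's profile value and more starts never hurt", {
  s <- make_series(35, 0.03, -2, n = 20, noise_sd = 3, seed = 4)
  f64 <- fit_decay(s, "exponential", multistart_config(n_starts = 64))
  starts <- exp(seq(log(1e-4), log(2), length.out = 64))
  prof <- vapply(starts, function(b) {
    g <- exp(-b * s$t)
    sum(stats::lm.fit(cbind(g, 1), s$svh)$residuals^2)
  }, numeric(1))
  expect_lte(f64$sse, min(prof) + 1e-10)
  f128 <- fit_decay(s, "exponential", multistart_config(n_starts = 128))
  expect_lte(f128$sse, f64$sse * (1 + 1e-9))
})

test_that("fit is scale-equivariant and time-shift-covariant", {
  s <- make_series(24, 0.012, 3, n = 20, noise_sd = 1.5, seed = 7)
  f <- fit_decay(s, "exponential")
  k <- 3.7
  fk <- fit_decay(setting_series("x", 1, s$t, k * s$svh), "exponential")
  expect_equal(fk$params$A, k * f$params$A, tolerance = 1e-7)
  expect_equal(fk$params$C, k * f$params$C, tolerance = 1e-6)
  expect_equal(fk$params$b, f$params$b, tolerance = 1e-7)
  expect_equal(fk$rms, k * f$rms, tolerance = 1e-7)
  delta <- 30
  fs <- fit_decay(setting_series("x", 1, s$t + delta, s$svh), "exponential")
  expect_equal(fs$params$b, f$params$b, tolerance = 1e-6)
  expect_equal(fs$params$C, f$params$C, tolerance = 1e-5)
  expect_equal(fs$params$A, f$params$A * exp(f$params$b * delta), tolerance = 1e-5)
  expect_equal(fs$rms, f$rms, tolerance = 1e-8)
})

test_that("constant series give the flat solution, not the steep ridge", {
  s <- setting_series("c", 1, c(5, 20, 60, 120, 240), rep(2.5, 5))
  for (fam in c("exponential", "power")) {
    f <- fit_decay(s, fam)
    expect_equal(f$params$A, 0, tolerance = 1e-9)
    expect_equal(f$params$C, 2.5, tolerance = 1e-9)
    expect_lt(f$params$b, 1e-3)  # smallest-b tie-break, no b -> Inf ridge
    expect_equal(f$rms, 0, tolerance = 1e-9)
  }
})

test_that("fitting refuses unusable series", {
  expect_error(fit_decay(setting_series("x", 1, c(5, 10, 20), c(1, 2, 3)),
                         "exponential"), "at least 4 settings")
  expect_error(setting_series("x", 1, c(5, 10, 8, 20), c(1, 2, 3, 4)),
               "strictly increasing")
  expect_error(setting_series("x", 1, c(5, 10, 20, 30), c(1, NA, 3, 4)),
               "non-finite")
})

test_that("run averaging matches hand arithmetic and the identity case", {
  f1 <- make_fit("1", 1, "exponential", A = 45.7, b = 0.0223, C = 7.7,
                 f4 = 49.6, f360 = 7.9, rms = 3.085)
  f2 <- make_fit("1", 2, "exponential", A = 30.3, b = 0.0101, C = 5.6,
                 f4 = 34.7, f360 = 6.4, rms = 2.304)
  avg <- average_runs(list(f1, f2))
  expect_equal(avg$A, 38.0)
  expect_equal(avg$rms, 2.6945)
  expect_equal(avg$b, 0.0162)
  expect_equal(avg$T, 1 / 0.0162)
  expect_equal(avg$n_runs, 2)
  single <- make_fit("18", 1, "exponential", A = 22.4, b = 0.0074, C = -0.5,
                     f4 = 21.3, f360 = 1.1, rms = 2.136)
  one <- average_runs(list(single))
  expect_equal(one$A, 22.4)
  expect_equal(one$rms, 2.136)
  expect_equal(one$T, 1 / 0.0074)
  expect_error(average_runs(list(f1, make_fit("2", 1, "exponential",
                                              1, 0.01, 0, 1, 0, 1))),
               "different subjects")
  expect_error(average_runs(list(f1, make_fit("1", 2, "power",
                                              1, 0.01, 0, 1, 0, 1))),
               "families")
})

test_that("recovered decay rates track the generating rates without bias", {
  cfg <- cohort_config(n_subjects = 30, n_two_run = 0, seed = 2024)
  coh <- sample_cohort(cfg)
  fits <- fit_cohort(coh$series, "exponential")
  b_hat <- vapply(fits, function(f) f$params$b, numeric(1))
  ratio <- b_hat / coh$truth$b
  # no systematic multiplicative bias, and most runs recovered within half
  # their generating rate despite study-level setting noise
  expect_gt(stats::median(ratio), 0.8)
  expect_lt(stats::median(ratio), 1.25)
  expect_gt(mean(abs(ratio - 1) < 0.5), 0.6)
})
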