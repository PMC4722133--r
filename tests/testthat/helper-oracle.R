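# Independent variable-projection grid oracle: exhaustive log-spaced scan of
# the decay rate with the linear subproblem solved by base lm.fit at each
# trial rate, plus a Brent polish around the best grid point.  Shares no code
# with the package's multistart search.
grid_oracle_sse <- function(t, y, family, b_range = NULL, n_grid = 2000) {
  if (is.null(b_range))
    b_range <- if (family == "exponential") c(1e-4, 2) else c(1e-4, 4)
  sse_at <- function(b) {
    g <- if (family == "exponential") exp(-b * t) else t^(-b)
    fit <- stats::lm.fit(cbind(g, 1), y)
    sum(fit$residuals^2)
  }
  bs <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = n_grid))
  ss <- vapply(bs, sse_at, numeric(1))
  i <- which.min(ss)
  op <- stats::optimize(sse_at,
                        lower = bs[max(1L, i - 1L)],
                        upper = bs[min(n_grid, i + 1L)], tol = 1e-12)
  min(op$objective, ss[i])
}

# deterministic evenly spaced series on the observation window
make_series <- function(A, b, C, n = 20, noise_sd = 0, seed = NULL,
                        subject = "x", run = 1, family = "exponential") {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(4, 360, length.out = n)
  p <- decay_params(family, A = A, b = b, C = C)
  y <- eval_decay(p, tt) + stats::rnorm(n, 0, noise_sd)
  setting_series(subject, run, tt, y)
}

# minimal fit object for exercising run-averaging arithmetic directly
make_fit <- function(subject, run, family, A, b, C, f4, f360, rms, n = 20) {
  structure(list(subject_id = subject, run_id = as.integer(run),
                 family = family,
                 params = decay_params(family, A = A, b = b, C = C),
                 sse = rms^2 * n, rms = rms, n = n,
                 f_tmin = f4, f_tmax = f360,
                 converged = TRUE, n_starts_used = 64L),
            class = "decay_fit")
}

# run-averaged individual summaries from the study's printed exponential table
study_individuals_exponential <- function() {
  tab <- study_exponential_fits()
  ind <- stats::aggregate(cbind(A, b, C, F4, F360) ~ subject, tab, mean)
  data.frame(subject_id = as.character(ind$subject), family = "exponential",
             n_runs = as.vector(table(tab$subject)[as.character(ind$subject)]),
             A = ind$A, b = ind$b, C = ind$C,
             f_tmin = ind$F4, f_tmax = ind$F360,
             T = 1 / ind$b, stringsAsFactors = FALSE)
}
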