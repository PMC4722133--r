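#' Multistart search configuration
#'
#' The least-squares problem for both model families is separable: for a fixed
#' decay rate \code{b} the model is linear in \code{(A, C)}, so the fit
#' reduces to a one-dimensional global search over \code{b} in which the
#' linear subproblem is solved exactly at every trial rate.  The search
#' launches a local refinement from each of \code{n_starts} log-spaced rates
#' and keeps the best local optimum.
#'
#' @param n_starts Number of log-spaced starting rates (default 64).
#' @param b_range Search range for \code{b}, length 2.  \code{NULL} (default)
#'   resolves to \code{c(1e-4, 2)} for the exponential family and
#'   \code{c(1e-4, 4)} for the power family at fit time.
#' @param refine_tol Relative SSE change below which local refinement is
#'   considered converged (default 1e-10).
#' @param tie_tol Starts whose refined SSE is within this relative distance of
#'   the best are ties; the tie with the smallest \code{b} (flattest curve) is
#'   reported.  Default 1e-9.
#' @return A list of class \code{"multistart_config"}.
#' @export
multistart_config <- function(n_starts = 64, b_range = NULL,
                              refine_tol = 1e-10, tie_tol = 1e-9) {
  stopifnot(n_starts >= 2, refine_tol > 0, tie_tol > 0)
  if (!is.null(b_range))
    stopifnot(length(b_range) == 2, b_range[1] > 0, b_range[2] > b_range[1])
  structure(list(n_starts = as.integer(n_starts), b_range = b_range,
                 refine_tol = refine_tol, tie_tol = tie_tol),
            class = "multistart_config")
}

default_b_range <- function(family) {
  switch(family, exponential = c(1e-4, 2), power = c(1e-4, 4))
}

# basis function of the separable model: model = A * g_b(t) + C
decay_basis <- function(family, b, t) {
  switch(family, exponential = exp(-b * t), power = t^(-b))
}

# exact linear subproblem at fixed b; returns A, C and the SSE profile value.
# falls back to the flat solution when the basis is numerically constant.
profile_solve <- function(t, y, b, family) {
  g <- decay_basis(family, b, t)
  qx <- qr(cbind(g, 1))
  if (qx$rank < 2L) {
    A <- 0; C <- mean(y)
  } else {
    cf <- qr.coef(qx, y)
    A <- cf[[1]]; C <- cf[[2]]
  }
  r <- y - (A * g + C)
  list(A = A, C = C, sse = sum(r * r))
}

# multistart variable-projection fit on bare (t, y) vectors
fit_decay_xy <- function(t, y, family, control = multistart_config()) {
  n <- length(t)
  if (n < 4L)
    stop("at least 4 settings are required for a 3-parameter fit", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(y)))
    stop("non-finite observations; refusing to fit", call. = FALSE)
  if (family == "power" && any(t <= 0))
    stop("power function approaches infinity as t goes to zero; requires t > 0",
         call. = FALSE)
  rng <- if (is.null(control$b_range)) default_b_range(family) else control$b_range
  starts <- exp(seq(log(rng[1]), log(rng[2]), length.out = control$n_starts))
  ratio <- starts[2] / starts[1]
  sse_of <- function(b) profile_solve(t, y, b, family)$sse

  # local refinement from each start within its log-neighbourhood
  cand_b <- numeric(control$n_starts)
  cand_sse <- numeric(control$n_starts)
  for (i in seq_along(starts)) {
    lo <- max(rng[1], starts[i] / ratio)
    hi <- min(rng[2], starts[i] * ratio)
    op <- stats::optimize(sse_of, lower = lo, upper = hi,
                          tol = max(starts[i] * 1e-8, 1e-12))
    cand_b[i] <- op$minimum
    cand_sse[i] <- op$objective
  }

  # polish the incumbent until the relative SSE improvement stalls
  best <- which.min(cand_sse)
  b_best <- cand_b[best]; s_best <- cand_sse[best]
  for (k in 1:5) {
    lo <- max(rng[1], b_best / 1.05); hi <- min(rng[2], b_best * 1.05)
    op <- stats::optimize(sse_of, lower = lo, upper = hi,
                          tol = max(b_best * 1e-10, 1e-14))
    gain <- s_best - op$objective
    if (op$objective < s_best) { b_best <- op$minimum; s_best <- op$objective }
    if (gain <= control$refine_tol * max(s_best, .Machine$double.xmin)) break
  }

  # smallest-b tie-break among starts indistinguishable from the optimum
  tie <- cand_sse <= s_best + control$tie_tol * max(s_best, 1e-12)
  if (any(tie)) {
    b_tie <- min(cand_b[tie])
    if (b_tie < b_best) {
      b_best <- b_tie
      s_best <- sse_of(b_best)
    }
  }

  sol <- profile_solve(t, y, b_best, family)
  # the profile optimum can sit on the search boundary; flag it
  at_edge <- b_best <= rng[1] * (1 + 1e-6) || b_best >= rng[2] * (1 - 1e-6)
  list(A = sol$A, b = b_best, C = sol$C, sse = sol$sse, n = n,
       converged = !at_edge || sol$A == 0, n_starts_used = control$n_starts)
}

#' Fit a decay model to one setting series
#'
#' Unweighted least squares: every setting carries equal weight.  The global
#' optimum over \code{b > 0} (with \code{A}, \code{C} unconstrained) is
#' located by the multistart variable-projection search described in
#' \code{\link{multistart_config}}.  The procedure is deterministic: the start
#' pattern is a fixed log-spaced grid.
#'
#' Degenerate constant series are reported as the flat solution
#' (\code{A = 0}, \code{C = mean(svh)}, smallest searched \code{b}) rather
#' than the ridge of ever-steeper equivalent fits.
#'
#' @param series A \code{\link{setting_series}}.
#' @param family \code{"exponential"} or \code{"power"}.
#' @param control A \code{\link{multistart_config}}.
#' @param interval \code{\link{obs_interval}} at which the fitted function's
#'   endpoint values are reported.
#' @return An object of class \code{"decay_fit"}: fitted
#'   \code{\link{decay_params}}, \code{sse} (deg^2), \code{rms = sqrt(sse/n)}
#'   (deg), \code{n}, endpoint values \code{f_tmin}/\code{f_tmax},
#'   \code{converged} flag and \code{n_starts_used}.
#' @examples
#' p <- decay_params("exponential", A = 30, b = 0.01, C = 2)
#' tt <- seq(4, 360, length.out = 20)
#' s <- setting_series("x", 1, tt, eval_decay(p, tt))
#' fit_decay(s, "exponential")
#' @export
fit_decay <- function(series, family = c("exponential", "power"),
                      control = multistart_config(), interval = obs_interval()) {
  stopifnot(inherits(series, "setting_series"),
            inherits(control, "multistart_config"))
  family <- match.arg(family)
  res <- fit_decay_xy(series$t, series$svh, family, control)
  params <- decay_params(family, A = res$A, b = res$b, C = res$C)
  ext <- interval_extremes(params, interval)
  structure(list(subject_id = series$subject_id, run_id = series$run_id,
                 family = family, params = params,
                 sse = res$sse, rms = sqrt(res$sse / res$n), n = res$n,
                 f_tmin = unname(ext[1]), f_tmax = unname(ext[2]),
                 converged = res$converged, n_starts_used = res$n_starts_used),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> subject %s run %d, %s: A = %.4g, b = %.4g, C = %.4g | RMS = %.3f deg (n = %d)%s\n",
              x$subject_id, x$run_id, x$family,
              x$params$A, x$params$b, x$params$C, x$rms, x$n,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Fit every run in a cohort
#'
#' @param series List of \code{\link{setting_series}}.
#' @inheritParams fit_decay
#' @return List of \code{\link{fit_decay}} results, one per run.
#' @export
fit_cohort <- function(series, family = c("exponential", "power"),
                       control = multistart_config(), interval = obs_interval()) {
  family <- match.arg(family)
  stopifnot(is.list(series), length(series) > 0L)
  lapply(series, fit_decay, family = family, control = control,
         interval = interval)
}

#' Average a subject's runs into an individual summary
#'
#' For subjects who completed two runs, the per-run parameters, endpoint
#' values and RMS errors are averaged arithmetically before any group
#' statistics are computed; the exponential time constant is
#' \code{T = 1/mean(b)}.  Single-run subjects carry their run's values
#' unchanged.
#'
#' @param fits List of 1 or 2 \code{"decay_fit"} objects for the same subject
#'   and model family.
#' @return One-row data frame: subject_id, family, n_runs, A, b, C, f_tmin,
#'   f_tmax, rms, and T (seconds; NA for the power family).
#' @export
average_runs <- function(fits) {
  stopifnot(is.list(fits), length(fits) %in% 1:2,
            all(vapply(fits, inherits, logical(1), "decay_fit")))
  subj <- unique(vapply(fits, `[[`, character(1), "subject_id"))
  fam <- unique(vapply(fits, `[[`, character(1), "family"))
  if (length(subj) != 1L)
    stop("cannot average runs across different subjects", call. = FALSE)
  if (length(fam) != 1L)
    stop("cannot average runs across model families", call. = FALSE)
  m <- function(field) mean(vapply(fits, `[[`, numeric(1), field))
  mp <- function(field) mean(vapply(fits, function(f) f$params[[field]], numeric(1)))
  b_bar <- mp("b")
  data.frame(subject_id = subj, family = fam, n_runs = length(fits),
             A = mp("A"), b = b_bar, C = mp("C"),
             f_tmin = m("f_tmin"), f_tmax = m("f_tmax"), rms = m("rms"),
             T = if (fam == "exponential") 1 / b_bar else NA_real_,
             stringsAsFactors = FALSE)
}

#' Individual summaries for a whole cohort of fits
#'
#' Groups per-run fits by subject and applies \code{\link{average_runs}}.
#'
#' @param fits List of \code{"decay_fit"} objects (one family).
#' @return Data frame with one row per subject, ordered as first encountered.
#' @export
individual_summaries <- function(fits) {
  stopifnot(is.list(fits), length(fits) > 0L,
            all(vapply(fits, inherits, logical(1), "decay_fit")))
  subj <- vapply(fits, `[[`, character(1), "subject_id")
  out <- lapply(unique(subj), function(s) average_runs(fits[subj == s]))
  do.call(rbind, out)
}

#' Residual sum of squares of a decay model on a series
#'
#' Equal-weight sum over settings of the squared deviation between the
#' observed SVH and the model value.
#'
#' @param params A \code{\link{decay_params}} object.
#' @param series A \code{\link{setting_series}}.
#' @return SSE in degrees squared.
#' @export
decay_sse <- function(params, series) {
  stopifnot(inherits(series, "setting_series"))
  r <- series$svh - eval_decay(params, series$t)
  sum(r * r)
}
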