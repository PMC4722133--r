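#' Group statistics over individual summaries
#'
#' Column-wise mean, median and sample SD (n - 1) over subjects of the
#' run-averaged parameters, observation-interval endpoint values and RMS
#' error.  The time constant is summarised as the mean over per-individual
#' \code{T = 1/(run-averaged b)}: because \code{1/b} is convex this exceeds
#' the reciprocal of the mean rate, and both views are retained.
#'
#' @param individuals Data frame from \code{\link{individual_summaries}} (or
#'   of the same shape), one row per subject, single family.
#' @return Data frame with rows mean/median/sd and columns A, b, C, f_tmin,
#'   f_tmax, rms, T; attributes \code{n_subjects} and \code{family}.
#' @export
group_summary <- function(individuals) {
  stopifnot(is.data.frame(individuals), nrow(individuals) > 0L)
  if (anyDuplicated(individuals$subject_id))
    stop("duplicate subjects in individual summaries; average runs first",
         call. = FALSE)
  fam <- unique(individuals$family)
  if (length(fam) > 1L)
    stop("individual summaries mix model families", call. = FALSE)
  cols <- intersect(c("A", "b", "C", "f_tmin", "f_tmax", "rms", "T"),
                    names(individuals))
  stat <- function(f) vapply(cols, function(cl) f(individuals[[cl]]), numeric(1))
  out <- rbind(mean = stat(function(x) mean(x)),
               median = stat(function(x) stats::median(x)),
               sd = stat(function(x) stats::sd(x)))
  out <- as.data.frame(out)
  attr(out, "n_subjects") <- nrow(individuals)
  attr(out, "family") <- fam
  out
}

#' Exponential-versus-power model contest from per-run RMS errors
#'
#' Counts the runs in which the power function fit better (smaller RMS),
#' averages runs within subject before computing group mean RMS per family,
#' reports the percentage by which the power function's mean RMS exceeds the
#' exponential's, and runs a two-sided paired t-test across subjects on the
#' run-averaged RMS.
#'
#' @param runs Data frame with columns \code{subject}, \code{run},
#'   \code{rms_exponential}, \code{rms_power}, one row per centrifuge run.
#' @return List of class \code{"model_contest"}: \code{n_runs_total},
#'   \code{n_runs_power_wins}, \code{mean_rms} (named, over run-averaged
#'   individuals), \code{percent_excess}, and \code{paired_t} (statistic, df,
#'   p.value).  When every paired difference is zero the t statistic is NA and
#'   p is reported as 1.
#' @examples
#' contest_from_rms(study_rms())
#' @export
contest_from_rms <- function(runs) {
  stopifnot(is.data.frame(runs),
            all(c("subject", "run", "rms_exponential", "rms_power") %in% names(runs)))
  if (anyDuplicated(runs[c("subject", "run")]))
    stop("duplicate (subject, run) rows", call. = FALSE)
  wins <- sum(runs$rms_power < runs$rms_exponential)
  ind <- stats::aggregate(cbind(rms_exponential, rms_power) ~ subject, runs, mean)
  mean_rms <- c(exponential = mean(ind$rms_exponential),
                power = mean(ind$rms_power))
  excess <- 100 * (mean_rms[["power"]] / mean_rms[["exponential"]] - 1)
  d <- ind$rms_power - ind$rms_exponential
  if (all(d == 0)) {
    pt <- list(statistic = NA_real_, df = nrow(ind) - 1L, p.value = 1)
  } else {
    tt <- stats::t.test(ind$rms_power, ind$rms_exponential, paired = TRUE)
    pt <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p.value = tt$p.value)
  }
  structure(list(n_runs_total = nrow(runs), n_runs_power_wins = wins,
                 mean_rms = mean_rms, percent_excess = excess,
                 paired_t = pt, individuals = ind),
            class = "model_contest")
}

#' Model contest from matched per-run fit objects
#'
#' @param exp_fits,pow_fits Lists of \code{"decay_fit"} objects for the same
#'   set of (subject, run) pairs, exponential and power family respectively.
#' @return See \code{\link{contest_from_rms}}.
#' @export
model_contest <- function(exp_fits, pow_fits) {
  key <- function(fits) paste(vapply(fits, `[[`, character(1), "subject_id"),
                              vapply(fits, `[[`, numeric(1), "run_id"))
  ke <- key(exp_fits); kp <- key(pow_fits)
  if (length(ke) != length(kp) || !setequal(ke, kp) || anyDuplicated(ke))
    stop("exponential and power fits must cover the same (subject, run) set",
         call. = FALSE)
  ord <- match(ke, kp)
  runs <- data.frame(
    subject = vapply(exp_fits, `[[`, character(1), "subject_id"),
    run = vapply(exp_fits, `[[`, numeric(1), "run_id"),
    rms_exponential = vapply(exp_fits, `[[`, numeric(1), "rms"),
    rms_power = vapply(pow_fits, `[[`, numeric(1), "rms")[ord],
    stringsAsFactors = FALSE)
  contest_from_rms(runs)
}

#' @export
print.model_contest <- function(x, ...) {
  cat(sprintf("<model_contest> %d runs; power RMS smaller in %d\n",
              x$n_runs_total, x$n_runs_power_wins))
  cat(sprintf("  mean RMS (run-averaged individuals): exponential %.3f, power %.3f (+%.1f%%)\n",
              x$mean_rms[["exponential"]], x$mean_rms[["power"]],
              x$percent_excess))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.2g\n",
              x$paired_t$statistic, x$paired_t$df, x$paired_t$p.value))
  invisible(x)
}

# pooled (t, svh) points -> both family fits and their RMS gap
pooled_fit_of_points <- function(points, scheme, control, interval,
                                 n_settings_total) {
  if (nrow(points) < 4L)
    stop("fewer than 4 pooled points survive; cannot fit 3-parameter models",
         call. = FALSE)
  fits <- lapply(c(exponential = "exponential", power = "power"), function(fam) {
    res <- fit_decay_xy(points$t, points$svh, fam, control)
    params <- decay_params(fam, A = res$A, b = res$b, C = res$C)
    ext <- interval_extremes(params, interval)
    structure(list(subject_id = "(pooled)", run_id = 1L, family = fam,
                   params = params, sse = res$sse,
                   rms = sqrt(res$sse / res$n), n = res$n,
                   f_tmin = unname(ext[1]), f_tmax = unname(ext[2]),
                   converged = res$converged,
                   n_starts_used = res$n_starts_used),
              class = "decay_fit")
  })
  structure(list(scheme = scheme, points = points, fits = fits,
                 rms_gap_ratio = fits$power$rms / fits$exponential$rms,
                 n_settings_total = n_settings_total),
            class = "pooled_fit")
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("<pooled_fit> scheme %s: %d pooled points (%d settings)\n",
              x$scheme, nrow(x$points), x$n_settings_total))
  cat(sprintf("  RMS exponential %.3f, power %.3f; gap ratio %.3f\n",
              x$fits$exponential$rms, x$fits$power$rms, x$rms_gap_ratio))
  invisible(x)
}

#' Group curve fit on time-binned cohort means
#'
#' The recording window is divided into \code{k_bins} equal time intervals.
#' For each subject, the mean time and mean SVH of that subject's settings
#' falling in each interval are computed (both runs pooled by default); then
#' the group mean time and SVH are computed over the subjects contributing to
#' each interval.  Both model families are fitted to the resulting pooled
#' points.  Bins with no settings at all are dropped.
#'
#' @param series List of \code{\link{setting_series}}.
#' @param k_bins Number of equal time intervals (>= 2); the study used 15
#'   and 5.
#' @param window Recording window in seconds split into bins; default
#'   \code{c(0, 360)}, the 6-min recording period (the first bin is simply
#'   sparse since no setting precedes 4 s).
#' @param per_run If TRUE, bin each run separately instead of pooling a
#'   subject's runs before averaging.
#' @param control,interval Passed to the fits.
#' @return A \code{"pooled_fit"}: scheme label, the pooled points (with the
#'   number of contributing subjects and underlying settings per bin), both
#'   fits, and \code{rms_gap_ratio = rms_power / rms_exponential}.
#' @export
pool_binned <- function(series, k_bins, window = c(0, 360), per_run = FALSE,
                        control = multistart_config(), interval = obs_interval()) {
  stopifnot(is.list(series), length(series) > 0L, k_bins >= 2)
  dat <- series_to_frame(series)
  breaks <- seq(window[1], window[2], length.out = k_bins + 1)
  dat$bin <- cut(dat$t, breaks, include.lowest = TRUE, labels = FALSE)
  if (anyNA(dat$bin))
    stop("settings outside the binning window", call. = FALSE)
  unit <- if (per_run) paste(dat$subject_id, dat$run_id) else dat$subject_id
  per_ind <- stats::aggregate(cbind(t, svh) ~ unit + bin,
                       data.frame(unit = unit, dat), mean)
  counts <- stats::aggregate(list(n_settings = rep(1L, nrow(dat))),
                      list(bin = dat$bin), sum)
  grp <- stats::aggregate(cbind(t, svh) ~ bin, per_ind, mean)
  grp$n_units <- as.vector(table(factor(per_ind$bin, levels = grp$bin)))
  grp <- merge(grp, counts, by = "bin")
  grp <- grp[order(grp$t), c("t", "svh", "bin", "n_units", "n_settings")]
  rownames(grp) <- NULL
  pooled_fit_of_points(grp, scheme = sprintf("binned_%d", k_bins),
                       control = control, interval = interval,
                       n_settings_total = nrow(dat))
}

#' Group curve fit on all individual settings
#'
#' Concatenates every setting from every run of every subject and fits both
#' model families to the raw point cloud.
#'
#' @inheritParams pool_binned
#' @return A \code{"pooled_fit"} with scheme \code{"all_points"}.
#' @export
pool_all_points <- function(series, control = multistart_config(),
                            interval = obs_interval()) {
  stopifnot(is.list(series), length(series) > 0L)
  dat <- series_to_frame(series)
  pts <- dat[order(dat$t), c("t", "svh")]
  rownames(pts) <- NULL
  pooled_fit_of_points(pts, scheme = "all_points", control = control,
                       interval = interval, n_settings_total = nrow(dat))
}

#' Discriminability diagnostics for a cohort of runs
#'
#' Six checks, per run, of whether the data could discriminate between
#' candidate retention functions: (1) nine or more distinct measurement
#' times; (2) precise time values recorded (structurally true here — every
#' setting is time-stamped); (3) large dynamic range, reported as the ratio of
#' the last to the first measurement time (and, when per-run RMS errors are
#' supplied, the ratio of the SVH change over the run to the RMS);
#' (4) a single stimulus presentation per run (structurally true for the
#' centrifuge paradigm); (5) constant filler activity during retention
#' (metadata flag on the series); (6) enough settings to fit the individual
#' run (n >= 4).
#'
#' @param series List of \code{\link{setting_series}}.
#' @param rms Optional numeric vector of per-run RMS errors (same order as
#'   \code{series}) used for the change-to-noise ratio in check 3.
#' @param min_time_ratio Threshold for calling the last/first time ratio
#'   "large" (default 10).
#' @return Data frame, one row per run, with the quantities and the six
#'   boolean criteria columns \code{crit1} .. \code{crit6}.
#' @export
discriminability_check <- function(series, rms = NULL, min_time_ratio = 10) {
  stopifnot(is.list(series), length(series) > 0L)
  if (!is.null(rms)) stopifnot(length(rms) == length(series))
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    change <- abs(s$svh[1] - s$svh[length(s$svh)])
    noise <- if (is.null(rms)) NA_real_ else rms[i]
    time_ratio <- s$t[length(s$t)] / s$t[1]
    data.frame(subject_id = s$subject_id, run_id = s$run_id,
               n_settings = length(s$t), n_times = length(unique(s$t)),
               first_t = s$t[1], last_t = s$t[length(s$t)],
               time_ratio = time_ratio, svh_change = change,
               change_to_rms = if (is.na(noise)) NA_real_ else change / noise,
               crit1 = length(unique(s$t)) >= 9,
               crit2 = TRUE,
               crit3 = time_ratio >= min_time_ratio,
               crit4 = TRUE,
               crit5 = s$filler_constant,
               crit6 = length(s$t) >= 4,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
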