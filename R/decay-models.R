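#' Decay model parameters
#'
#' Construct a parameter set for one of the candidate forgetting functions:
#' the three-parameter exponential \eqn{A e^{-bt} + C}, the three-parameter
#' power function \eqn{A t^{-b} + C}, or Wickelgren's single-trace fragility
#' function \eqn{\lambda (1 + \beta t)^{-\psi} e^{-\pi t}}.
#'
#' For the exponential and power families the decay rate \code{b} must be
#' strictly positive: the decay orientation is fixed and the sign of the tilt
#' is carried by the amplitude \code{A}.  The asymptote \code{C} is
#' unconstrained; for the SVH it absorbs the static (graviceptive) component
#' of the setting, which need not be zero.
#'
#' @param family One of \code{"exponential"}, \code{"power"},
#'   \code{"wickelgren"}.
#' @param A Amplitude in degrees (exponential) or degrees·s^b (power).
#' @param b Decay rate in 1/s (exponential) or dimensionless exponent (power);
#'   must be > 0.
#' @param C Asymptote, degrees.
#' @param lam,beta,psi,pi_rate Wickelgren parameters: initial trace strength
#'   \eqn{\lambda}, time-scaling rate \eqn{\beta} (1/s), power exponent
#'   \eqn{\psi}, and interference rate \eqn{\pi} (1/s).  Used only when
#'   \code{family = "wickelgren"}.
#' @return An object of class \code{"decay_params"}.
#' @examples
#' p <- decay_params("exponential", A = 27.8, b = 0.018, C = 0.5)
#' eval_decay(p, c(4, 60, 360))
#' @export
decay_params <- function(family = c("exponential", "power", "wickelgren"),
                         A = NULL, b = NULL, C = NULL,
                         lam = NULL, beta = NULL, psi = NULL, pi_rate = NULL) {
  family <- match.arg(family)
  if (family == "wickelgren") {
    if (is.null(lam) || is.null(beta) || is.null(psi) || is.null(pi_rate))
      stop("wickelgren family requires lam, beta, psi and pi_rate", call. = FALSE)
    if (!is.null(A) || !is.null(b) || !is.null(C))
      stop("wickelgren family does not take A, b, C", call. = FALSE)
    stopifnot(is.finite(lam), is.finite(beta), is.finite(psi), is.finite(pi_rate),
              beta >= 0, pi_rate >= 0)
    out <- list(family = family, lam = lam, beta = beta, psi = psi,
                pi_rate = pi_rate)
  } else {
    if (is.null(A) || is.null(b) || is.null(C))
      stop(family, " family requires A, b and C", call. = FALSE)
    if (!is.null(lam) || !is.null(beta) || !is.null(psi) || !is.null(pi_rate))
      stop(family, " family does not take wickelgren parameters", call. = FALSE)
    stopifnot(is.finite(A), is.finite(b), is.finite(C))
    if (b <= 0)
      stop("decay rate b must be > 0 (tilt sign is carried by A)", call. = FALSE)
    out <- list(family = family, A = A, b = b, C = C)
  }
  class(out) <- "decay_params"
  out
}

#' @export
print.decay_params <- function(x, ...) {
  if (x$family == "wickelgren") {
    cat(sprintf("<decay_params> wickelgren: lam = %g, beta = %g, psi = %g, pi = %g\n",
                x$lam, x$beta, x$psi, x$pi_rate))
  } else {
    cat(sprintf("<decay_params> %s: A = %g, b = %g, C = %g\n",
                x$family, x$A, x$b, x$C))
  }
  invisible(x)
}

#' Observation interval
#'
#' The time window over which fitted forgetting functions are evaluated and
#' compared.  The default, 4 to 360 s after reaching the G plateau, covers the
#' span in which line settings exist: no setting is made before 4 s and the
#' recording ends at 6 min.  A positive lower bound also keeps the power
#' function finite, since \eqn{A t^{-b}} diverges as \eqn{t \to 0^+}.
#'
#' @param t_min,t_max Interval endpoints in seconds; \code{0 < t_min < t_max}.
#' @return Numeric vector of length 2 with class \code{"obs_interval"}.
#' @export
obs_interval <- function(t_min = 4, t_max = 360) {
  stopifnot(is.finite(t_min), is.finite(t_max))
  if (!(t_min > 0 && t_max > t_min))
    stop("observation interval requires 0 < t_min < t_max", call. = FALSE)
  structure(c(t_min = t_min, t_max = t_max), class = "obs_interval")
}

#' Evaluate a decay model
#'
#' @param params A \code{\link{decay_params}} object.
#' @param t Time(s) in seconds since the start of the G plateau.  Must be
#'   >= 0 for the exponential and wickelgren families and strictly > 0 for the
#'   power family.
#' @return Model value(s) in degrees (trace strength for wickelgren).
#' @seealso \code{\link{interval_extremes}}, \code{\link{time_constant}}
#' @export
eval_decay <- function(params, t) {
  stopifnot(inherits(params, "decay_params"), is.numeric(t), all(is.finite(t)))
  switch(params$family,
    exponential = {
      if (any(t < 0)) stop("exponential family requires t >= 0", call. = FALSE)
      params$A * exp(-params$b * t) + params$C
    },
    power = {
      if (any(t <= 0))
        stop("power function approaches infinity as t goes to zero; requires t > 0",
             call. = FALSE)
      params$A * t^(-params$b) + params$C
    },
    wickelgren = {
      if (any(t < 0)) stop("wickelgren family requires t >= 0", call. = FALSE)
      params$lam * (1 + params$beta * t)^(-params$psi) * exp(-params$pi_rate * t)
    }
  )
}

#' Function values at the observation-interval endpoints
#'
#' Evaluates the fitted function at \code{t_min} and \code{t_max} of the
#' observation interval (default 4 and 360 s).  For the monotone exponential
#' and power families these are the extreme values the function takes on the
#' interval.
#'
#' @param params A \code{\link{decay_params}} object.
#' @param interval An \code{\link{obs_interval}} (default \code{obs_interval()}).
#' @return Named numeric vector \code{c(f_tmin =, f_tmax =)} in degrees.
#' @export
interval_extremes <- function(params, interval = obs_interval()) {
  if (!inherits(interval, "obs_interval")) interval <- obs_interval(interval[1], interval[2])
  c(f_tmin = eval_decay(params, interval[[1]]),
    f_tmax = eval_decay(params, interval[[2]]))
}

#' Time constant of exponential decay
#'
#' For the exponential model \eqn{A e^{-bt} + C} the time constant
#' \eqn{T = 1/b} is the e-folding time of the tilt sensation: after \eqn{T}
#' seconds the deviation from the asymptote has shrunk by a factor \eqn{e}.
#' Note that because \eqn{1/b} is convex, the mean of per-individual time
#' constants exceeds the reciprocal of the mean decay rate.
#'
#' @param b Decay rate(s) in 1/s; must be > 0.
#' @return Time constant(s) in seconds.
#' @export
time_constant <- function(b) {
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (any(b <= 0)) stop("time constant requires b > 0", call. = FALSE)
  1 / b
}
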