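#' Plot a setting series with fitted decay curves
#'
#' Base-graphics scatter of one run's settings over time, optionally overlaid
#' with fitted exponential (solid) and power (dotted) curves.
#'
#' @param x A \code{\link{setting_series}}.
#' @param fits Optional list of \code{"decay_fit"} objects to overlay.
#' @param ... Passed to \code{plot}.
#' @export
plot.setting_series <- function(x, fits = NULL, ...) {
  plot(x$t, x$svh, pch = 16,
       xlab = "time from plateau onset (s)", ylab = "SVH tilt (deg)",
       main = sprintf("subject %s run %d", x$subject_id, x$run_id), ...)
  add_fit_curves(fits, range(x$t))
  invisible(x)
}

#' Plot pooled group points with both fitted curves
#'
#' @param x A \code{"pooled_fit"} from \code{\link{pool_binned}} or
#'   \code{\link{pool_all_points}}.
#' @param ... Passed to \code{plot}.
#' @export
plot.pooled_fit <- function(x, ...) {
  plot(x$points$t, x$points$svh,
       pch = if (x$scheme == "all_points") 1 else 16,
       cex = if (x$scheme == "all_points") 0.5 else 1,
       xlab = "time from plateau onset (s)", ylab = "SVH tilt (deg)",
       main = sprintf("pooled fit (%s)", x$scheme), ...)
  add_fit_curves(x$fits, range(x$points$t))
  invisible(x)
}

add_fit_curves <- function(fits, t_range) {
  if (is.null(fits)) return(invisible())
  tt <- seq(max(t_range[1], 1e-3), t_range[2], length.out = 300)
  for (f in fits) {
    lty <- if (f$family == "power") 3 else 1
    graphics::lines(tt, eval_decay(f$params, tt), lty = lty, lwd = 1.5)
  }
  invisible()
}
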