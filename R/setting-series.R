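#' A single centrifuge run of SVH settings
#'
#' One run is an ordered series of line settings: at times \code{t} (seconds
#' since the beginning of the G plateau) the subject adjusted a luminous line
#' to the perceived horizontal, and the deviation \code{svh} of the line from
#' the gravitoinertial horizontal was recorded in degrees.  Tilt of the SVH to
#' the right (right end of the line set down, from the subject's point of
#' view) is positive; tilt to the left is negative.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param run_id Run number within subject, 1 or 2.
#' @param t Setting times in seconds; strictly increasing, all > 0.
#' @param svh SVH tilt at each setting, degrees.
#' @param g_level Gravitoinertial load during the run, multiples of Earth
#'   gravity (metadata; default 2.5).
#' @param filler_constant Logical metadata flag: was the activity filling the
#'   retention interval constant?  Used only by
#'   \code{\link{discriminability_check}}.
#' @return An object of class \code{"setting_series"}.
#' @examples
#' s <- setting_series("s1", 1, t = c(10, 25, 40), svh = c(20.1, 17.0, 15.2))
#' s
#' @export
setting_series <- function(subject_id, run_id, t, svh, g_level = 2.5,
                           filler_constant = TRUE) {
  subject_id <- as.character(subject_id)
  run_id <- as.integer(run_id)
  stopifnot(length(subject_id) == 1L, length(run_id) == 1L,
            run_id %in% c(1L, 2L), is.numeric(t), is.numeric(svh))
  if (length(t) != length(svh))
    stop("t and svh must have equal length", call. = FALSE)
  if (length(t) == 0L) stop("a run must contain at least one setting", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(svh)))
    stop("non-finite setting time or SVH value", call. = FALSE)
  if (any(t <= 0))
    stop("setting times must be > 0 (seconds from plateau onset)", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("setting times must be strictly increasing within a run", call. = FALSE)
  structure(list(subject_id = subject_id, run_id = run_id,
                 t = as.numeric(t), svh = as.numeric(svh),
                 g_level = g_level, filler_constant = isTRUE(filler_constant)),
            class = "setting_series")
}

#' @export
print.setting_series <- function(x, ...) {
  cat(sprintf("<setting_series> subject %s run %d: %d settings, t in [%.1f, %.1f] s, SVH in [%.1f, %.1f] deg (%.1fG)\n",
              x$subject_id, x$run_id, length(x$t), min(x$t), max(x$t),
              min(x$svh), max(x$svh), x$g_level))
  invisible(x)
}

#' @export
as.data.frame.setting_series <- function(x, ...) {
  data.frame(subject_id = x$subject_id, run_id = x$run_id,
             t = x$t, svh = x$svh, stringsAsFactors = FALSE)
}

#' Flatten a list of setting series to one settings table
#'
#' @param series A list of \code{\link{setting_series}}.
#' @return A data frame with columns subject_id, run_id, t, svh.
#' @export
series_to_frame <- function(series) {
  stopifnot(is.list(series), length(series) > 0L,
            all(vapply(series, inherits, logical(1), "setting_series")))
  do.call(rbind, lapply(series, as.data.frame))
}
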