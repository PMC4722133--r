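#' Reported per-run results of the 2.5G centrifuge study
#'
#' The study that motivated this package deposited no raw setting data, but
#' reported its per-run fitted parameters and goodness of fit in full.  These
#' accessors load those printed values, which serve as reference inputs for
#' group-level statistics and for reproduction checks (the package's fitted
#' pipeline is validated against them via re-evaluation and via synthetic
#' regeneration, since the underlying settings are not recoverable).
#'
#' \code{study_exponential_fits()}: per-run exponential parameters
#' (A in degrees, b in 1/s, C in degrees) with the function values
#' \code{F4}/\code{F360} at the observation-interval endpoints.
#' Subjects 1-17 have two runs, 18-27 one.
#'
#' \code{study_power_fits()}: the same for the power family (b is a
#' dimensionless exponent).  \code{int_printed} flags rows whose A or C was
#' printed at integer (0.5-degree quantum) rather than 0.1-degree precision,
#' which matters when re-evaluating the rounded parameters.
#'
#' \code{study_rms()}: per-run RMS errors (degrees) of both fits and the
#' number of settings per run.
#'
#' @return A data frame (see above).
#' @examples
#' head(study_exponential_fits())
#' contest_from_rms(study_rms())
#' @name study_tables
NULL

study_csv <- function(name) {
  path <- system.file("extdata", name, package = "svhdecay", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' @rdname study_tables
#' @export
study_exponential_fits <- function() study_csv("study_exponential_fits.csv")

#' @rdname study_tables
#' @export
study_power_fits <- function() study_csv("study_power_fits.csv")

#' @rdname study_tables
#' @export
study_rms <- function() study_csv("study_rms.csv")
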