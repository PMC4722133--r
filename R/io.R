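#' Read SVH setting series from a delimited file
#'
#' Expects comma-delimited UTF-8 text with a header row
#' \code{subject_id,run_id,t,svh}, '.' as the decimal mark and '#' comment
#' lines.  \code{t} is seconds since the start of the G plateau; \code{svh} is
#' the line deviation in degrees, right tilt positive.  Rows belonging to one
#' (subject, run) must appear with strictly increasing times; violations and
#' malformed fields are reported with their line numbers.
#'
#' @param path Path to the settings file.
#' @param g_level G level stamped on the parsed series (default 2.5).
#' @return List of \code{\link{setting_series}}, in order of first appearance.
#' @export
read_settings <- function(path, g_level = 2.5) {
  if (!file.exists(path)) stop("no such settings file: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 2L)
    stop("settings file has no data rows: ", path, call. = FALSE)
  header <- trimws(strsplit(lines[1], ",")[[1]])
  need <- c("subject_id", "run_id", "t", "svh")
  if (!all(need %in% header))
    stop("settings file is missing column(s): ",
         paste(setdiff(need, header), collapse = ", "), call. = FALSE)
  idx <- match(need, header)
  body <- lines[-1]; body_ln <- lineno[-1]
  parts <- strsplit(body, ",")
  bad_len <- which(lengths(parts) < length(header))
  if (length(bad_len))
    stop(sprintf("line %d: expected %d fields, found %d",
                 body_ln[bad_len[1]], length(header),
                 lengths(parts)[bad_len[1]]), call. = FALSE)
  field <- function(i) trimws(vapply(parts, `[[`, character(1), i))
  subj <- field(idx[1]); run <- field(idx[2])
  t_chr <- field(idx[3]); y_chr <- field(idx[4])
  t <- suppressWarnings(as.numeric(t_chr))
  y <- suppressWarnings(as.numeric(y_chr))
  run_n <- suppressWarnings(as.integer(run))
  bad <- which(is.na(t) | is.na(y) | is.na(run_n))
  if (length(bad))
    stop(sprintf("line %d: non-numeric field in (run_id, t, svh) = (%s, %s, %s)",
                 body_ln[bad[1]], run[bad[1]], t_chr[bad[1]], y_chr[bad[1]]),
         call. = FALSE)
  key <- paste(subj, run_n, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    ts <- t[sel]
    if (any(diff(ts) <= 0)) {
      off <- body_ln[sel][which(diff(ts) <= 0)[1] + 1L]
      stop(sprintf("line %d: setting times not strictly increasing for subject %s run %s",
                   off, subj[sel][1], run_n[sel][1]), call. = FALSE)
    }
    out[[length(out) + 1L]] <- setting_series(subj[sel][1], run_n[sel][1],
                                              ts, y[sel], g_level = g_level)
  }
  out
}

#' Write setting series to a delimited file
#'
#' Writes the format read by \code{\link{read_settings}}, with a header
#' comment documenting units and the sign convention.
#'
#' @param series List of \code{\link{setting_series}}.
#' @param path Output path.
#' @param digits Decimal places for t and svh (default 3).
#' @return \code{path}, invisibly.
#' @export
write_settings <- function(series, path, digits = 3) {
  dat <- series_to_frame(series)
  dat$t <- round(dat$t, digits)
  dat$svh <- round(dat$svh, digits)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# SVH setting series: t in seconds from G-plateau onset,",
               "# svh in degrees, tilt of the SVH to the right positive."),
             con)
  utils::write.table(dat, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

round_col <- function(x, digits) formatC(round(x, digits), format = "f",
                                         digits = digits)

#' Render per-run results as study-style tables
#'
#' Produces three delimited-ready data frames mirroring the study's report
#' layout: per-run exponential parameters (A, b, C and the
#' observation-interval endpoint values), the same for the power family, and
#' the per-run RMS contest with data-point counts.  Each table carries
#' Mean/Median/SD footer rows computed over run-averaged individuals at full
#' precision, then rounded for display (A, C and endpoint values to 0.1
#' degree; b to 4 decimals; RMS to 3 decimals by default).
#'
#' @param exp_fits,pow_fits Lists of \code{"decay_fit"} objects covering the
#'   same (subject, run) set.
#' @param digits Named list of display precisions:
#'   \code{list(par = 1, b = 4, rms = 3)}.
#' @return List of data frames \code{exponential}, \code{power}, \code{rms}
#'   (values as character columns at display precision; footer rows labelled
#'   in \code{subject}).
#' @export
render_tables <- function(exp_fits, pow_fits,
                          digits = list(par = 1, b = 4, rms = 3)) {
  if (length(exp_fits) == 0L || length(pow_fits) == 0L)
    stop("no fits to render", call. = FALSE)
  fit_frame <- function(fits) data.frame(
    subject = vapply(fits, `[[`, character(1), "subject_id"),
    run = vapply(fits, `[[`, numeric(1), "run_id"),
    A = vapply(fits, function(f) f$params$A, numeric(1)),
    b = vapply(fits, function(f) f$params$b, numeric(1)),
    C = vapply(fits, function(f) f$params$C, numeric(1)),
    f_tmin = vapply(fits, `[[`, numeric(1), "f_tmin"),
    f_tmax = vapply(fits, `[[`, numeric(1), "f_tmax"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    rms = vapply(fits, `[[`, numeric(1), "rms"),
    stringsAsFactors = FALSE)
  ef <- fit_frame(exp_fits); pf <- fit_frame(pow_fits)
  if (!identical(sort(paste(ef$subject, ef$run)), sort(paste(pf$subject, pf$run))))
    stop("exponential and power fits cover different (subject, run) sets; ",
         "missing cells: ",
         paste(union(setdiff(paste(ef$subject, ef$run), paste(pf$subject, pf$run)),
                     setdiff(paste(pf$subject, pf$run), paste(ef$subject, ef$run))),
               collapse = "; "), call. = FALSE)

  param_table <- function(df) {
    ind <- stats::aggregate(cbind(A, b, C, f_tmin, f_tmax) ~ subject, df, mean)
    foot <- rbind(Mean = colMeans(ind[-1]),
                  Median = apply(ind[-1], 2, stats::median),
                  SD = apply(ind[-1], 2, stats::sd))
    body <- data.frame(subject = df$subject, run = as.character(df$run),
                       A = round_col(df$A, digits$par),
                       b = round_col(df$b, digits$b),
                       C = round_col(df$C, digits$par),
                       f_tmin = round_col(df$f_tmin, digits$par),
                       f_tmax = round_col(df$f_tmax, digits$par),
                       stringsAsFactors = FALSE)
    footer <- data.frame(subject = rownames(foot), run = "",
                         A = round_col(foot[, "A"], digits$par),
                         b = round_col(foot[, "b"], digits$b),
                         C = round_col(foot[, "C"], digits$par),
                         f_tmin = round_col(foot[, "f_tmin"], digits$par),
                         f_tmax = round_col(foot[, "f_tmax"], digits$par),
                         stringsAsFactors = FALSE)
    rbind(body, footer)
  }

  key <- paste(ef$subject, ef$run)
  pf <- pf[match(key, paste(pf$subject, pf$run)), ]
  runs <- data.frame(subject = ef$subject, run = ef$run, n = ef$n,
                     rms_exponential = ef$rms, rms_power = pf$rms,
                     stringsAsFactors = FALSE)
  ind <- stats::aggregate(cbind(rms_exponential, rms_power) ~ subject, runs, mean)
  rms_body <- data.frame(subject = runs$subject, run = as.character(runs$run),
                         n = as.character(runs$n),
                         rms_exponential = round_col(runs$rms_exponential, digits$rms),
                         rms_power = round_col(runs$rms_power, digits$rms),
                         stringsAsFactors = FALSE)
  rms_foot <- data.frame(
    subject = c("Mean", "Median"), run = "", n = "",
    rms_exponential = round_col(c(mean(ind$rms_exponential),
                                  stats::median(ind$rms_exponential)), digits$rms),
    rms_power = round_col(c(mean(ind$rms_power),
                            stats::median(ind$rms_power)), digits$rms),
    stringsAsFactors = FALSE)
  list(exponential = param_table(ef), power = param_table(pf),
       rms = rbind(rms_body, rms_foot))
}
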