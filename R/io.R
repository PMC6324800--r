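## Reading dwell-time files and writing result reports. Dwell times are
## plain scalars, so only two carrier formats exist: one value per line
## (with '#' comments) or a delimited table with a named/indexed column.
## Seconds by convention; `time_unit` rescales on input.

#' Read dwell times from a text file
#'
#' Accepts either a plain list (one positive number per line, `#` comments
#' and blank lines skipped) or a delimited table, in which case `column`
#' selects the dwell-time column by name or index. All values must parse
#' as finite positive numbers; offending lines are reported by number.
#'
#' @param path Path to the file.
#' @param column Optional column name or index; its presence (or a
#'   delimiter in the first data line) switches to table mode.
#' @param sep Field separator for table mode (default `","`).
#' @param time_unit Multiplier converting file values to seconds
#'   (default 1).
#' @return Numeric vector of dwell times in seconds, with attribute
#'   `time_unit`.
#' @export
read_dwell_times <- function(path, column = NULL, sep = ",", time_unit = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(time_unit) || length(time_unit) != 1L || time_unit <= 0)
    stop("`time_unit` must be a single positive number", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data in file: ", path, call. = FALSE)
  tabular <- !is.null(column) || grepl(sep, lines[which(keep)[1]], fixed = TRUE)
  if (tabular) {
    df <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                            comment.char = "#", check.names = FALSE)
    if (is.null(column)) column <- 1L
    if (is.character(column) && !column %in% names(df))
      stop(sprintf("column '%s' not found (columns: %s)", column,
                   paste(names(df), collapse = ", ")), call. = FALSE)
    vals <- df[[column]]
    if (!is.numeric(vals))
      stop(sprintf("column '%s' is not numeric", as.character(column)),
           call. = FALSE)
    if (anyNA(vals) || any(!is.finite(vals)))
      stop("non-numeric or missing dwell-time entries in column", call. = FALSE)
    if (any(vals <= 0))
      stop(sprintf("non-positive dwell time(s) in rows %s",
                   paste(which(vals <= 0), collapse = ", ")), call. = FALSE)
  } else {
    raw <- trimws(lines)
    vals <- suppressWarnings(as.numeric(raw))
    bad <- keep & (is.na(vals) | !is.finite(vals))
    if (any(bad))
      stop(sprintf("cannot parse line(s) %s of %s as numbers",
                   paste(which(bad), collapse = ", "), path), call. = FALSE)
    nonpos <- keep & !bad & vals <= 0
    if (any(nonpos))
      stop(sprintf("non-positive dwell time(s) on line(s) %s of %s",
                   paste(which(nonpos), collapse = ", "), path), call. = FALSE)
    vals <- vals[keep]
  }
  structure(as.numeric(vals) * time_unit, time_unit = time_unit)
}

#' Write dwell times to a plain-text file
#'
#' One value per line at full float precision -- the inverse of
#' [read_dwell_times()]'s plain mode.
#'
#' @param times Dwell-time vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dwell_times <- function(times, path) {
  times <- check_dwell_times(times)
  writeLines(format(times, digits = 17, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

as_report <- function(x, ...) UseMethod("as_report")

#' @export
as_report.gmm_fit <- function(x, ...) {
  list(method = "gmm", estimates = x$estimates, Q_min = x$Q_min,
       n_steps = x$n_steps, order = x$order, weight_scheme = x$weight_scheme,
       passes = x$passes, double_root = x$double_root,
       n_starts = x$n_starts, converged_starts = x$converged_starts,
       sample = list(T = x$T, k_statistics = x$kstats))
}

#' @export
as_report.cmm_result <- function(x, ...) {
  list(method = "cmm", n_steps = x$n_steps, all_real = x$all_real,
       estimates = x$estimates, any_negative = x$any_negative,
       roots = lapply(x$roots, function(z) c(Re(z), Im(z))),
       sample = list(T = x$T, k_statistics = x$kstats))
}

#' @export
as_report.nlsq_fit <- function(x, ...) {
  list(method = "nlsq", estimates = x$estimates, rss = x$rss,
       n_exp = x$n_exp, n_bins = length(x$histogram$counts),
       converged = x$converged, negative_or_failed = x$negative_or_failed,
       sample = list(T = x$T))
}

#' @export
as_report.model_order_scan <- function(x, ...) {
  list(method = "model_order_scan", T = x$T,
       orders = lapply(x$fits, function(f)
         if (inherits(f, "error")) list(error = conditionMessage(f))
         else as_report(f)))
}

#' @export
as_report.trial_batch <- function(x, ...) {
  s <- summary(x)
  list(method = "bench",
       taus = x$taus, n = x$n, n_trials = x$n_trials, seed = x$seed,
       summary = s)
}

#' Write a result report as JSON
#'
#' Serialises a fit, solve, scan or batch object together with the package
#' version, a timestamp, the seed (when one was used) and an optional
#' configuration echo. The JSON round-trips: numeric fields re-read with
#' [jsonlite::read_json()] equal the in-memory values.
#'
#' @param x A `gmm_fit`, `cmm_result`, `nlsq_fit`, `model_order_scan` or
#'   `trial_batch`.
#' @param path Output path (`.json`).
#' @param config Optional named list echoed verbatim into the report (CLI
#'   invocations record their parsed arguments here).
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config = NULL, seed = NULL) {
  report <- list(tool = "dwellgmm",
                 version = as.character(utils::packageVersion("dwellgmm")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = if (!is.null(seed)) as_seed(seed),
                 config = config,
                 result = as_report(x))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Write a batch summary as TSV
#'
#' Tabular twin of the JSON report for [run_batch()] results: one row per
#' method x sorted-parameter index, columns `method`, `param`, `mean`,
#' `mean_deviation`, `n_ok`, `n_fail`, `n_double_root`, `n_negative`.
#'
#' @param batch A `trial_batch`.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_batch_tsv <- function(batch, path) {
  stopifnot(inherits(batch, "trial_batch"))
  utils::write.table(summary(batch), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
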