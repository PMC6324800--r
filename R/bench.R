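## Simulation-study harness: paired batches of simulated trials analysed by
## several estimators, bias/dispersion summaries, and the just-specified
## model-order scan used to probe how many steps a dataset supports.

#' Describe an estimator for [run_batch()]
#'
#' @param method `"gmm"`, `"cmm"` or `"nlsq"`.
#' @param n_steps Model steps (`gmm`/`cmm`) or exponential components
#'   (`nlsq`).
#' @param order GMM moment order (defaults to just-specified).
#' @param weights GMM weight scheme.
#' @param ... Further arguments passed through to the estimator (e.g.
#'   `region`, `cov_table`).
#' @param label Column label; defaults to a compact description.
#' @return A list of class `"bench_method"`.
#' @export
bench_method <- function(method = c("gmm", "cmm", "nlsq"), n_steps,
                         order = n_steps, weights = "jackknife_diag", ...,
                         label = NULL) {
  method <- match.arg(method)
  n_steps <- check_count(n_steps, 1L, "n_steps")
  if (is.null(label))
    label <- switch(method,
      gmm = sprintf("gmm_n%d_M%d_%s", n_steps, order, weights),
      cmm = sprintf("cmm_n%d", n_steps),
      nlsq = sprintf("nlsq_n%d", n_steps))
  structure(list(method = method, n_steps = n_steps, order = order,
                 weights = weights, extra = list(...), label = label),
            class = "bench_method")
}

apply_method <- function(m, times) {
  n <- m$n_steps
  out <- list(estimates = rep(NA_real_, n), failed = TRUE,
              double_root = NA, negative = NA)
  res <- tryCatch(switch(m$method,
    gmm = do.call(gmm_fit, c(list(times = times, n_steps = n, order = m$order,
                                  weights = m$weights), m$extra)),
    cmm = cmm_solve(times, n),
    nlsq = do.call(nlsq_fit, c(list(times = times, n_exp = n), m$extra))),
    error = function(e) NULL)
  if (is.null(res)) return(out)
  if (m$method == "gmm") {
    out <- list(estimates = res$estimates, failed = FALSE,
                double_root = res$double_root,
                negative = any(res$estimates <= 0))
  } else if (m$method == "cmm") {
    if (res$all_real)
      out <- list(estimates = res$estimates, failed = FALSE,
                  double_root = FALSE, negative = res$any_negative)
    else
      out$double_root <- FALSE     # complex solution counts as a failure
  } else {
    out <- list(estimates = res$estimates,
                failed = res$negative_or_failed,
                double_root = NA,
                negative = any(res$estimates <= 0, na.rm = TRUE))
  }
  out
}

#' Run a paired batch of simulated trials
#'
#' Simulates `n_trials` dwell-time samples of size `n` from the scheme and
#' applies every configured estimator to each sample, so all methods see
#' identical draws (paired comparison). Per-trial estimator failures
#' (complex classical solutions, non-converged fits) are recorded, never
#' abort the batch. Bit-reproducible under `seed`; trial i uses the
#' offset stream `seed + i`.
#'
#' @param taus True decay parameters of the simulated irreversible scheme.
#' @param n Sample size per trial.
#' @param n_trials Number of trials (the reference protocol uses 1000).
#' @param methods List of [bench_method()] descriptors.
#' @param seed Integer seed.
#' @return Object of class `"trial_batch"`: per-method matrices of sorted
#'   estimates (`n_trials` rows), failure/double-root/negative flags, and
#'   the batch configuration.
#' @export
run_batch <- function(taus, n, n_trials, methods, seed = NULL) {
  taus <- check_taus(taus)
  n <- check_count(n, 1L, "n")
  n_trials <- check_count(n_trials, 1L, "n_trials")
  if (inherits(methods, "bench_method")) methods <- list(methods)
  stopifnot(all(vapply(methods, inherits, logical(1), "bench_method")))
  labels <- vapply(methods, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("method labels must be unique", call. = FALSE)
  est <- lapply(methods, function(m)
    matrix(NA_real_, n_trials, m$n_steps,
           dimnames = list(NULL, paste0("tau", seq_len(m$n_steps)))))
  failed <- dbl <- neg <- matrix(FALSE, n_trials, length(methods),
                                 dimnames = list(NULL, labels))
  names(est) <- labels
  for (i in seq_len(n_trials)) {
    times <- simulate_irreversible(taus, n, seed = trial_seed(seed, i))
    for (j in seq_along(methods)) {
      r <- apply_method(methods[[j]], times)
      est[[j]][i, ] <- r$estimates
      failed[i, j] <- isTRUE(r$failed)
      dbl[i, j] <- isTRUE(r$double_root)
      neg[i, j] <- isTRUE(r$negative)
    }
  }
  structure(list(estimates = est, failed = failed, double_root = dbl,
                 negative = neg, taus = taus, n = n, n_trials = n_trials,
                 methods = methods, seed = seed),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("Trial batch: scheme (%s) s, T = %d, %d trials, %d method(s)\n",
              paste(signif(x$taus, 4), collapse = ", "), x$n, x$n_trials,
              length(x$methods)))
  print(summary(x))
  invisible(x)
}

#' Summarise a trial batch: mean estimates and dispersion
#'
#' For each method and sorted-parameter index: the arithmetic mean of the
#' estimate over successful trials, the mean absolute deviation about that
#' mean (the dispersion measure plotted as error bars in the reference
#' simulation studies), and the failure count. Failed trials are excluded
#' from the means, never imputed; an all-failed cell reports `NA`.
#'
#' @param object A `trial_batch`.
#' @param ... Unused.
#' @return A `data.frame` with columns `method`, `param`, `mean`,
#'   `mean_deviation`, `n_ok`, `n_fail`, `n_double_root`, `n_negative`.
#' @export
summary.trial_batch <- function(object, ...) {
  rows <- list()
  for (j in seq_along(object$methods)) {
    lab <- object$methods[[j]]$label
    E <- object$estimates[[lab]]
    ok <- !object$failed[, j]
    for (p in seq_len(ncol(E))) {
      v <- E[ok, p]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        method = lab, param = p,
        mean = if (length(v)) mean(v) else NA_real_,
        mean_deviation = if (length(v)) mean(abs(v - mean(v))) else NA_real_,
        n_ok = length(v), n_fail = sum(!ok),
        n_double_root = sum(object$double_root[, j]),
        n_negative = sum(object$negative[, j]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Just-specified model-order scan
#'
#' Fits single-pass just-specified GMMs with the diagonal-jackknife weight
#' for every model order `n = 1..min(max_steps, 4)` and reports, per order,
#' the sorted estimates together with the double-root and
#' negative-constant flags. Negative or negligible extra steps at higher
#' orders are the overfit diagnostic: the data do not support that many
#' steps. Orders above 4 are not available because the unbiased cumulant
#' estimators stop at order 4; requesting more caps the scan with a
#' warning.
#'
#' @param times Dwell-time sample.
#' @param max_steps Largest model order to try.
#' @param ... Passed to [gmm_fit()] (e.g. `region`).
#' @return Object of class `"model_order_scan"`: `fits` (list of
#'   `gmm_fit`s indexed by order) and `table` (one row per order: sum of
#'   estimates, largest estimate, flags).
#' @export
model_order_scan <- function(times, max_steps = 4L, ...) {
  max_steps <- check_count(max_steps, 1L, "max_steps")
  if (max_steps > 4L) {
    warning("model-order scan capped at 4 steps (k-statistics are implemented to order 4)",
            call. = FALSE)
    max_steps <- 4L
  }
  times <- check_dwell_times(times)
  fits <- list()
  rows <- list()
  for (n in seq_len(max_steps)) {
    fit <- tryCatch(gmm_fit(times, n_steps = n, order = n, ...),
                    error = function(e) e)
    fits[[n]] <- fit
    if (inherits(fit, "error")) {
      rows[[n]] <- data.frame(n_steps = n, sum = NA_real_, largest = NA_real_,
                              double_root = NA, any_negative = NA,
                              error = conditionMessage(fit))
    } else {
      rows[[n]] <- data.frame(n_steps = n, sum = sum(fit$estimates),
                              largest = max(fit$estimates),
                              double_root = fit$double_root,
                              any_negative = any(fit$estimates <= 0),
                              error = NA_character_)
    }
  }
  structure(list(fits = fits, table = do.call(rbind, rows), T = length(times)),
            class = "model_order_scan")
}

#' @export
print.model_order_scan <- function(x, digits = 5L, ...) {
  cat(sprintf("Just-specified model-order scan (T = %d)\n", x$T))
  for (n in seq_along(x$fits)) {
    f <- x$fits[[n]]
    if (inherits(f, "error")) {
      cat(sprintf("  %d step(s): error (%s)\n", n, conditionMessage(f)))
    } else {
      cat(sprintf("  %d step(s): (%s) s%s%s\n", n,
                  paste(signif(f$estimates, digits), collapse = ", "),
                  if (f$double_root) " [double root]" else "",
                  if (any(f$estimates <= 0)) " [negative -> overfit]" else ""))
    }
  }
  invisible(x)
}
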