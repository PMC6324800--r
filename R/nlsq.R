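## Histogram-based nonlinear least-squares comparator (NL-LSQM): dwell
## times are binned into ceil(sqrt(T)) equal-width bins and the counts are
## fit to a multi-exponential model by Levenberg-Marquardt. The finite
## bin-width correction is exact: the expected count in a bin is
## T * [F(upper) - F(lower)] with F the model CDF, i.e. the model is
## integrated over each bin rather than evaluated at its midpoint.

#' Bin a dwell-time sample with the square-root rule
#'
#' `ceiling(sqrt(T))` equal-width bins spanning `[0, max(times)]`; counts
#' conserve the sample size.
#'
#' @param times Dwell-time sample, `T >= 2`.
#' @param n_bins Optional override of the square-root rule (departs from
#'   the standard protocol; recorded in the result).
#' @return List of class `"binned_histogram"`: `edges` (length
#'   `n_bins + 1`), `counts`, `T`, `sqrt_rule` flag.
#' @export
bin_sample <- function(times, n_bins = NULL) {
  times <- check_dwell_times(times, min_n = 2L)
  T <- length(times)
  sqrt_rule <- is.null(n_bins)
  if (sqrt_rule) n_bins <- ceiling(sqrt(T))
  n_bins <- check_count(n_bins, 1L, "n_bins")
  edges <- seq(0, max(times), length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(times, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  structure(list(edges = edges, counts = counts, T = T, sqrt_rule = sqrt_rule),
            class = "binned_histogram")
}

#' @export
print.binned_histogram <- function(x, ...) {
  cat(sprintf("Dwell-time histogram: %d bins over [0, %.4g] s, T = %d%s\n",
              length(x$counts), max(x$edges), x$T,
              if (x$sqrt_rule) " (sqrt-rule)" else ""))
  invisible(x)
}

#' Bin-integrated multi-exponential model counts
#'
#' Expected count per bin for a sum-of-exponentials dwell-time model:
#' `T * [F(edge_{i+1}) - F(edge_i)]` with `F` the model CDF (exact
#' finite-bin-width correction). The two-exponential case uses the closed
#' biexponential CDF including its degenerate equal-constant branch.
#'
#' @param edges Strictly increasing bin edges (seconds).
#' @param T Total sample size the counts scale to.
#' @param taus Positive decay parameters, one per exponential step.
#' @return Expected counts, one per bin; their sum approaches `T` as the
#'   last edge grows.
#' @export
biexp_bin_model <- function(edges, T, taus) {
  taus <- check_taus(taus)
  if (is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be strictly increasing", call. = FALSE)
  F <- cdf_hypoexp(edges, taus)
  T * diff(F)
}

# residual model used inside the LM loop: tolerates nonpositive/absurd
# candidate taus by returning a large finite penalty so the optimizer can
# retreat rather than crash.
nlsq_model_safe <- function(edges, T, taus) {
  if (any(!is.finite(taus)) || any(taus <= 0)) return(rep(1e12, length(edges) - 1L))
  out <- tryCatch(biexp_bin_model(edges, T, taus), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) return(rep(1e12, length(edges) - 1L))
  pmin(out, 1e12)
}

#' Fit binned dwell times to a multi-exponential model (NL-LSQM)
#'
#' The standard histogram comparator: square-root-rule binning, exact
#' bin-integrated model, unweighted least squares on counts, minimised by
#' Levenberg-Marquardt ([minpack.lm::nls.lm]) from the same log-spaced
#' start grid as the GMM. A fit is flagged `negative_or_failed` when no
#' start converges, an estimate is nonpositive or non-finite, or an
#' estimate runs away beyond 1e4 times the data range (it then carries no
#' information at the sample's scale) -- the small-sample regime where this
#' method breaks down while the moment estimator still returns values.
#'
#' @param times Dwell-time sample, `T >= 4`.
#' @param n_exp Number of exponential components (default 2, the
#'   biexponential protocol).
#' @param n_bins Optional bin-count override (see [bin_sample()]).
#' @param region,grid_factor Start grid, as in [gmm_fit()].
#' @return Object of class `"nlsq_fit"`: sorted `estimates`, `rss`,
#'   `converged`, `negative_or_failed`, the histogram, diagnostics.
#' @export
nlsq_fit <- function(times, n_exp = 2L, n_bins = NULL,
                     region = c(1, 1000), grid_factor = 10) {
  times <- check_dwell_times(times, min_n = 4L)
  n_exp <- check_count(n_exp, 1L, "n_exp")
  h <- bin_sample(times, n_bins)
  out <- nlsq_fit_counts(h$edges, h$counts, h$T, n_exp, region, grid_factor)
  out$histogram <- h
  out$call <- match.call()
  out
}

# LM multi-start core on explicit histogram counts; nlsq_fit wraps it.
nlsq_fit_counts <- function(edges, counts, T, n_exp = 2L,
                            region = c(1, 1000), grid_factor = 10) {
  starts <- start_grid(n_exp, region, grid_factor)
  resid_fn <- function(theta) counts - nlsq_model_safe(edges, T, theta)
  best <- NULL
  converged <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    if (ok) converged <- converged + 1L
    cand <- list(par = sort(res$par), rss = res$deviance, ok = ok)
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best))
    best <- list(par = rep(NA_real_, n_exp), rss = NA_real_, ok = FALSE)
  runaway <- any(!is.finite(best$par)) ||
    any(abs(best$par) > 1e4 * max(edges))
  flagged <- !best$ok || converged == 0L || runaway ||
    any(!is.finite(best$par)) || any(best$par <= 0)
  structure(list(estimates = best$par, rss = best$rss,
                 converged = best$ok, negative_or_failed = flagged,
                 histogram = list(edges = edges, counts = counts, T = T),
                 n_exp = n_exp,
                 n_starts = nrow(starts), converged_starts = converged,
                 T = T, call = match.call()),
            class = "nlsq_fit")
}

#' @export
print.nlsq_fit <- function(x, digits = 6L, ...) {
  cat(sprintf("NL-LSQM fit: %d-exponential model, %d bins, T = %d\n",
              x$n_exp, length(x$histogram$counts), x$T))
  cat("Decay parameter estimates (s, sorted):\n")
  print(signif(x$estimates, digits))
  cat(sprintf("RSS = %.6g; %d/%d starts converged\n",
              x$rss, x$converged_starts, x$n_starts))
  if (x$negative_or_failed)
    cat("Flagged: negative, runaway or non-converged estimate(s)\n")
  invisible(x)
}

#' @export
coef.nlsq_fit <- function(object, ...) {
  stats::setNames(object$estimates, paste0("tau", seq_len(object$n_exp)))
}

#' @export
residuals.nlsq_fit <- function(object, ...) {
  object$histogram$counts -
    nlsq_model_safe(object$histogram$edges, object$T, object$estimates)
}
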