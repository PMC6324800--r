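## S3 methods for "gmm_fit" objects.

#' @export
print.gmm_fit <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat(sprintf("GMM fit: %d-step scheme, order %d, %s weights%s\n",
              x$n_steps, x$order, x$weight_scheme,
              if (x$passes > 1L) sprintf(" (%d passes)", x$passes) else ""))
  cat("Decay parameter estimates (s, sorted):\n")
  print(signif(x$estimates, digits))
  cat(sprintf("Q_min = %.6g on %d dwell times\n", x$Q_min, x$T))
  if (x$double_root)
    cat("Note: double root -- the just-specified classical solution is complex here\n")
  if (any(x$estimates <= 0))
    cat("Note: nonpositive estimate(s) -- likely overfit (too many model steps)\n")
  invisible(x)
}

#' @export
coef.gmm_fit <- function(object, ...) {
  stats::setNames(object$estimates, paste0("tau", seq_len(object$n_steps)))
}

#' Moment-function residuals of a GMM fit
#'
#' Returns `g_m = kappa^(m)(hat tau) - k^(m)(t, T)` for `m = 1..order` at
#' the fitted parameters: the amount by which each moment condition is
#' missed. For a just-specified fit with a real classical solution these
#' are numerically zero.
#'
#' @param object A `gmm_fit`.
#' @param ... Unused.
#' @return Named numeric vector of length `order` (units s^m).
#' @export
residuals.gmm_fit <- function(object, ...) {
  g <- pop_cumulants_raw(object$estimates, object$order) - object$kstats
  stats::setNames(g, paste0("g", seq_len(object$order)))
}

#' @export
summary.gmm_fit <- function(object, ...) {
  structure(list(fit = object,
                 residuals = residuals(object),
                 kappa_hat = pop_cumulants_raw(object$estimates, object$order)),
            class = "summary.gmm_fit")
}

#' @export
print.summary.gmm_fit <- function(x, digits = 6L, ...) {
  print(x$fit, digits = digits)
  cat("\nSample k-statistics vs fitted population cumulants:\n")
  tab <- cbind(`k^(m)` = x$fit$kstats, `kappa^(m)` = x$kappa_hat,
               `g_m` = x$residuals)
  rownames(tab) <- paste0("m=", seq_len(x$fit$order))
  print(signif(tab, digits))
  cat(sprintf("\nStarts: %d (%d converged); weight scheme: %s\n",
              x$fit$n_starts, x$fit$converged_starts, x$fit$weight_scheme))
  invisible(x)
}

#' Fitted dwell-time density or distribution
#'
#' Evaluates the density (or CDF) of the fitted sum-of-exponentials scheme.
#' Only available when every estimate is positive (a negative constant is
#' an overfit diagnostic, not a distribution).
#'
#' @param object A `gmm_fit`.
#' @param newdata Times at which to evaluate (seconds); defaults to an even
#'   grid over the data range.
#' @param type `"density"` or `"cdf"`.
#' @param ... Unused.
#' @return Numeric vector of the same length as `newdata`.
#' @export
predict.gmm_fit <- function(object, newdata = NULL,
                            type = c("density", "cdf"), ...) {
  type <- match.arg(type)
  if (any(object$estimates <= 0))
    stop("fitted scheme has nonpositive decay parameters; no density exists",
         call. = FALSE)
  if (is.null(newdata))
    newdata <- seq(0, max(object$times), length.out = 200L)
  if (type == "density") density_hypoexp(newdata, object$estimates)
  else cdf_hypoexp(newdata, object$estimates)
}

#' Simulate dwell times from a fitted scheme
#'
#' @param object A `gmm_fit` with all-positive estimates.
#' @param nsim Number of samples to generate.
#' @param seed Optional integer seed.
#' @param n Size of each sample; defaults to the fitted sample size.
#' @param ... Unused.
#' @return A list of `nsim` dwell-time vectors.
#' @export
simulate.gmm_fit <- function(object, nsim = 1, seed = NULL, n = object$T, ...) {
  if (any(object$estimates <= 0))
    stop("fitted scheme has nonpositive decay parameters; cannot simulate",
         call. = FALSE)
  lapply(seq_len(nsim), function(i)
    simulate_irreversible(object$estimates, n, seed = trial_seed(seed, i)))
}

#' Plot a GMM fit against the dwell-time histogram
#'
#' Density-scaled histogram of the data with the fitted sum-of-exponentials
#' density overlaid.
#'
#' @param x A `gmm_fit`.
#' @param breaks Passed to [graphics::hist()]; defaults to the square-root
#'   rule used by the NL-LSQM comparator.
#' @param ... Further arguments for `hist`.
#' @return `x`, invisibly.
#' @export
plot.gmm_fit <- function(x, breaks = NULL, ...) {
  if (is.null(breaks)) breaks <- ceiling(sqrt(x$T))
  h <- hist(x$times, breaks = breaks, freq = FALSE,
            main = sprintf("%d-step GMM fit (order %d)", x$n_steps, x$order),
            xlab = "dwell time (s)", ...)
  if (all(x$estimates > 0)) {
    tt <- seq(0, max(x$times), length.out = 400L)
    graphics::lines(tt, density_hypoexp(tt, x$estimates), col = 2, lwd = 2)
    legend("topright", legend = sprintf("tau%d = %.3g s",
                                        seq_along(x$estimates), x$estimates),
           bty = "n", text.col = 2)
  }
  invisible(x)
}
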