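## Classical Method of Moments: solve the just-specified moment equations
## g_m = 0 (m = 1..n) exactly. Setting each population cumulant equal to
## its k-statistic gives the power sums of the decay parameters,
##   p_m = sum_j tau_j^m = k^(m) / (m-1)!,
## from which Newton's identities yield the elementary symmetric
## polynomials and hence a degree-n polynomial whose roots are the
## parameter estimates. The roots may be complex -- that failure mode is
## exactly what distinguishes the CMM from the GMM.

#' Solve the classical method of moments for an n-step scheme
#'
#' Converts the sample k-statistics to power sums, applies Newton's
#' identities, and extracts the roots of the resulting monic polynomial via
#' the companion-matrix root finder ([base::polyroot()]). Roots with
#' `|Im| <= 1e-8 * (1 + |Re|)` are classed as real (root finders return
#' tiny spurious imaginary parts). Real-but-negative roots are reported
#' with `all_real = TRUE` and flagged: negativity is information (an
#' overfit diagnostic), not an error.
#'
#' @param times Dwell-time sample.
#' @param n_steps Number of steps (1..4; higher orders would need
#'   k-statistics beyond order 4).
#' @return An object of class `"cmm_result"`: list with `roots` (complex,
#'   sorted by real part), `all_real`, `estimates` (sorted real parts when
#'   `all_real`, else `NULL`), `any_negative`, `kstats`, `n_steps`, `T`.
#' @examples
#' cmm_solve(c(1, 2, 3), 1)       # the sample mean
#' cmm_solve(c(10, 10, 10), 2)    # complex pair 5 +/- 5i
#' @export
cmm_solve <- function(times, n_steps) {
  n_steps <- check_order(n_steps, arg = "n_steps")
  times <- check_dwell_times(times)
  k <- k_statistics(times, n_steps)
  p <- k / factorial(seq_len(n_steps) - 1)      # power sums
  e <- newton_identities(p)
  # monic polynomial x^n - e1 x^(n-1) + e2 x^(n-2) - ... ; polyroot wants
  # ascending coefficients
  coefs <- c(rev((-1)^seq_len(n_steps) * e), 1)
  roots <- if (n_steps == 1L) complex(real = e[1]) else polyroot(coefs)
  roots <- roots[order(Re(roots), Im(roots))]
  real <- abs(Im(roots)) <= 1e-8 * (1 + abs(Re(roots)))
  all_real <- all(real)
  est <- if (all_real) sort(Re(roots)) else NULL
  structure(list(roots = roots, all_real = all_real, estimates = est,
                 any_negative = all_real && any(est <= 0),
                 kstats = k, n_steps = n_steps, T = length(times)),
            class = "cmm_result")
}

# elementary symmetric polynomials e_1..e_n from power sums p_1..p_n
newton_identities <- function(p) {
  n <- length(p)
  e <- numeric(n)
  for (m in seq_len(n)) {
    acc <- p[m] * (-1)^(m - 1)
    if (m > 1) for (j in seq_len(m - 1))
      acc <- acc + (-1)^(j - 1) * e[m - j] * p[j]
    e[m] <- acc / m
  }
  e
}

#' @export
print.cmm_result <- function(x, digits = 6L, ...) {
  cat(sprintf("Classical method of moments, %d-step scheme (T = %d)\n",
              x$n_steps, x$T))
  if (x$all_real) {
    cat("Real solution (s, sorted):\n")
    print(signif(x$estimates, digits))
    if (x$any_negative)
      cat("Note: nonpositive root(s) -- overfit diagnostic\n")
  } else {
    cat("No real solution; complex roots:\n")
    print(signif(x$roots, digits))
  }
  invisible(x)
}

#' @export
coef.cmm_result <- function(object, ...) {
  if (object$all_real) object$estimates else object$roots
}

#' Consistency check between just-specified GMM and CMM
#'
#' The just-specified GMM coincides with the CMM whenever the latter has a
#' real solution, and (for two steps) must return a double root when it
#' does not. This check compares a `gmm_fit` at order `n_steps` with the
#' Newton-identities CMM solution on the same sample.
#'
#' @param times Dwell-time sample.
#' @param n_steps Model order of both estimators.
#' @param fit A just-specified [gmm_fit()] on `times` (computed with
#'   defaults when omitted).
#' @param tol Relative agreement tolerance.
#' @return An object of class `"cmm_gmm_check"`: list with `all_real`,
#'   `agrees` (estimate agreement when real), `double_root_ok` (double-root
#'   flag when complex, two-step case), `max_rel_err`, `passed`.
#' @export
cmm_gmm_consistency_check <- function(times, n_steps,
                                      fit = gmm_fit(times, n_steps),
                                      tol = 1e-6) {
  stopifnot(inherits(fit, "gmm_fit"))
  if (fit$order != n_steps || fit$n_steps != n_steps)
    stop("`fit` must be just-specified at order `n_steps`", call. = FALSE)
  cmm <- cmm_solve(times, n_steps)
  agrees <- NA; dr_ok <- NA; err <- NA_real_
  if (cmm$all_real) {
    err <- max(abs(fit$estimates - cmm$estimates) / (1 + abs(cmm$estimates)))
    agrees <- err <= tol
  } else if (n_steps == 2L) {
    dr_ok <- isTRUE(fit$double_root)
  }
  passed <- (isTRUE(agrees) || is.na(agrees)) && (isTRUE(dr_ok) || is.na(dr_ok))
  structure(list(all_real = cmm$all_real, agrees = agrees,
                 double_root_ok = dr_ok, max_rel_err = err,
                 cmm = cmm, gmm = fit, passed = passed),
            class = "cmm_gmm_check")
}

#' @export
print.cmm_gmm_check <- function(x, ...) {
  cat("GMM/CMM consistency check:",
      if (x$passed) "PASS" else "FAIL", "\n")
  if (x$all_real)
    cat(sprintf("  real CMM solution; max relative disagreement %.3g\n",
                x$max_rel_err))
  else
    cat(sprintf("  complex CMM solution; GMM double root: %s\n",
                if (isTRUE(x$double_root_ok)) "yes"
                else if (is.na(x$double_root_ok)) "n/a" else "NO"))
  invisible(x)
}
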