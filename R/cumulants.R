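## Cumulant machinery: central moments, unbiased sample cumulants
## (k-statistics), population cumulants of n-step schemes, and the moment
## functions g_m = kappa^(m) - k^(m) that the GMM objective is built from.
##
## Orders above 4 are deliberately unsupported: the unique unbiased
## cumulant estimators are implemented to 4th order and higher-order
## extensions would silently change the estimator's bias properties.

#' Central sample moments with divisor T
#'
#' `central_moments(t, 1)` is the sample mean; for `l > 1` it returns
#' `mean((t - mean(t))^l)` (divisor `T`, the convention the k-statistic
#' prefactors assume).
#'
#' @param times Numeric vector of dwell times.
#' @param l Moment order, a positive integer (vectorised over `l`).
#' @return Numeric vector of the requested central moments.
#' @export
central_moments <- function(times, l) {
  times <- check_dwell_times(times)
  if (!is.numeric(l) || any(l < 1) || any(l != round(l)))
    stop("moment order `l` must consist of positive integers", call. = FALSE)
  m1 <- mean(times)
  vapply(as.integer(l), function(ll)
    if (ll == 1L) m1 else mean((times - m1)^ll), numeric(1))
}

#' Unbiased sample cumulants (k-statistics) up to order 4
#'
#' The k-statistic of order m is the unique symmetric unbiased estimator of
#' the m-th cumulant. With central moments `m_l` (divisor T):
#' \deqn{k^{(1)} = m_1,\quad k^{(2)} = \frac{T}{T-1} m_2,\quad
#'   k^{(3)} = \frac{T^2}{(T-1)(T-2)} m_3,}
#' \deqn{k^{(4)} = \frac{T^2\left[(T+1) m_4 - 3 (T-1) m_2^2\right]}
#'   {(T-1)(T-2)(T-3)}.}
#'
#' @param times Numeric vector of dwell times; needs `T >= M` observations
#'   (`T >= 4` for `M = 4`) so the denominators are nonzero.
#' @param M Maximum order, an integer in 1..4.
#' @return Numeric vector `k` of length `M`, `k[m]` the order-m k-statistic
#'   (units s^m).
#' @examples
#' k_statistics(c(1, 2, 3), 3)  # c(2, 1, 0): mean, unbiased variance, ...
#' @export
k_statistics <- function(times, M = 4L) {
  M <- check_order(M)
  times <- check_dwell_times(times)
  T <- length(times)
  if (T < min_T_for_order(M))
    stop(sprintf("sample size T = %d is below the minimum T = %d for order-%d k-statistics",
                 T, min_T_for_order(M), M), call. = FALSE)
  m <- central_moments(times, seq_len(max(M, 1L)))
  k_from_central(m, T, M)
}

# k-statistics from central moments (divisor T) and sample size.
k_from_central <- function(m, T, M) {
  k <- numeric(M)
  k[1] <- m[1]
  if (M >= 2) k[2] <- T / (T - 1) * m[2]
  if (M >= 3) k[3] <- T^2 / ((T - 1) * (T - 2)) * m[3]
  if (M >= 4) k[4] <- T^2 * ((T + 1) * m[4] - 3 * (T - 1) * m[2]^2) /
      ((T - 1) * (T - 2) * (T - 3))
  k
}

# Row-wise k-statistics for a matrix of samples (trials in rows). Vectorised
# across trials; used by the Monte-Carlo covariance and the bias studies.
k_statistics_rows <- function(X, M) {
  M <- check_order(M)
  T <- ncol(X)
  if (T < min_T_for_order(M))
    stop(sprintf("sample size T = %d too small for order %d", T, M), call. = FALSE)
  m1 <- rowMeans(X)
  C <- X - m1
  K <- matrix(0, nrow(X), M)
  K[, 1] <- m1
  if (M >= 2) { m2 <- rowMeans(C^2); K[, 2] <- T / (T - 1) * m2 }
  if (M >= 3) K[, 3] <- T^2 / ((T - 1) * (T - 2)) * rowMeans(C^3)
  if (M >= 4) K[, 4] <- T^2 * ((T + 1) * rowMeans(C^4) - 3 * (T - 1) * m2^2) /
      ((T - 1) * (T - 2) * (T - 3))
  K
}

# Leave-one-out k-statistics, one row per deleted observation. Computed from
# downdated power sums of the values centred on the full-sample mean, which
# keeps the arithmetic well conditioned and the whole sweep O(T) per order.
k_statistics_loo <- function(times, M) {
  M <- check_order(M)
  T <- length(times)
  if (T - 1L < min_T_for_order(M))
    stop(sprintf("jackknife at order %d needs T >= %d (leave-one-out subsamples must support the k-statistics)",
                 M, min_T_for_order(M) + 1L), call. = FALSE)
  u <- times - mean(times)
  Tm <- T - 1L
  U <- vapply(seq_len(M), function(j) sum(u^j), numeric(1))  # U[1] == 0
  # subsample mean (of centred values) after deleting u_i:
  d <- -u / Tm
  # subsample central power sums about the full mean: S_j = U_j - u_i^j
  # central moments about the subsample's own mean via binomial expansion:
  #   m_l = (1/Tm) * sum_{j=0}^{l} choose(l, j) S_j (-d)^(l-j),  S_0 = Tm
  mom <- matrix(0, T, M)
  for (l in seq_len(M)) {
    acc <- Tm * (-d)^l                       # j = 0 term
    for (j in seq_len(l))
      acc <- acc + choose(l, j) * (U[j] - u^j) * (-d)^(l - j)
    mom[, l] <- acc / Tm
  }
  K <- matrix(0, T, M)
  K[, 1] <- mean(times) + d                  # subsample mean (order 1 is not central)
  if (M >= 2) K[, 2] <- Tm / (Tm - 1) * mom[, 2]
  if (M >= 3) K[, 3] <- Tm^2 / ((Tm - 1) * (Tm - 2)) * mom[, 3]
  if (M >= 4) K[, 4] <- Tm^2 * ((Tm + 1) * mom[, 4] - 3 * (Tm - 1) * mom[, 2]^2) /
      ((Tm - 1) * (Tm - 2) * (Tm - 3))
  K
}

#' Population cumulants of an n-step irreversible scheme
#'
#' Cumulants add over independent steps and the order-m cumulant of an
#' exponential step with mean `tau` is `(m-1)! tau^m`, so
#' \deqn{\kappa^{(m)} = (m-1)!\,\sum_j \tau_j^m.}
#'
#' @param taus Positive decay parameters, one per step (seconds).
#' @param M Maximum order (positive integer; any order is defined for the
#'   population quantity, but the estimator side caps at 4).
#' @return Numeric vector of cumulants of orders 1..M (units s^m).
#' @export
population_cumulants <- function(taus, M = 4L) {
  taus <- check_taus(taus)
  M <- check_count(M, 1L, "M")
  vapply(seq_len(M), function(m) factorial(m - 1) * sum(taus^m), numeric(1))
}

#' Generalized moment functions
#'
#' The order-m moment function is the population cumulant of the candidate
#' scheme minus the sample k-statistic,
#' \eqn{g_m = \kappa^{(m)}(\tau) - k^{(m)}(t, T)}; it has zero expectation at
#' the true parameters because the k-statistics are unbiased.
#'
#' @inheritParams k_statistics
#' @param taus Candidate decay parameters (seconds).
#' @return Numeric vector `g` of length `M` (units s^m per element).
#' @export
moment_functions <- function(taus, times, M = 4L) {
  population_cumulants(taus, M) - k_statistics(times, M)
}
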