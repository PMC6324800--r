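## Simulation of dwell-time samples and the analytic biexponential density.
##
## A dwell time of an n-step irreversible scheme is the sum of n independent
## exponential residence times with means tau_1..tau_n.  A two-step scheme
## with a reversible first step has a total dwell time whose density is
## exactly the two-exponential convolution of the decay constants obtained
## from the rate map (see rates_to_decay), so it is simulated through that
## map rather than by trajectory simulation.

#' Simulate dwell times of an n-step irreversible reaction
#'
#' Each dwell time is an independent sum of `length(taus)` exponential draws
#' with means `taus` (seconds).
#'
#' @param taus Numeric vector of positive decay parameters, one per step,
#'   in seconds.
#' @param n Number of dwell times to draw.
#' @param seed Optional integer seed; identical inputs and seed reproduce the
#'   sample bit-exactly. The caller's RNG state is left untouched when a seed
#'   is supplied.
#' @return Numeric vector of `n` strictly positive dwell times (seconds).
#' @examples
#' t <- simulate_irreversible(c(10, 50), 1000, seed = 1)
#' mean(t)  # close to 60
#' @seealso [simulate_reversible()], [population_cumulants()]
#' @export
simulate_irreversible <- function(taus, n, seed = NULL) {
  taus <- check_taus(taus)
  n <- check_count(n, 1L, "n")
  with_seed(seed, {
    out <- numeric(n)
    for (tau in taus) out <- out + rexp(n, rate = 1 / tau)
    out
  })
}

#' Simulate dwell times of a two-step scheme with a reversible first step
#'
#' Transition rates `k1` (A -> B), `k2` (B -> A) and `k3` (B -> final)
#' determine two effective decay constants via [rates_to_decay()]; the total
#' dwell time is distributed as the convolution of two exponentials with
#' those constants, which is drawn directly.
#'
#' @param k1,k2,k3 Transition rates in 1/seconds; `k1 > 0`, `k3 > 0`,
#'   `k2 >= 0` (`k2 = 0` recovers the irreversible two-step scheme).
#' @inheritParams simulate_irreversible
#' @return Numeric vector of `n` dwell times (seconds).
#' @export
simulate_reversible <- function(k1, k2, k3, n, seed = NULL) {
  taus <- rates_to_decay(k1, k2, k3)
  simulate_irreversible(c(taus[["tau_A"]], taus[["tau_B"]]), n, seed = seed)
}

#' Map reversible two-step rates to effective decay constants
#'
#' The inverse decay constants are the two roots
#' \deqn{1/\tau = (k_1+k_2+k_3)/2 \pm \sqrt{(k_1+k_2+k_3)^2/4 - k_1 k_3},}
#' the plus sign giving the faster step \eqn{\tau_B} and the minus sign the
#' slower \eqn{\tau_A}. The roots satisfy
#' \eqn{1/\tau_A + 1/\tau_B = k_1+k_2+k_3} and
#' \eqn{(1/\tau_A)(1/\tau_B) = k_1 k_3}.
#'
#' @inheritParams simulate_reversible
#' @return Named numeric vector `c(tau_A =, tau_B =)` in seconds, with
#'   `tau_B <= tau_A`.
#' @examples
#' rates_to_decay(0.1, 0, 0.02)  # tau_A = 50, tau_B = 10
#' @export
rates_to_decay <- function(k1, k2, k3) {
  for (nm in c("k1", "k2", "k3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("`%s` must be a single finite rate", nm), call. = FALSE)
  }
  if (k1 <= 0 || k3 <= 0 || k2 < 0)
    stop("rates must satisfy k1 > 0, k3 > 0, k2 >= 0", call. = FALSE)
  s <- (k1 + k2 + k3) / 2
  disc <- s^2 - k1 * k3          # >= 0 for all nonnegative real rates
  root <- sqrt(max(disc, 0))
  c(tau_A = 1 / (s - root), tau_B = 1 / (s + root))
}

#' Biexponential dwell-time probability density
#'
#' Density of the sum of two independent exponential dwell times,
#' \deqn{p(t) = \frac{e^{-t/\tau_A} - e^{-t/\tau_B}}{\tau_A - \tau_B},}
#' switching to the degenerate branch \eqn{t/\tau^2 e^{-t/\tau}} when the two
#' constants agree to within a relative tolerance of 1e-6 (the removable
#' singularity would otherwise cancel catastrophically).
#'
#' @param t Vector of times (seconds), all `>= 0`.
#' @param tau_A,tau_B Positive decay constants (seconds); the density is
#'   symmetric in the two.
#' @return Vector of density values (1/seconds).
#' @export
density_biexp <- function(t, tau_A, tau_B) {
  check_taus(c(tau_A, tau_B), "tau_A/tau_B")
  if (!is.numeric(t) || anyNA(t) || any(t < 0))
    stop("`t` must be numeric and nonnegative", call. = FALSE)
  if (abs(tau_A - tau_B) / max(tau_A, tau_B) < 1e-6) {
    tau <- (tau_A + tau_B) / 2
    t / tau^2 * exp(-t / tau)
  } else {
    (exp(-t / tau_A) - exp(-t / tau_B)) / (tau_A - tau_B)
  }
}

# Cumulative distribution of the biexponential density, same degenerate
# handling as density_biexp. Used by the bin-integrated NL-LSQM model.
cdf_biexp <- function(t, tau_A, tau_B) {
  if (abs(tau_A - tau_B) / max(tau_A, tau_B) < 1e-6) {
    tau <- (tau_A + tau_B) / 2
    1 - (1 + t / tau) * exp(-t / tau)
  } else {
    1 - (tau_A * exp(-t / tau_A) - tau_B * exp(-t / tau_B)) / (tau_A - tau_B)
  }
}

# Density and CDF of a sum of n independent exponentials with distinct means
# (hypoexponential), by partial fractions:
#   p(t) = sum_j w_j exp(-t/tau_j)/tau_j,  w_j = prod_{l != j} tau_j/(tau_j - tau_l).
# Near-ties are split by a tiny relative perturbation; exact for n <= 2 via
# the dedicated biexponential branches.
hypoexp_part <- function(taus) {
  taus <- sort(taus)
  n <- length(taus)
  # nudge ties apart; keeps weights finite, error O(eps) in the density
  eps <- 1e-7 * max(taus)
  for (j in seq_len(n - 1))
    if (taus[j + 1] - taus[j] < eps) taus[j + 1] <- taus[j] + eps
  w <- vapply(seq_len(n), function(j)
    prod(taus[j] / (taus[j] - taus[-j])), numeric(1))
  list(taus = taus, w = w)
}

density_hypoexp <- function(t, taus) {
  taus <- check_taus(taus)
  if (length(taus) == 1L) return(exp(-t / taus) / taus)
  if (length(taus) == 2L) return(density_biexp(t, taus[1], taus[2]))
  pp <- hypoexp_part(taus)
  out <- numeric(length(t))
  for (j in seq_along(pp$taus))
    out <- out + pp$w[j] * exp(-t / pp$taus[j]) / pp$taus[j]
  out
}

cdf_hypoexp <- function(t, taus) {
  taus <- check_taus(taus)
  if (length(taus) == 1L) return(1 - exp(-t / taus))
  if (length(taus) == 2L) return(cdf_biexp(t, taus[1], taus[2]))
  pp <- hypoexp_part(taus)
  out <- rep(1, length(t))
  for (j in seq_along(pp$taus))
    out <- out - pp$w[j] * exp(-t / pp$taus[j])
  out
}
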