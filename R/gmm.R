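## The GMM estimator. The objective is the quadratic form
##   Q(tau) = g' W g,   g_m = kappa^(m)(tau) - k^(m)(t, T),
## with the weight matrix built once from the sample (or a covariance
## table) and held fixed during minimisation. Because kappa^(m) is a
## polynomial in the candidate parameters, Q is a smooth multi-polynomial
## surface; the global minimum is located by quasi-Newton (BFGS) descent
## from a logarithmically spaced grid of starting points, with the analytic
## gradient
##   dQ/dtau_j = 2 sum_m (W g)_m * m! * tau_j^(m-1).
## Candidate parameters are deliberately unconstrained in sign: negative
## returned constants are the standard overfit diagnostic in the
## model-order scan.

# population cumulants without a positivity check -- the optimizer and the
# diagnostics must be able to evaluate the polynomial at any real tau
pop_cumulants_raw <- function(taus, M) {
  vapply(seq_len(M), function(m) factorial(m - 1) * sum(taus^m), numeric(1))
}

#' GMM objective function
#'
#' `Q = g' W g` with `g` the moment functions of `taus` against the sample's
#' k-statistics. Nonnegative for any positive semi-definite `W`, and zero
#' exactly at a real classical-method-of-moments solution when the order
#' equals the number of steps.
#'
#' @param taus Candidate decay parameters (any real values; the population
#'   cumulant polynomial is evaluated as-is).
#' @param times Dwell-time sample.
#' @param W Weight matrix, `M x M`; `M` is taken from its dimension.
#' @return The scalar objective value.
#' @export
gmm_objective <- function(taus, times, W) {
  M <- ncol(as.matrix(W))
  k <- k_statistics(times, M)
  g <- pop_cumulants_raw(taus, M) - k
  drop(crossprod(g, W %*% g))
}

#' Analytic gradient of the GMM objective
#'
#' `dQ/dtau_j = 2 sum_m (W g)_m m! tau_j^(m-1)`, the chain rule through the
#' cumulant polynomial with the weight matrix held fixed.
#'
#' @inheritParams gmm_objective
#' @return Numeric gradient, one element per decay parameter.
#' @export
gmm_gradient <- function(taus, times, W) {
  M <- ncol(as.matrix(W))
  k <- k_statistics(times, M)
  g <- pop_cumulants_raw(taus, M) - k
  gmm_grad_core(taus, g, W, M)
}

gmm_grad_core <- function(taus, g, W, M) {
  wg <- as.vector(W %*% g)
  fm <- factorial(seq_len(M))                       # m!
  # outer(taus, m) powers tau^(m-1)
  P <- outer(taus, seq_len(M) - 1, `^`)
  2 * as.vector(P %*% (fm * wg))
}

#' Optimiser settings for [gmm_fit()]
#'
#' @param reltol Relative function-reduction tolerance passed to
#'   [stats::optim()]'s BFGS.
#' @param maxit Iteration cap per start.
#' @param double_root_tol Relative tolerance under which two adjacent sorted
#'   estimates are flagged as a double root.
#' @param tie_tol Relative Q tolerance under which multi-start minima count
#'   as tied; ties resolve to the lexicographically smallest sorted
#'   estimate vector (determinism).
#' @return A list of class `gmm_control`.
#' @export
gmm_control <- function(reltol = 1e-12, maxit = 500L,
                        double_root_tol = 1e-4, tie_tol = 1e-12) {
  structure(list(reltol = reltol, maxit = as.integer(maxit),
                 double_root_tol = double_root_tol, tie_tol = tie_tol),
            class = "gmm_control")
}

# log-spaced start grid over region^n_steps with the given multiplicative
# spacing; unordered duplicates pruned (Q is permutation symmetric).
start_grid <- function(n_steps, region, grid_factor) {
  pts <- 10^seq(log10(region[1]), log10(region[2]) + 1e-9,
                by = log10(grid_factor))
  grid <- as.matrix(expand.grid(rep(list(pts), n_steps),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  sorted <- t(apply(grid, 1, sort))
  if (n_steps == 1L) sorted <- matrix(grid, ncol = 1)
  grid[!duplicated(sorted), , drop = FALSE]
}

# core minimisation shared by gmm_fit and the second pass: multi-start BFGS
# over precomputed k-statistics, with one polish restart from the winner.
gmm_minimize <- function(kstats, M, W, starts, control) {
  fm <- factorial(seq_len(M))
  fn <- function(tau) {
    g <- pop_cumulants_raw(tau, M) - kstats
    drop(crossprod(g, W %*% g))
  }
  gr <- function(tau) {
    g <- pop_cumulants_raw(tau, M) - kstats
    2 * as.vector(outer(tau, seq_len(M) - 1, `^`) %*% (fm * as.vector(W %*% g)))
  }
  best <- NULL
  converged <- 0L
  for (s in seq_len(nrow(starts))) {
    st <- starts[s, ]
    res <- tryCatch(
      optim(st, fn, gr, method = "BFGS",
            control = list(reltol = control$reltol, maxit = control$maxit,
                           parscale = pmax(abs(st), 1))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) converged <- converged + 1L
    cand <- list(par = sort(res$par), value = res$value,
                 convergence = res$convergence)
    if (is.null(best)) { best <- cand; next }
    if (cand$value < best$value * (1 - control$tie_tol) ||
        (abs(cand$value - best$value) <=
           control$tie_tol * max(abs(best$value), .Machine$double.xmin) &&
         lex_less(cand$par, best$par)))
      best <- cand
  }
  if (is.null(best))
    stop("GMM optimisation failed from every starting point", call. = FALSE)
  # polish: one more descent from the winner tightens the minimum
  res <- tryCatch(
    optim(best$par, fn, gr, method = "BFGS",
          control = list(reltol = control$reltol, maxit = control$maxit,
                         parscale = pmax(abs(best$par), 1))),
    error = function(e) NULL)
  if (!is.null(res) && res$value <= best$value)
    best <- list(par = sort(res$par), value = res$value,
                 convergence = res$convergence)
  best$converged_starts <- converged
  best
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Fit an n-step dwell-time model by the Generalized Method of Moments
#'
#' Estimates the decay parameters of an n-step irreversible reaction scheme
#' (equivalently, the effective decay constants of a two-step reversible
#' scheme) from a sample of dwell times by minimising the weighted quadratic
#' form of cumulant moment functions. The weight matrix is built once from
#' the sample according to `weights` and held fixed; minimisation is BFGS
#' with the analytic gradient from every point of a log-spaced start grid.
#'
#' @param times Dwell-time sample (strictly positive; seconds by
#'   convention).
#' @param n_steps Number of steps in the candidate scheme (1..4).
#' @param order Number of moment conditions M, `n_steps <= order <= 4`.
#'   `order = n_steps` is the just-specified case, which coincides with the
#'   classical method of moments whenever the latter has a real solution.
#' @param weights Weighting scheme: `"jackknife_diag"` (the D-matrix;
#'   default, lowest bias in simulation studies), `"identity"`,
#'   `"jackknife_full"` (C-matrix), or `"mc_interp"` (inverse of a
#'   covariance interpolated from `cov_table` at `interp_at`).
#' @param cov_table A [build_covariance_table()] result; required for
#'   `weights = "mc_interp"`.
#' @param interp_at Decay parameters at which to interpolate the MC
#'   covariance (e.g. a previous fit's estimates); required for
#'   `weights = "mc_interp"`.
#' @param region Two positive numbers: the per-dimension search region for
#'   the start grid, default `c(1, 1000)` seconds. Choose roughly one
#'   decade beyond the plausible extremes of the data.
#' @param grid_factor Multiplicative spacing of the start grid (default 10).
#' @param control A [gmm_control()] list.
#' @return An object of class `"gmm_fit"`: a list with sorted `estimates`
#'   (seconds), the minimised objective `Q_min`, `order`, `n_steps`,
#'   `weight_scheme`, the weight matrix `W`, sample k-statistics `kstats`,
#'   sample size `T`, start-grid diagnostics, `double_root` flag, and the
#'   data. Supports `print`, `summary`, `coef`, `residuals`, `predict`,
#'   `simulate` and `plot`.
#' @examples
#' t <- simulate_irreversible(c(10, 50), 500, seed = 42)
#' fit <- gmm_fit(t, n_steps = 2)
#' coef(fit)
#' @seealso [cmm_solve()], [gmm_two_pass()], [nlsq_fit()]
#' @export
gmm_fit <- function(times, n_steps, order = n_steps,
                    weights = c("jackknife_diag", "identity",
                                "jackknife_full", "mc_interp"),
                    cov_table = NULL, interp_at = NULL,
                    region = c(1, 1000), grid_factor = 10,
                    control = gmm_control()) {
  times <- check_dwell_times(times)
  n_steps <- check_count(n_steps, 1L, "n_steps")
  order <- check_order(order)
  if (order < n_steps)
    stop("`order` must be >= `n_steps` (fewer moment conditions than parameters is under-specified)",
         call. = FALSE)
  weights <- match.arg(weights)
  if (length(region) != 2L || any(region <= 0) || region[2] <= region[1])
    stop("`region` must be c(low, high) with 0 < low < high", call. = FALSE)
  T <- length(times)
  if (T < min_T_for_order(order))
    stop(sprintf("sample size T = %d too small for order %d", T, order),
         call. = FALSE)

  W <- build_weight(times, order, weights, cov_table, interp_at)
  kst <- k_statistics(times, order)
  starts <- start_grid(n_steps, region, grid_factor)
  best <- gmm_minimize(kst, order, W, starts, control)

  est <- best$par
  dr <- n_steps > 1L &&
    any(diff(est) < control$double_root_tol * pmax(abs(est[-1]), abs(est[-n_steps]),
                                                   .Machine$double.eps))
  structure(list(estimates = est, Q_min = max(best$value, 0),
                 n_steps = n_steps, order = order,
                 weight_scheme = attr(W, "scheme"), W = W,
                 kstats = kst, T = T, times = times,
                 n_starts = nrow(starts),
                 converged_starts = best$converged_starts,
                 double_root = dr, passes = 1L,
                 region = region, grid_factor = grid_factor,
                 control = control, call = match.call()),
            class = "gmm_fit")
}

build_weight <- function(times, order, weights, cov_table, interp_at) {
  switch(weights,
    identity = identity_weight(order),
    jackknife_diag = invert_to_weight(
      jackknife_cumulant_covariance(times, order, diagonal_only = TRUE)),
    jackknife_full = invert_to_weight(
      jackknife_cumulant_covariance(times, order, diagonal_only = FALSE)),
    mc_interp = {
      if (is.null(cov_table) || is.null(interp_at))
        stop("`weights = \"mc_interp\"` needs both `cov_table` and `interp_at`",
             call. = FALSE)
      if (cov_table$M < order)
        stop("covariance table order is below the requested fit order", call. = FALSE)
      v <- interpolate_covariance(cov_table, interp_at, length(times))
      invert_to_weight(structure(v[seq_len(order), seq_len(order), drop = FALSE],
                                 scheme = "mc_interp"))
    })
}

#' Two-pass GMM
#'
#' Pass 1 fits with a simple data-driven weight (default: just-specified
#' order with the diagonal jackknife D-matrix). Pass 2 inverts the
#' Monte-Carlo covariance interpolated at the pass-1 estimates and
#' re-minimises from the single starting point given by those estimates.
#'
#' @inheritParams gmm_fit
#' @param order1,order2 Moment orders of the two passes (defaults: the
#'   just-specified order for both).
#' @param weights1 Weight scheme of the first pass.
#' @param cov_table Covariance table covering the expected estimate range;
#'   required.
#' @return A `"gmm_fit"` of the second pass with `passes = 2` and the first
#'   pass attached as `$pass1`.
#' @export
gmm_two_pass <- function(times, n_steps, order1 = n_steps, order2 = n_steps,
                         weights1 = "jackknife_diag", cov_table,
                         region = c(1, 1000), grid_factor = 10,
                         control = gmm_control()) {
  stopifnot(inherits(cov_table, "cov_table"))
  pass1 <- gmm_fit(times, n_steps, order = order1, weights = weights1,
                   region = region, grid_factor = grid_factor,
                   control = control)
  order2 <- check_order(order2)
  if (order2 < n_steps) stop("`order2` must be >= `n_steps`", call. = FALSE)
  # interpolation needs positive parameters; clamp a (rare) nonpositive
  # first-pass estimate to the table floor
  at <- pmax(pass1$estimates, min(vapply(cov_table$tau_grids, min, numeric(1))))
  W <- build_weight(times, order2, "mc_interp", cov_table, at)
  kst <- k_statistics(times, order2)
  best <- gmm_minimize(kst, order2, W,
                       matrix(pass1$estimates, nrow = 1), control)
  est <- best$par
  dr <- n_steps > 1L &&
    any(diff(est) < control$double_root_tol * pmax(abs(est[-1]),
                                                   abs(est[-n_steps]),
                                                   .Machine$double.eps))
  structure(list(estimates = est, Q_min = max(best$value, 0),
                 n_steps = n_steps, order = order2,
                 weight_scheme = "mc_interp", W = W,
                 kstats = kst, T = length(times), times = times,
                 n_starts = 1L, converged_starts = best$converged_starts,
                 double_root = dr, passes = 2L, pass1 = pass1,
                 region = region, grid_factor = grid_factor,
                 control = control, call = match.call()),
            class = "gmm_fit")
}
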