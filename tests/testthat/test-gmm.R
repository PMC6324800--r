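test_that("objective is the weighted quadratic form of the moment functions", {
  t <- c(1, 2, 3)                          # k = (2, 1)
  # taus = (2, 2): kappa = (4, 8) -> g = (2, 7); Q = 4 + 49 with W = I
  expect_equal(gmm_objective(c(2, 2), t, identity_weight(2)), 53)
  W <- matrix(c(2, 1, 1, 3), 2)
  g <- c(2, 7)
  expect_equal(gmm_objective(c(2, 2), t, W), drop(g %*% W %*% g))
  # permutation symmetry
  set.seed(31)
  ts <- simulate_irreversible(c(10, 50), 40)
  expect_equal(gmm_objective(c(4, 30), ts, identity_weight(3)),
               gmm_objective(c(30, 4), ts, identity_weight(3)))
})

test_that("objective vanishes at a real classical solution", {
  set.seed(32)
  t <- simulate_irreversible(c(10, 50), 200)
  cmm <- cmm_solve(t, 2)
  expect_true(cmm$all_real)
  expect_lt(gmm_objective(cmm$estimates, t, identity_weight(2)), 1e-16)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(33)
  t <- simulate_irreversible(c(10, 50), 60)
  for (rep in 1:5) {
    taus <- runif(3, 2, 80)
    W <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    gr <- gmm_gradient(taus, t, W)
    h <- 1e-5
    fd <- vapply(1:3, function(j) {
      e <- replace(numeric(3), j, h * max(1, abs(taus[j])))
      (gmm_objective(taus + e, t, W) - gmm_objective(taus - e, t, W)) /
        (2 * e[j])
    }, numeric(1))
    expect_lt(max(abs(gr - fd) / pmax(abs(fd), 1)), 1e-5)
  }
  # zero at the classical solution; equal components at equal taus
  cmm <- cmm_solve(t, 2)
  g0 <- gmm_gradient(cmm$estimates, t, identity_weight(2))
  expect_lt(max(abs(g0)), 1e-6)
  ge <- gmm_gradient(c(20, 20), t, identity_weight(2))
  expect_equal(ge[1], ge[2])
})

test_that("just-specified GMM equals the classical solution when the latter is real", {
  for (s in 1:5) {
    t <- simulate_irreversible(c(10, 50), 100, seed = 330 + s)
    cmm <- cmm_solve(t, 2)
    if (!cmm$all_real) next
    fit <- gmm_fit(t, 2)
    expect_lt(max(abs(fit$estimates - cmm$estimates) /
                    (1 + abs(cmm$estimates))), 1e-6)
    expect_lt(fit$Q_min, 1e-12)
    # sum of estimates equals the sample mean (just-specified conservation)
    expect_equal(sum(fit$estimates), mean(t), tolerance = 1e-8)
  }
})

test_that("a complex classical solution forces a GMM double root", {
  fit <- suppressWarnings(gmm_fit(c(10, 10, 10), 2))
  expect_true(fit$double_root)
  expect_false(cmm_solve(c(10, 10, 10), 2)$all_real)
  expect_equal(fit$estimates[1], fit$estimates[2], tolerance = 1e-6)
})

test_that("first-order one-step fit returns exactly the sample mean", {
  set.seed(34)
  t <- simulate_irreversible(10, 50)
  fit <- gmm_fit(t, 1, order = 1)
  expect_equal(unname(coef(fit)), mean(t), tolerance = 1e-10)
})

test_that("just-specified fits with identity weights are scale-equivariant", {
  t <- simulate_irreversible(c(10, 50), 150, seed = 35)
  stopifnot(cmm_solve(t, 2)$all_real)
  f1 <- gmm_fit(t, 2, weights = "identity")
  for (c in c(0.25, 4)) {
    f2 <- gmm_fit(c * t, 2, weights = "identity",
                  region = c * c(1, 1000))
    expect_equal(f2$estimates, c * f1$estimates, tolerance = 1e-6)
  }
})

test_that("refining the start grid never worsens the global search", {
  t <- simulate_irreversible(c(10, 50), 80, seed = 36)
  coarse <- gmm_fit(t, 2, order = 3, grid_factor = 100)
  fine <- gmm_fit(t, 2, order = 3, grid_factor = 10)
  expect_lte(fine$Q_min, coarse$Q_min * (1 + 1e-9) + 1e-12)
})

test_that("fit validates its configuration", {
  t <- simulate_irreversible(c(10, 50), 30, seed = 37)
  expect_error(gmm_fit(t, 2, order = 1), "under-specified")
  expect_error(gmm_fit(t, 2, order = 5), "unsupported")
  expect_error(gmm_fit(t, 2, region = c(10, 5)), "region")
  expect_error(gmm_fit(c(1, 2, 3), 2, order = 4), "too small")
  expect_error(gmm_fit(t, 2, weights = "mc_interp"), "cov_table")
})

test_that("estimator output is deterministic and sorted, with diagnostics", {
  t <- simulate_irreversible(c(10, 50), 120, seed = 38)
  f1 <- gmm_fit(t, 2, order = 4)
  f2 <- gmm_fit(t, 2, order = 4)
  expect_identical(f1$estimates, f2$estimates)
  expect_false(is.unsorted(f1$estimates))
  expect_gte(f1$Q_min, 0)
  expect_gte(f1$converged_starts, 1L)
  expect_equal(f1$n_starts, 10L)   # 4^2 grid points, unordered pairs pruned
})

test_that("bias of sorted two-step estimates shrinks with sample size", {
  est_bias <- function(T, n_trials) {
    E <- t(vapply(seq_len(n_trials), function(i)
      gmm_fit(simulate_irreversible(c(10, 50), T, seed = 390 + i), 2)$estimates,
      numeric(2)))
    colMeans(abs(E - matrix(c(10, 50), n_trials, 2, byrow = TRUE)))
  }
  small <- est_bias(5, 60)
  large <- est_bias(500, 60)
  expect_lt(sum(large), sum(small))
})

test_that("two-pass refinement starts from pass 1 and cannot do worse at its own weight", {
  tab <- build_covariance_table(list(c(4, 16, 64), c(12, 60, 300)),
                                c(30, 120, 500), M = 4, n_trials = 500,
                                seed = 40)
  t <- simulate_irreversible(c(10, 50), 120, seed = 41)
  fit <- gmm_two_pass(t, 2, cov_table = tab)
  expect_equal(fit$passes, 2L)
  # just-specified solutions are weight-independent: pass 2 stays at pass 1
  expect_equal(fit$estimates, fit$pass1$estimates, tolerance = 1e-5)
  # minimisation contract: Q2 at the pass-1 start >= Q2 at the minimum
  q_start <- gmm_objective(fit$pass1$estimates, t, fit$W)
  expect_gte(q_start * (1 + 1e-12) + 1e-15, fit$Q_min)

  # over-specified second pass still runs and reports its order
  fit34 <- gmm_two_pass(t, 2, order2 = 3, cov_table = tab)
  expect_equal(fit34$order, 3L)
  expect_gte(fit34$Q_min, 0)
})

test_that("single-pass fit can take an interpolated MC weight", {
  tab <- build_covariance_table(list(c(4, 16, 64), c(12, 60, 300)),
                                c(30, 120, 500), M = 2, n_trials = 500,
                                seed = 42)
  t <- simulate_irreversible(c(10, 50), 120, seed = 43)
  fit <- gmm_fit(t, 2, weights = "mc_interp", cov_table = tab,
                 interp_at = c(10, 50))
  expect_equal(fit$weight_scheme, "mc_interp")
  # just-specified: same answer as the D-matrix fit
  expect_equal(fit$estimates, gmm_fit(t, 2)$estimates, tolerance = 1e-5)
})
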