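test_that("identity weight is the identity and collapses Q to a plain sum of squares", {
  expect_equal(unclass(identity_weight(2)), diag(2), ignore_attr = TRUE)
  expect_equal(dim(identity_weight(4)), c(4L, 4L))
  set.seed(21)
  t <- simulate_irreversible(c(10, 50), 30)
  g <- moment_functions(c(8, 40), t, 2)
  expect_equal(gmm_objective(c(8, 40), t, identity_weight(2)), sum(g^2))
})

test_that("jackknife covariance of the mean is exactly s^2/T", {
  v <- jackknife_cumulant_covariance(c(1, 2, 3), 2)
  expect_equal(v[1, 1], 1 / 3, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:10) {
    t <- simulate_irreversible(c(10, 50), sample(6:60, 1))
    v <- jackknife_cumulant_covariance(t, 4)
    expect_equal(v[1, 1], var(t) / length(t), tolerance = 1e-9)
  }
})

test_that("leave-one-out k-statistics match a brute-force oracle", {
  set.seed(23)
  t <- simulate_irreversible(c(10, 50), 25)
  loo <- dwellgmm:::k_statistics_loo(t, 4)
  brute <- t(vapply(seq_along(t), function(i) k_statistics(t[-i], 4),
                    numeric(4)))
  expect_lt(max(abs(loo - brute) / pmax(abs(brute), 1)), 1e-10)
})

test_that("jackknife covariance is symmetric PSD; constant samples give zero", {
  set.seed(24)
  for (i in 1:10) {
    t <- simulate_irreversible(c(3, 30), 20)
    v <- jackknife_cumulant_covariance(t, 4)
    expect_equal(v, t(v))
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
  vz <- jackknife_cumulant_covariance(rep(4, 10), 3)
  expect_equal(max(abs(vz)), 0)
  expect_error(jackknife_cumulant_covariance(c(1, 2, 3, 4), 4), "T >= 5")
})

test_that("diagonal-only jackknife zeroes off-diagonals and the D-weight of order 1 is T/s^2", {
  set.seed(25)
  t <- simulate_irreversible(c(10, 50), 30)
  v <- jackknife_cumulant_covariance(t, 3, diagonal_only = TRUE)
  expect_equal(v[row(v) != col(v)], rep(0, 6))
  W <- invert_to_weight(v)
  expect_equal(W[1, 1], length(t) / var(t), tolerance = 1e-9)
})

test_that("covariance inversion satisfies W V = I and falls back on degeneracy", {
  expect_equal(unclass(invert_to_weight(structure(diag(c(4, 25)), scheme = "x"))),
               diag(c(0.25, 0.04)), ignore_attr = TRUE)
  expect_equal(unclass(invert_to_weight(structure(diag(3), scheme = "x"))),
               diag(3), ignore_attr = TRUE)
  set.seed(26)
  A <- matrix(rnorm(16), 4)
  V <- structure(crossprod(A) + diag(4), scheme = "x")
  W <- invert_to_weight(V)
  expect_lt(max(abs(W %*% V - diag(4))), 1e-10)
  # singular: rank-1 matrix falls back to its diagonal, with a warning
  Vs <- structure(tcrossprod(c(1, 2)), scheme = "x")
  expect_warning(Ws <- invert_to_weight(Vs), "singular")
  expect_equal(diag(Ws), 1 / diag(Vs))
  # zero diagonal entry falls back to unit weight there
  expect_warning(Wz <- invert_to_weight(structure(diag(c(0, 4)), scheme = "x")),
                 "unit weight")
  expect_equal(diag(Wz), c(1, 0.25))
})

test_that("Monte-Carlo covariance of the sample mean is kappa2/T", {
  v <- mc_covariance(10, n = 100, M = 2, n_trials = 2e4, seed = 27)
  # var of the mean = tau^2 / T = 1; MC relative error ~ sqrt(2/n_trials)
  expect_lt(abs(v[1, 1] - 1), 5 * sqrt(2 / 2e4))
  expect_equal(v, t(v))
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("covariance table interpolation is exact at nodes and linear between them", {
  tab <- build_covariance_table(list(c(5, 20), c(25, 100)), c(50, 200),
                                M = 2, n_trials = 400, seed = 28)
  # node identity
  v <- interpolate_covariance(tab, c(5, 25), 50)
  expect_equal(unclass(v), tab$matrices[[1]], ignore_attr = TRUE)
  # permutation of the query taus is irrelevant
  expect_equal(unclass(interpolate_covariance(tab, c(25, 5), 50)),
               tab$matrices[[1]], ignore_attr = TRUE)
  # geometric midpoint in T -> element-wise average of the two T nodes
  vm <- interpolate_covariance(tab, c(5, 25), 100)
  lo <- tab$matrices[[1]]
  hi <- tab$matrices[[1 + 4]]      # same taus, next T plane
  expect_equal(unclass(vm), (lo + hi) / 2, ignore_attr = TRUE)
  # out-of-hull queries clamp with a warning
  expect_warning(vc <- interpolate_covariance(tab, c(1, 25), 50), "clamp")
  expect_equal(unclass(vc), tab$matrices[[1]], ignore_attr = TRUE)
})

test_that("interpolated covariance at a stored node agrees with direct simulation", {
  tab <- build_covariance_table(list(c(10), c(50)), c(100), M = 2,
                                n_trials = 4000, seed = 29)
  v1 <- interpolate_covariance(tab, c(10, 50), 100)
  v2 <- mc_covariance(c(10, 50), 100, M = 2, n_trials = 4000, seed = 92)
  # combined MC error: a few percent relative at 4000 trials; compare loosely
  expect_lt(max(abs(v1 - v2) / pmax(abs(v2), 1)), 0.2)
})

test_that("covariance tables round-trip through JSON", {
  tab <- build_covariance_table(list(c(5, 20)), c(10, 40), M = 3,
                                n_trials = 200, seed = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_cov_table(tab, path)
  tab2 <- read_cov_table(path)
  expect_equal(tab2$n_grid, tab$n_grid)
  expect_equal(tab2$tau_grids, tab$tau_grids)
  expect_equal(tab2$M, tab$M)
  for (i in seq_along(tab$matrices))
    expect_equal(tab2$matrices[[i]], tab$matrices[[i]], tolerance = 1e-12)
})
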