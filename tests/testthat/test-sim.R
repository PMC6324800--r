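test_that("irreversible simulation reproduces the scheme's mean and variance", {
  t1 <- simulate_irreversible(10, 1e5, seed = 101)
  se_mean <- 10 / sqrt(1e5)
  expect_lt(abs(mean(t1) - 10), 5 * se_mean)

  t2 <- simulate_irreversible(c(10, 50), 1e5, seed = 102)
  # Var(s^2) ~ (kappa4 + 2 kappa2^2) / T for the two-step scheme
  k2 <- 10^2 + 50^2
  k4 <- factorial(3) * (10^4 + 50^4)
  se_var <- sqrt((k4 + 2 * k2^2) / 1e5)
  expect_lt(abs(var(t2) - 2600), 5 * se_var)
  expect_true(all(t2 > 0))
})

test_that("simulation is seed-reproducible and validates inputs", {
  a <- simulate_irreversible(c(10, 50), 100, seed = 7)
  b <- simulate_irreversible(c(10, 50), 100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_irreversible(c(10, 50), 100, seed = 8)))
  expect_error(simulate_irreversible(c(10, -1), 10, seed = 1), "positive")
  expect_error(simulate_irreversible(10, 0, seed = 1), "integer")

  r1 <- simulate_reversible(0.1, 0.05, 0.02, 50, seed = 3)
  expect_identical(r1, simulate_reversible(0.1, 0.05, 0.02, 50, seed = 3))
  expect_error(simulate_reversible(-0.1, 0, 0.02, 10, seed = 1), "rates")
})

test_that("rate map gives the closed-form decay constants", {
  taus <- rates_to_decay(0.1, 0, 0.02)
  expect_equal(unname(taus["tau_A"]), 50, tolerance = 1e-12)
  expect_equal(unname(taus["tau_B"]), 10, tolerance = 1e-12)

  # equal rates: 1/tau = (3 +/- sqrt(5)) k / 2
  k <- 0.25
  taus <- rates_to_decay(k, k, k)
  expect_equal(unname(taus["tau_B"]), 2 / ((3 + sqrt(5)) * k), tolerance = 1e-12)
  expect_equal(unname(taus["tau_A"]), 2 / ((3 - sqrt(5)) * k), tolerance = 1e-12)

  # zero discriminant collapses the two constants
  taus <- rates_to_decay(1, 0, 1)
  expect_equal(unname(taus["tau_A"]), unname(taus["tau_B"]))
})

test_that("rate map satisfies the Vieta relations for random rates", {
  set.seed(41)
  for (i in 1:25) {
    k <- c(runif(1, 0.01, 2), runif(1, 0, 2), runif(1, 0.01, 2))
    taus <- rates_to_decay(k[1], k[2], k[3])
    expect_equal(sum(1 / taus), sum(k), tolerance = 1e-10)
    expect_equal(prod(1 / taus), k[1] * k[3], tolerance = 1e-10)
    expect_lte(taus[["tau_B"]], taus[["tau_A"]])
  }
})

test_that("reversible simulation mean follows the mapped decay constants", {
  t <- simulate_reversible(0.1, 0, 0.02, 1e5, seed = 104)
  se <- sqrt(10^2 + 50^2) / sqrt(1e5)
  expect_lt(abs(mean(t) - 60), 5 * se)
})

test_that("reversible draw with k2 = 0 matches the irreversible distribution", {
  a <- simulate_reversible(0.1, 0, 0.02, 1e4, seed = 105)
  b <- simulate_irreversible(c(1 / 0.1, 1 / 0.02), 1e4, seed = 205)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.001)
})

test_that("biexponential density normalises, is symmetric and continuous in the degenerate limit", {
  q <- integrate(density_biexp, 0, 50 * 50, tau_A = 10, tau_B = 50,
                 rel.tol = 1e-9)
  expect_lt(abs(q$value - 1), 1e-6)

  tt <- c(0, 1, 7, 33, 120)
  expect_equal(density_biexp(tt, 10, 50), density_biexp(tt, 50, 10))

  # degenerate branch value at t = tau
  expect_equal(density_biexp(10, 10, 10), exp(-1) / 10, tolerance = 1e-12)
  # continuity across the branch switch
  expect_equal(density_biexp(tt, 10, 10 * (1 + 5e-6)),
               density_biexp(tt, 10, 10), tolerance = 1e-4)
  expect_error(density_biexp(-1, 10, 50), "nonnegative")
})

test_that("hypoexponential density integrates to one for three steps", {
  q <- integrate(function(t) dwellgmm:::density_hypoexp(t, c(10, 30, 100)),
                 0, 5000, rel.tol = 1e-9)
  expect_lt(abs(q$value - 1), 1e-5)
  # CDF consistent with the density by quadrature
  F50 <- integrate(function(t) dwellgmm:::density_hypoexp(t, c(10, 30, 100)),
                   0, 50, rel.tol = 1e-10)$value
  expect_equal(dwellgmm:::cdf_hypoexp(50, c(10, 30, 100)), F50,
               tolerance = 1e-7)
})

test_that("sample cumulants of large simulated samples approach the population values", {
  taus <- c(10, 50)
  t <- simulate_irreversible(taus, 1e5, seed = 106)
  k <- k_statistics(t, 4)
  kappa <- population_cumulants(taus, 4)
  # tolerance scaled to sqrt(T) sampling error per order
  sds <- c(sqrt(kappa[2]), sqrt(2 * kappa[2]^2 + kappa[4]),
           25 * kappa[3], 40 * kappa[4])
  for (m in 1:4)
    expect_lt(abs(k[m] - kappa[m]), 5 * sds[m] / sqrt(1e5))
})
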