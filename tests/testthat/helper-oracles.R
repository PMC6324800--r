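# Shared test helpers.

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1)), tol)
}

# sample with exactly prescribed first two k-statistics (mean m, unbiased
# variance v), built as a symmetric triple about the mean
sample_with_k12 <- function(m, v) m + c(-sqrt(v), 0, sqrt(v))

# closed-form two-step classical solution from k-statistics (independent
# of the Newton-identities code path)
quadratic_cmm <- function(k1, k2) {
  e1 <- k1
  e2 <- (k1^2 - k2) / 2
  disc <- e1^2 - 4 * e2
  if (disc < 0) return(NULL)
  sort(c((e1 - sqrt(disc)) / 2, (e1 + sqrt(disc)) / 2))
}
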