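## Internal helpers: validation and seeded evaluation.

# Evaluate `expr` under a Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards. seed = NULL leaves the
# global stream untouched (draws advance it as usual).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Coerce to a valid 32-bit integer seed.
as_seed <- function(seed) {
  seed <- as.numeric(seed)
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  as.integer(seed %% .Machine$integer.max)
}

# Derive the seed for an independent trial stream by offsetting.
trial_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(as_seed(seed)) + i) %% .Machine$integer.max)
}

check_dwell_times <- function(times, min_n = 1L, arg = "times") {
  if (!is.numeric(times) || length(times) < min_n)
    stop(sprintf("`%s` must be a numeric vector of at least %d dwell time(s)",
                 arg, min_n), call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop(sprintf("`%s` contains missing or non-finite values", arg), call. = FALSE)
  if (any(times <= 0))
    stop(sprintf("`%s` must be strictly positive (dwell times are durations)", arg),
         call. = FALSE)
  invisible(as.numeric(times))
}

check_taus <- function(taus, arg = "taus") {
  if (!is.numeric(taus) || length(taus) < 1L)
    stop(sprintf("`%s` must contain at least one decay parameter", arg), call. = FALSE)
  if (anyNA(taus) || any(!is.finite(taus)) || any(taus <= 0))
    stop(sprintf("`%s` must be finite and strictly positive", arg), call. = FALSE)
  as.numeric(taus)
}

check_count <- function(n, min = 1L, arg = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < min || n != round(n))
    stop(sprintf("`%s` must be a single integer >= %d", arg, min), call. = FALSE)
  as.integer(n)
}

check_order <- function(M, max_order = 4L, arg = "order") {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M != round(M) || M < 1)
    stop(sprintf("`%s` must be a single positive integer", arg), call. = FALSE)
  if (M > max_order)
    stop(sprintf(paste0("`%s` = %d is unsupported: unbiased cumulant estimators ",
                        "(k-statistics) are implemented up to order %d only"),
         arg, as.integer(M), max_order), call. = FALSE)
  as.integer(M)
}

# Minimum sample size for k-statistics of order M (denominators T-1..T-3).
min_T_for_order <- function(M) max(as.integer(M), if (M >= 4L) 4L else M)

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
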