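## Weight matrices for the GMM objective. Four schemes are supported:
## identity (I-matrix), diagonal jackknife (D-matrix), full jackknife
## covariance (C-matrix), and linear interpolation into a precomputed grid
## of Monte-Carlo cumulant covariances. The optimal weight is the inverse of
## the covariance of the moment functions; the jackknife and MC routines
## estimate that covariance and invert_to_weight() inverts it with guarded
## fallbacks for degenerate samples.

#' Identity weight matrix
#'
#' @param M Moment order; the matrix is M x M.
#' @return An M x M identity matrix with attribute `scheme = "identity"`.
#' @export
identity_weight <- function(M) {
  M <- check_order(M)
  structure(diag(M), scheme = "identity")
}

#' Jackknife estimate of the k-statistic covariance
#'
#' Forms the T leave-one-out subsamples, computes the order-1..M
#' k-statistics of each, and returns the jackknife covariance
#' \deqn{v_{mm'} = \frac{T-1}{T} \sum_i (k_i^{(m)} - \bar k^{(m)})
#'   (k_i^{(m')} - \bar k^{(m')}),}
#' the standard leave-one-out estimator. Its (1,1) element equals `var(t)/T`
#' exactly (the jackknife variance of the mean).
#'
#' @inheritParams k_statistics
#' @param diagonal_only If `TRUE`, off-diagonal entries are zeroed (the
#'   D-matrix precursor).
#' @return M x M symmetric positive semi-definite covariance matrix.
#' @export
jackknife_cumulant_covariance <- function(times, M = 4L, diagonal_only = FALSE) {
  times <- check_dwell_times(times)
  K <- k_statistics_loo(times, M)           # T x M, validates sizes
  T <- length(times)
  D <- K - matrix(colMeans(K), T, ncol(K), byrow = TRUE)
  v <- (T - 1) / T * crossprod(D)
  v <- (v + t(v)) / 2
  if (diagonal_only) v <- diag(diag(v), nrow = nrow(v))
  structure(v, scheme = if (diagonal_only) "jackknife_diag" else "jackknife_full")
}

#' Invert a cumulant covariance into a GMM weight matrix
#'
#' Well-conditioned covariances are inverted directly. A near-singular
#' matrix (reciprocal condition number below 1e-12) falls back to inverting
#' its diagonal; a zero diagonal entry falls back to unit weight for that
#' order. Both fallbacks emit a warning — the objective must stay finite and
#' positive semi-definite even for degenerate samples such as repeated
#' values.
#'
#' @param cov M x M symmetric positive semi-definite covariance estimate.
#' @return M x M symmetric weight matrix; attribute `scheme` records the
#'   provenance (suffixed `"_fallback"` when a fallback fired).
#' @export
invert_to_weight <- function(cov) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("`cov` must be a square matrix", call. = FALSE)
  scheme <- attr(cov, "scheme")
  if (is.null(scheme)) scheme <- "custom"
  M <- nrow(cov)
  d <- diag(cov)
  diagonal <- all(abs(cov[row(cov) != col(cov)]) <= 1e-300)
  if (!diagonal) {
    rc <- tryCatch(rcond(cov), error = function(e) 0)
    if (rc > 1e-12) {
      W <- solve(cov)
      W <- (W + t(W)) / 2
      return(structure(W, scheme = scheme))
    }
    warning("covariance is numerically singular; falling back to its diagonal",
            call. = FALSE)
    scheme <- paste0(scheme, "_fallback")
  }
  w <- numeric(M)
  zero <- d <= 0 | !is.finite(d)
  if (any(zero)) {
    if (!grepl("fallback", scheme)) scheme <- paste0(scheme, "_fallback")
    warning(sprintf("zero variance for order(s) %s; using unit weight there",
                    paste(which(zero), collapse = ", ")), call. = FALSE)
  }
  w[zero] <- 1
  w[!zero] <- 1 / d[!zero]
  structure(diag(w, nrow = M), scheme = scheme)
}

#' Monte-Carlo estimate of the k-statistic covariance
#'
#' Simulates `n_trials` independent samples of size `n` from the scheme and
#' returns the empirical covariance of their order-1..M k-statistics.
#'
#' @param taus Decay parameters of the n-step irreversible scheme (seconds).
#' @param n Sample size of each simulated trial.
#' @param M Moment order.
#' @param n_trials Number of Monte-Carlo trials (>= 2); 1e5 gives
#'   percent-level element accuracy.
#' @param seed Optional integer seed.
#' @return M x M symmetric PSD covariance matrix, attribute
#'   `scheme = "mc"`.
#' @export
mc_covariance <- function(taus, n, M = 4L, n_trials = 1e5, seed = NULL) {
  taus <- check_taus(taus)
  n <- check_count(n, min_T_for_order(check_order(M)), "n")
  n_trials <- check_count(n_trials, 2L, "n_trials")
  with_seed(seed, {
    # chunked so the trials x n draw matrix stays modest
    chunk <- max(1L, min(n_trials, as.integer(ceiling(2e6 / n))))
    K <- matrix(0, n_trials, M)
    done <- 0L
    while (done < n_trials) {
      nb <- min(chunk, n_trials - done)
      X <- matrix(0, nb, n)
      for (tau in taus)
        X <- X + matrix(rexp(nb * n, rate = 1 / tau), nb, n)
      K[done + seq_len(nb), ] <- k_statistics_rows(X, M)
      done <- done + nb
    }
    v <- cov(K)
    structure((v + t(v)) / 2, scheme = "mc")
  })
}

#' Precompute a grid of Monte-Carlo cumulant covariances
#'
#' Builds the lookup table used by the interpolated ("MC") weight scheme and
#' the second pass of the two-pass GMM: one [mc_covariance()] matrix per node
#' of the cartesian grid `tau_grids[[1]] x ... x tau_grids[[d]] x n_grid`.
#' Interpolation is element-wise multilinear in `log10(tau)` and `log10(n)`
#' (covariances vary over decades along each axis).
#'
#' @param tau_grids List of strictly increasing positive grids, one per
#'   decay parameter (a single numeric vector is recycled as a one-step
#'   grid list).
#' @param n_grid Strictly increasing grid of sample sizes.
#' @param M Moment order of the stored matrices.
#' @param n_trials Monte-Carlo trials per node.
#' @param seed Optional integer seed (node streams are derived by
#'   offsetting).
#' @return An object of class `cov_table`.
#' @seealso [interpolate_covariance()], [write_cov_table()]
#' @export
build_covariance_table <- function(tau_grids, n_grid, M = 4L, n_trials = 1e5,
                                   seed = NULL) {
  if (is.numeric(tau_grids)) tau_grids <- list(tau_grids)
  stopifnot(is.list(tau_grids), length(tau_grids) >= 1L)
  for (g in tau_grids) {
    check_taus(g, "tau_grids")
    if (is.unsorted(g, strictly = TRUE))
      stop("each tau grid must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(n_grid, strictly = TRUE) || any(n_grid < 1))
    stop("`n_grid` must be strictly increasing sample sizes", call. = FALSE)
  M <- check_order(M)
  axes <- c(tau_grids, list(as.numeric(n_grid)))
  nodes <- expand.grid(lapply(axes, seq_along), KEEP.OUT.ATTRS = FALSE)
  mats <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    idx <- as.integer(nodes[i, ])
    taus <- vapply(seq_along(tau_grids), function(j) tau_grids[[j]][idx[j]],
                   numeric(1))
    n <- n_grid[idx[length(idx)]]
    m <- mc_covariance(taus, n, M, n_trials, seed = trial_seed(seed, i))
    attributes(m) <- attributes(m)["dim"]
    mats[[i]] <- m
  }
  structure(list(tau_grids = lapply(tau_grids, as.numeric),
                 n_grid = as.numeric(n_grid),
                 M = M, n_trials = n_trials, seed = seed,
                 matrices = mats),
            class = "cov_table")
}

#' @export
print.cov_table <- function(x, ...) {
  cat("Cumulant covariance table\n")
  cat(sprintf("  steps: %d, order M = %d, %d nodes, %g MC trials/node\n",
              length(x$tau_grids), x$M, length(x$matrices), x$n_trials))
  for (j in seq_along(x$tau_grids))
    cat(sprintf("  tau_%d grid: %s s\n", j,
                paste(signif(x$tau_grids[[j]], 4), collapse = ", ")))
  cat(sprintf("  sample-size grid: %s\n", paste(x$n_grid, collapse = ", ")))
  invisible(x)
}

#' Interpolate a covariance matrix from a precomputed table
#'
#' Element-wise multilinear interpolation in `log10(tau_1)..log10(tau_d),
#' log10(n)`. Decay parameters are sorted ascending before lookup (the
#' covariance is symmetric under permutation of the steps). Queries outside
#' the grid hull are clamped to the boundary with a warning. A query at a
#' stored node returns the stored matrix exactly.
#'
#' @param table A [build_covariance_table()] result.
#' @param taus Decay parameters of the query scheme (length must match the
#'   table's number of steps).
#' @param n Sample size of the query.
#' @return M x M covariance matrix, attribute `scheme = "mc_interp"`.
#' @export
interpolate_covariance <- function(table, taus, n) {
  stopifnot(inherits(table, "cov_table"))
  d <- length(table$tau_grids)
  if (length(taus) != d)
    stop(sprintf("`taus` must have length %d to match the table", d), call. = FALSE)
  taus <- sort(as.numeric(taus))
  axes <- c(table$tau_grids, list(table$n_grid))
  query <- c(taus, n)
  dims <- lengths(axes)
  lo <- integer(length(axes)); fr <- numeric(length(axes))
  clamped <- FALSE
  for (a in seq_along(axes)) {
    g <- axes[[a]]
    x <- query[a]
    if (x < min(g) || x > max(g)) { clamped <- TRUE; x <- min(max(x, min(g)), max(g)) }
    if (length(g) == 1L) { lo[a] <- 1L; fr[a] <- 0; next }
    i <- findInterval(x, g, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(g) - 1L)
    lo[a] <- i
    fr[a] <- (log10(x) - log10(g[i])) / (log10(g[i + 1]) - log10(g[i]))
  }
  if (clamped)
    warning("query outside the covariance table hull; clamped to the boundary",
            call. = FALSE)
  M <- table$M
  out <- matrix(0, M, M)
  corners <- expand.grid(rep(list(0:1), length(axes)), KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(corners))) {
    cc <- as.integer(corners[r, ])
    w <- prod(ifelse(cc == 1L, fr, 1 - fr))
    if (w == 0) next
    idx <- pmin(lo + cc, dims)
    lin <- idx[1]; mult <- dims[1]
    for (a in seq_along(axes)[-1]) { lin <- lin + (idx[a] - 1L) * mult; mult <- mult * dims[a] }
    out <- out + w * table$matrices[[lin]]
  }
  structure((out + t(out)) / 2, scheme = "mc_interp")
}

#' Write / read a covariance table as self-describing JSON
#'
#' The file stores the grid axes, order, trial count, seed and the matrices
#' in row-major order, so tables can be precomputed once and reused.
#'
#' @param table A `cov_table` object.
#' @param path File path.
#' @return `write_cov_table` returns `path` invisibly; `read_cov_table`
#'   returns the reconstructed `cov_table`.
#' @export
write_cov_table <- function(table, path) {
  stopifnot(inherits(table, "cov_table"))
  obj <- list(
    format = "dwellgmm-cov-table",
    version = 1L,
    M = table$M,
    n_trials = table$n_trials,
    seed = if (is.null(table$seed)) NULL else as_seed(table$seed),
    tau_grids = table$tau_grids,
    n_grid = table$n_grid,
    matrices = lapply(table$matrices, function(m) as.vector(t(m)))  # row-major
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cov_table
#' @export
read_cov_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dwellgmm-cov-table"))
    stop("not a dwellgmm covariance-table file: ", path, call. = FALSE)
  M <- as.integer(obj$M)
  tg <- obj$tau_grids
  if (is.numeric(tg)) tg <- list(tg)          # JSON collapses a 1-grid list
  if (is.matrix(tg)) tg <- lapply(seq_len(nrow(tg)), function(i) tg[i, ])
  mats <- obj$matrices
  if (is.matrix(mats)) mats <- lapply(seq_len(nrow(mats)), function(i) mats[i, ])
  structure(list(tau_grids = lapply(tg, as.numeric),
                 n_grid = as.numeric(obj$n_grid),
                 M = M,
                 n_trials = as.numeric(obj$n_trials),
                 seed = obj$seed,
                 matrices = lapply(mats, function(v) matrix(as.numeric(v), M, M,
                                                            byrow = TRUE))),
            class = "cov_table")
}
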