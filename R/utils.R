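# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-patient RNG sub-streams that depend on patient identity,
# not on row position, so results are invariant to cohort row order.
hash31 <- function(x) {
  m <- 2147483647 # 2^31 - 1
  vapply(x, function(s) {
    h <- 0
    for (k in utf8ToInt(s)) h <- (h * 31 + k) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Combine a user seed with a tag (string or integer) into a sub-seed < 2^31.
derive_seed <- function(seed, tag) {
  m <- 2147483647
  t <- if (is.character(tag)) hash31(tag) else as.numeric(tag) %% m
  as.integer((((seed %% m) * 48271) %% m + t) %% m)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Moore-Penrose pseudo-inverse via SVD; used for the k-group log-rank
# statistic where the covariance matrix of the first k-1 groups can be
# numerically singular in degenerate designs.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

`%||%` <- rlang::`%||%`

# Fraction of a calendar year elapsed at a date (for op-date -> op-year grids).
date_to_year <- function(d) {
  d <- as.Date(d)
  as.integer(format(d, "%Y"))
}

years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / 365.25
}
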