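# Small shared helpers: multiple-testing correction, Welch test with
# degenerate-variance handling, cosine distance, adjusted Rand index,
# rolling statistics, RNG scoping.

#' Holm-Šídák step-down adjusted p values
#'
#' Step-down Šídák procedure: order the m raw p values increasingly, adjust
#' the k-th as `1 - (1 - p)^(m - k + 1)`, and enforce monotonicity.
#' Controls the family-wise error rate at the nominal level under
#' independence (and is slightly more powerful than Holm-Bonferroni).
#'
#' @param p numeric vector of raw p values (NAs kept as NA).
#' @return vector of adjusted p values, same order as input.
#' @export
#' @examples
#' p_adjust_holm_sidak(c(0.01, 0.04, 0.03))
p_adjust_holm_sidak <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  adj <- 1 - (1 - pv[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

# Welch's two-sided t-test tolerating zero-variance groups.
# Returns list(p, degenerate). Count data in short sub-segments can be
# constant; stats::t.test errors there, so intercept:
#   both groups constant, equal means   -> p = 1
#   both groups constant, unequal means -> p = 0, degenerate flag
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(p = NA_real_, degenerate = TRUE))
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(p = 1, degenerate = FALSE))
    return(list(p = 0, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(p = tt$p.value, degenerate = FALSE)
}

# Cosine distance between two nonnegative vectors; 0 identical direction,
# 1 orthogonal. Errors on zero vectors.
cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(x * y) / (nx * ny)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

# Rolling mean over a window (stride 1) via cumulative sums.
# Returns vector of length n - window + 1.
rolling_mean <- function(x, window) {
  n <- length(x)
  if (window > n) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

# Rolling (population) variance per window; numerically adequate for the
# trajectory scales used here (coordinates centred before accumulating).
rolling_var <- function(x, window) {
  x <- x - mean(x)
  m <- rolling_mean(x, window)
  m2 <- rolling_mean(x^2, window)
  pmax(m2 - m^2, 0)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so operations needing internal randomness (e.g. k-means restarts)
#' do not perturb the surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed and an index, staying below 2^31.
split_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
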