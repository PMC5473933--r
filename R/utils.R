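# Internal helpers shared across modules.

# Population (divisor-n) standard deviation.
sd_n <- function(x) sqrt(mean((x - mean(x))^2))

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Pairwise squared Euclidean distances between rows of x (n x n).
pairwise_sq_dists <- function(x) {
  x <- as.matrix(x)
  as.matrix(stats::dist(x))^2
}

# Squared distances between rows of x and rows of y (nrow(x) x nrow(y)).
cross_sq_dists <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) stop("dimension mismatch between query and training features")
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
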