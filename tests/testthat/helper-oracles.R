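# Independent brute-force oracles, deliberately written with explicit loops
# and explicit matrix inversion, unlike the package's solver-based paths.

oracle_kernel <- function(x, y, sigma) exp(-sum((x - y)^2) / (2 * sigma^2))

oracle_kernel_matrix <- function(x1, x2, sigma) {
  K <- matrix(0, nrow(x1), nrow(x2))
  for (i in seq_len(nrow(x1)))
    for (j in seq_len(nrow(x2)))
      K[i, j] <- oracle_kernel(x1[i, ], x2[j, ], sigma)
  K
}

# KRR prediction by explicit inversion of (K + lambda I).
oracle_krr_predict <- function(x_train, a, lambda, sigma, x_query) {
  x_train <- as.matrix(x_train); x_query <- as.matrix(x_query)
  K <- oracle_kernel_matrix(x_train, x_train, sigma)
  w <- solve(K + lambda * diag(nrow(x_train))) %*% a
  drop(oracle_kernel_matrix(x_query, x_train, sigma) %*% w)
}

# S-fold CV error by an explicit loop over folds.
oracle_cv_error <- function(x, a, assignment, lambda, sigma) {
  x <- as.matrix(x)
  s <- max(assignment)
  per_fold <- numeric(s)
  for (f in seq_len(s)) {
    te <- which(assignment == f)
    tr <- which(assignment != f)
    pred <- oracle_krr_predict(x[tr, , drop = FALSE], a[tr], lambda, sigma,
                               x[te, , drop = FALSE])
    per_fold[f] <- mean((a[te] - pred)^2)
  }
  mean(per_fold)
}

# Full subset-search table by nested loops over masks and grid points.
oracle_search <- function(x, a, assignment, grid) {
  d <- ncol(x)
  masks <- seq_len(2^d - 1)
  out <- data.frame(mask = masks, delta = NA_real_,
                    lambda_star = NA_real_, sigma_star = NA_real_)
  for (m in masks) {
    cols <- which(bitwAnd(m, 2^(seq_len(d) - 1)) > 0)
    best <- Inf; bl <- NA; bs <- NA
    for (g in seq_len(nrow(grid))) {
      dl <- oracle_cv_error(x[, cols, drop = FALSE], a, assignment,
                            grid$lambda[g], grid$sigma[g])
      if (dl < best) { best <- dl; bl <- grid$lambda[g]; bs <- grid$sigma[g] }
    }
    out$delta[out$mask == m] <- best
    out$lambda_star[out$mask == m] <- bl
    out$sigma_star[out$mask == m] <- bs
  }
  out
}
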