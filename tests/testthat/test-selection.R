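test_that("fold assignment partitions rows with balanced sizes", {
  f <- make_folds(96, 24, seed = 1)
  expect_equal(sort(unique(f$assignment)), 1:24)
  expect_equal(unname(table(f$assignment)), rep(4, 24), ignore_attr = TRUE)
  # leave-one-out
  loo <- make_folds(10, 10, seed = 2)
  expect_equal(unname(table(loo$assignment)), rep(1, 10), ignore_attr = TRUE)
  # determinism
  expect_identical(make_folds(50, 7, seed = 5)$assignment,
                   make_folds(50, 7, seed = 5)$assignment)
  expect_false(identical(make_folds(50, 7, seed = 5)$assignment,
                         make_folds(50, 7, seed = 6)$assignment))
  expect_error(make_folds(5, 6, seed = 1), "folds")
})

test_that("sample grouping keeps all cycles of one liquid in one fold", {
  groups <- rep(paste0("s", 1:32), each = 3)
  f <- make_folds(96, 24, seed = 3, grouping = "sample", groups = groups)
  per_sample <- tapply(f$assignment, groups, function(v) length(unique(v)))
  expect_true(all(per_sample == 1))
  # sample-level fold sizes balanced to within one unit
  sample_folds <- tapply(f$assignment, groups, unique)
  sz <- table(factor(sample_folds, levels = 1:24))
  expect_lte(max(sz) - min(sz), 1)
})

test_that("cross-validation error matches trivial and closed-form cases", {
  # identical rows, equal targets, lambda = 0: perfect interpolation
  x <- rbind(c(1, 2), c(1, 2))
  f <- fold_assignment(c(1, 2))
  expect_equal(cv_error(x, c(5, 5), f, lambda = 0, sigma = 1), 0)
  # two distinct points, constant target: hand-derived shrinkage offset
  x2 <- rbind(0, 3)
  c0 <- 7; lambda <- 10; sigma <- 5
  k12 <- exp(-9 / (2 * sigma^2))
  closed <- c0^2 * (1 - k12 / (1 + lambda))^2
  expect_equal(cv_error(x2, c(c0, c0), f, lambda, sigma), closed,
               tolerance = 1e-12)
})

test_that("cross-validation error equals an independent fold-loop oracle", {
  set.seed(13)
  x <- matrix(rnorm(36), 12, 3)
  a <- rnorm(12, mean = 20, sd = 10)
  f <- make_folds(12, 4, seed = 2)
  for (pars in list(c(0.1, 1), c(1, 0.5), c(0.001, 3))) {
    expect_equal(cv_error(x, a, f, pars[1], pars[2]),
                 oracle_cv_error(x, a, f$assignment, pars[1], pars[2]),
                 tolerance = 1e-8)
  }
})

test_that("CV error is invariant under fold relabeling and row permutation", {
  set.seed(14)
  x <- matrix(rnorm(30), 10, 3)
  a <- rnorm(10)
  f <- make_folds(10, 5, seed = 1)
  relab <- fold_assignment(((f$assignment + 1) %% 5) + 1)
  expect_equal(cv_error(x, a, f, 0.1, 1), cv_error(x, a, relab, 0.1, 1),
               tolerance = 1e-10)
  p <- sample(10)
  fp <- fold_assignment(f$assignment[p])
  expect_equal(cv_error(x[p, ], a[p], fp, 0.1, 1),
               cv_error(x, a, f, 0.1, 1), tolerance = 1e-10)
})

test_that("grid minimisation returns the first-encountered argmin", {
  set.seed(15)
  x <- matrix(rnorm(20), 10, 2)
  a <- 2 * x[, 1] + rnorm(10, sd = 0.1)
  f <- make_folds(10, 5, seed = 1)
  g1 <- data.frame(lambda = 0.1, sigma = 1)
  one <- optimize_hyperparameters(x, a, f, g1)
  expect_equal(one$lambda_star, 0.1)
  expect_equal(one$sigma_star, 1)
  expect_equal(one$delta_star, cv_error(x, a, f, 0.1, 1))
  # duplicated optimum: the first occurrence wins deterministically
  gdup <- data.frame(lambda = c(0.1, 0.1), sigma = c(1, 1))
  dup <- optimize_hyperparameters(x, a, f, gdup)
  expect_equal(which.min(dup$delta_surface), 1L)
  # the reported optimum is the exhaustive minimum of the surface
  grid <- expand.grid(lambda = c(1e-4, 1e-2, 1), sigma = c(0.5, 1, 5))
  cv <- optimize_hyperparameters(x, a, f, grid)
  expect_equal(cv$delta_star, min(cv$delta_surface))
  expect_true(all(cv$delta_surface >= cv$delta_star))
  expect_error(optimize_hyperparameters(x, a, f, grid[0, ]), "empty")
})

test_that("mask encoding follows the binary-digit convention", {
  expect_equal(encode_mask(c(1, 3, 4)), 13)
  expect_equal(encode_mask(1), 1)
  expect_equal(encode_mask(1:4), 15)
  expect_equal(decode_mask(13, 4), c(1, 3, 4))
  for (m in 1:15) expect_equal(encode_mask(decode_mask(m, 4)), m)
  expect_error(decode_mask(0, 4), "mask")
  expect_error(decode_mask(16, 4), "mask")
  expect_error(encode_mask(integer(0)), "empty")
})

test_that("combination enumeration covers all non-empty subsets", {
  expect_equal(enumerate_combinations(1), 1)
  expect_length(enumerate_combinations(4), 15)
  expect_length(enumerate_combinations(16), 65535)
  expect_error(enumerate_combinations(0), "d")
})

test_that("subset search finds a planted informative feature", {
  set.seed(16)
  a <- runif(12, 0, 40)
  x <- cbind(inf = a / sd(a) + rnorm(12, sd = 0.05),
             n1 = rnorm(12), n2 = rnorm(12))
  f <- make_folds(12, 4, seed = 3)
  grid <- expand.grid(lambda = c(1e-4, 1e-2), sigma = c(1, 10))
  res <- search_combinations(x, a, f, grid)
  best_cols <- decode_mask(res$mask[1], 3)
  expect_true(1 %in% best_cols)
})

test_that("the full search table equals a nested-loop recomputation", {
  set.seed(17)
  a <- runif(8, 0, 40)
  x <- cbind(a / 20 + rnorm(8, sd = 0.3), rnorm(8))
  f <- make_folds(8, 4, seed = 1)
  grid <- expand.grid(lambda = c(1e-3, 0.1), sigma = c(0.5, 2))
  res <- search_combinations(x, a, f, grid)
  ora <- oracle_search(x, a, f$assignment, grid)
  for (m in res$mask) {
    expect_equal(res$delta[res$mask == m], ora$delta[ora$mask == m],
                 tolerance = 1e-8)
    expect_equal(res$lambda_star[res$mask == m],
                 ora$lambda_star[ora$mask == m])
    expect_equal(res$sigma_star[res$mask == m],
                 ora$sigma_star[ora$mask == m])
  }
  expect_true(all(diff(res$delta) >= -1e-12))
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("duplicated best columns tie and the smaller mask ranks first", {
  set.seed(18)
  a <- runif(10, 0, 40)
  good <- a / sd(a) + rnorm(10, sd = 0.05)
  x <- cbind(good, good)
  f <- make_folds(10, 5, seed = 2)
  grid <- data.frame(lambda = 0.01, sigma = 1)
  res <- search_combinations(x, a, f, grid)
  d1 <- res$delta[res$mask == 1]
  d2 <- res$delta[res$mask == 2]
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_lt(res$rank[res$mask == 1], res$rank[res$mask == 2])
})

test_that("usage rates count feature membership among the top combinations", {
  set.seed(19)
  a <- runif(9, 0, 40)
  x <- cbind(`ch:p1` = a / 10 + rnorm(9, sd = 0.1), `ch:p2` = rnorm(9))
  f <- make_folds(9, 3, seed = 1)
  res <- search_combinations(x, a, f, data.frame(lambda = 0.01, sigma = 1))
  u1 <- usage_rates(res, top_k = 1)
  expect_equal(u1$usage_rate[u1$feature == "ch:p1"], 100)
  expect_equal(u1$usage_rate[u1$feature == "ch:p2"], 0)
  # over all three masks of two features each appears in 2 of 3
  uall <- usage_rates(res, top_k = 3)
  expect_equal(uall$usage_rate, rep(200 / 3, 2), tolerance = 1e-12)
  expect_error(usage_rates(res, 0), "top_k")
  expect_error(usage_rates(res, 4), "top_k")
})

test_that("held-out evaluation interpolates and counts parity records", {
  set.seed(20)
  x <- matrix(rnorm(24), 12, 2)
  x[10, ] <- x[1, ]  # unknown row duplicating a training row
  a <- rnorm(12, 20, 10)
  a[10] <- a[1]
  known <- rep(TRUE, 12); known[10:12] <- FALSE
  fm <- make_fm(x, a, known = known,
                sample = rep(paste0("s", 1:4), each = 3),
                t_a = rep(c(60, 80, 100), 4))
  fm <- normalize_features(fm)
  fit <- krr(fm$x[known, ], a[known], lambda = 0, sigma = 1)
  rec <- evaluate_unknowns(fit, fm)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$predicted[1], a[1], tolerance = 1e-6)
  expect_false(any(rec$known))
})

test_that("usage of the uninformative quasi-equilibrium slope is lowest on a hydrophobic channel", {
  ds <- default_dataset(seed = 1)
  fm <- normalize_features(extract_features(ds))
  known <- which(fm$known)
  f <- make_folds(length(known), 24, seed = 2, grouping = "sample",
                  groups = fm$sample[known])
  cols <- grep("^c18_np:", colnames(fm$x))
  res <- search_combinations(fm$x[known, cols], fm$a[known], f,
                             grid = small_grid())
  u <- usage_rates(res, top_k = 7)
  p2 <- u$usage_rate[u$feature == "c18_np:p2"]
  expect_lt(p2, u$usage_rate[u$feature == "c18_np:p1"])
  expect_lt(p2, u$usage_rate[u$feature == "c18_np:p3"])
  expect_lt(p2, u$usage_rate[u$feature == "c18_np:p4"])
})
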