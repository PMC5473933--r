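#' Random fold assignment for S-fold cross-validation
#'
#' Randomly partitions N observations into S folds. With
#' `grouping = "row"` the rows themselves are shuffled and dealt into folds,
#' giving fold sizes `N/S` when S divides N (differing by at most one
#' otherwise). With `grouping = "sample"` the grouping units are whole
#' samples, so the three cycles of one liquid always share a fold and cannot
#' leak near-duplicate observations between training and testing; fold sizes
#' are then balanced in samples rather than rows.
#'
#' @param n Number of observations (ignored if `groups` given with
#'   `grouping = "row"`).
#' @param s Number of folds, `2 <= s <= number of grouping units`.
#' @param seed Integer seed; the same `(n, s, seed)` always gives the same
#'   assignment.
#' @param grouping `"row"` or `"sample"`.
#' @param groups For `grouping = "sample"`: vector of sample identifiers,
#'   one per row.
#' @return An object of class `fold_assignment`: list with `s`,
#'   `assignment` (fold label in 1..s per row), `seed`, `grouping`.
#' @examples
#' f <- make_folds(96, 24, seed = 1)
#' table(f$assignment)  # 24 folds of 4 rows
#' @export
make_folds <- function(n, s, seed = 1, grouping = c("row", "sample"),
                       groups = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "sample") {
    if (is.null(groups)) stop("grouping = 'sample' requires groups")
    if (length(groups) != n) stop("groups must have length n")
    units <- unique(groups)
  } else {
    units <- seq_len(n)
  }
  if (s < 2) stop("need at least 2 folds")
  if (s > length(units))
    stop("more folds (", s, ") than grouping units (", length(units), ")")
  unit_fold <- with_seed(seed, {
    sizes <- rep(length(units) %/% s, s)
    extra <- length(units) %% s
    if (extra > 0) {
      grow <- sample.int(s, extra)
      sizes[grow] <- sizes[grow] + 1
    }
    sample(rep(seq_len(s), times = sizes))
  })
  assignment <- if (grouping == "sample") {
    unit_fold[match(groups, units)]
  } else {
    unit_fold
  }
  structure(list(s = s, assignment = assignment, seed = seed,
                 grouping = grouping),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(x$s, "-fold assignment over ", length(x$assignment), " rows (grouping: ",
      x$grouping, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Core CV engine: cross-validation error Delta(lambda, sigma) for every grid
# point, given a precomputed squared-distance matrix d2 (n x n). Grid points
# whose linear systems are singular get NA. Kernel matrices are computed once
# per sigma and shared across lambdas and folds.
cv_surface <- function(d2, a, folds, grid) {
  stopifnot(inherits(folds, "fold_assignment"))
  assignment <- folds$assignment
  n <- length(a)
  if (nrow(d2) != n) stop("d2 / target size mismatch")
  s <- folds$s
  for (f in seq_len(s)) {
    if (sum(assignment != f) == 0) stop("fold ", f, " leaves an empty training set")
  }
  delta <- numeric(nrow(grid))
  for (sig in unique(grid$sigma)) {
    K <- kernel_from_d2(d2, sig)
    rows <- which(grid$sigma == sig)
    acc <- stats::setNames(numeric(length(rows)), NULL)
    bad <- logical(length(rows))
    for (f in seq_len(s)) {
      te <- which(assignment == f)
      tr <- which(assignment != f)
      K_tr <- K[tr, tr, drop = FALSE]
      K_te <- K[te, tr, drop = FALSE]
      for (j in seq_along(rows)) {
        if (bad[j]) next
        lam <- grid$lambda[rows[j]]
        alpha <- tryCatch(solve_dual(K_tr, lam, a[tr]),
                          error = function(e) NULL)
        if (is.null(alpha)) { bad[j] <- TRUE; next }
        pred <- drop(K_te %*% alpha)
        acc[j] <- acc[j] + mean((a[te] - pred)^2) / s
      }
    }
    delta[rows] <- ifelse(bad, NA_real_, acc)
  }
  delta
}

#' Cross-validation error at one hyperparameter point
#'
#' For each fold s, a model is fitted on the remaining folds and the
#' mean-square deviation between actual and predicted targets is computed on
#' the held-out fold; the S per-fold deviations are averaged. Feature
#' normalisation is not recomputed per fold: the matrix is assumed already
#' scaled once on the full training set.
#'
#' @param x Feature matrix (rows = observations), already normalised.
#' @param a Target vector (vol %).
#' @param folds A [make_folds()] assignment over the rows of `x`.
#' @param lambda,sigma Hyperparameters.
#' @return The cross-validation error (squared vol %).
#' @export
cv_error <- function(x, a, folds, lambda, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  d2 <- pairwise_sq_dists(x)
  delta <- cv_surface(d2, a, folds, data.frame(lambda = lambda, sigma = sigma))
  if (is.na(delta))
    stop("singular system at (lambda, sigma) = (", lambda, ", ", sigma, ")")
  delta
}

#' Default hyperparameter grids
#'
#' `default_grid()` is the full log-spaced grid: 9 ridge strengths
#' `10^-6 .. 10^2` by 9 kernel widths `10^-2 .. 10^2` (81 points, lambda
#' varying fastest). `small_grid()` is the reduced 5 x 5 grid spanning the
#' same ranges, used for large subset searches.
#'
#' @return Data.frame with columns `lambda` and `sigma`.
#' @export
default_grid <- function() {
  expand.grid(lambda = 10^seq(-6, 2, length.out = 9),
              sigma = 10^seq(-2, 2, length.out = 9))
}

#' @rdname default_grid
#' @export
small_grid <- function() {
  expand.grid(lambda = 10^seq(-6, 2, length.out = 5),
              sigma = 10^seq(-2, 2, length.out = 5))
}

#' Joint (lambda, sigma) grid minimisation of the CV error
#'
#' Evaluates the cross-validation error on every grid point and returns the
#' minimiser; ties are broken by the first occurrence in grid order.
#'
#' @param x Normalised feature matrix.
#' @param a Target vector.
#' @param folds A [make_folds()] assignment.
#' @param grid Data.frame with `lambda` and `sigma` columns (see
#'   [default_grid()]).
#' @param d2 Optional precomputed squared-distance matrix of `x`'s rows.
#' @return An object of class `cv_result`: list with `grid`,
#'   `delta_surface`, `lambda_star`, `sigma_star`, `delta_star`.
#' @export
optimize_hyperparameters <- function(x, a, folds, grid = default_grid(),
                                     d2 = NULL) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(d2)) d2 <- pairwise_sq_dists(x)
  delta <- cv_surface(d2, a, folds, grid)
  if (all(is.na(delta))) stop("all grid points failed (singular systems)")
  best <- which.min(delta)  # first occurrence on ties, NAs skipped
  structure(list(grid = grid, delta_surface = delta,
                 lambda_star = grid$lambda[best],
                 sigma_star = grid$sigma[best],
                 delta_star = delta[best]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CV grid search over", nrow(x$grid), "points: Delta =",
      format(x$delta_star, digits = 6), "at lambda =",
      format(x$lambda_star), ", sigma =", format(x$sigma_star), "\n")
  invisible(x)
}
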