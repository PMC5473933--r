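#' Gaussian kernel
#'
#' `k(x, y) = exp(-|x - y|^2 / (2 sigma^2))`, the similarity measure used
#' throughout the package's kernel ridge regression.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Kernel width, > 0.
#' @return A number in (0, 1].
#' @examples
#' gaussian_kernel(c(0, 0), c(0, 0), 1)  # 1
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(x) != length(y)) stop("x and y must have equal length")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# Kernel matrix from a squared-distance matrix.
kernel_from_d2 <- function(d2, sigma) exp(-d2 / (2 * sigma^2))

# Solve (K + lambda I) alpha = a. Cholesky first (K + lambda I is symmetric
# positive definite for lambda > 0 and for distinct points at lambda = 0),
# generic solve as fallback; the residual is checked either way.
solve_dual <- function(K, lambda, a) {
  n <- nrow(K)
  M <- K + diag(lambda, n)
  alpha <- tryCatch({
    R <- chol(M)
    backsolve(R, backsolve(R, a, transpose = TRUE))
  }, error = function(e) {
    tryCatch(solve(M, a), error = function(e2)
      stop("K + lambda*I is singular; use lambda > 0", call. = FALSE))
  })
  resid <- sqrt(sum((M %*% alpha - a)^2))
  if (resid > 1e-8 * max(sqrt(sum(a^2)), .Machine$double.eps))
    stop("K + lambda*I is numerically singular (residual ", format(resid),
         "); use lambda > 0", call. = FALSE)
  drop(alpha)
}

#' Fit a Gaussian-kernel ridge regression model
#'
#' Fits the dual form of kernel ridge regression: with kernel matrix
#' `K[n, m] = k(X_n, X_m)` over the training rows, the dual weights are
#' `alpha = (K + lambda I)^{-1} A` and a query `x` is predicted as
#' `A*(x) = sum_n k(X_n, x) alpha_n`. The weights are obtained by solving
#' the linear system (Cholesky factorisation, never an explicit inverse).
#'
#' Features are expected on a common scale (see [normalize_features()]);
#' targets are alcohol contents in vol %, but any numeric response works.
#'
#' @param x Training feature matrix (N x d), or a `feature_matrix` (its
#'   known rows are used).
#' @param a Numeric response vector of length N; taken from the
#'   `feature_matrix` when `x` is one.
#' @param lambda Ridge strength, >= 0 (0 only when K is invertible, i.e.
#'   all training points distinct).
#' @param sigma Gaussian kernel width, > 0.
#' @return An object of class `krr` with elements `x_train`, `a`, `lambda`,
#'   `sigma`, `dual_weights` and `labels`. Methods: `print`, `summary`,
#'   `coef` (dual weights), `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' a <- rowSums(x)
#' fit <- krr(x, a, lambda = 0.1, sigma = 1)
#' predict(fit, x[1:2, , drop = FALSE])
#' @export
krr <- function(x, a = NULL, lambda, sigma) {
  if (inherits(x, "feature_matrix")) {
    rows <- which(x$known)
    a <- a %||% x$a[rows]
    x <- x$x[rows, , drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(a)) stop("response vector a is required")
  if (length(a) != nrow(x)) stop("length(a) must equal nrow(x)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  K <- kernel_from_d2(pairwise_sq_dists(x), sigma)
  alpha <- solve_dual(K, lambda, a)
  structure(list(x_train = x, a = a, lambda = lambda, sigma = sigma,
                 dual_weights = alpha, labels = colnames(x)),
            class = "krr")
}

#' Predict alcohol content for new observations
#'
#' @param object A fitted `krr` model.
#' @param newdata Query matrix (rows = observations) or vector (one query);
#'   a `feature_matrix` is also accepted (all its rows are predicted).
#' @param ... Unused.
#' @return Numeric vector of predictions (vol %).
#' @export
predict.krr <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_train))
    stop("query dimension (", ncol(newdata), ") does not match training (",
         ncol(object$x_train), ")")
  Kq <- kernel_from_d2(cross_sq_dists(newdata, object$x_train), object$sigma)
  drop(Kq %*% object$dual_weights)
}

#' @export
fitted.krr <- function(object, ...) predict(object, object$x_train)

#' @export
residuals.krr <- function(object, ...) object$a - fitted(object)

#' @export
coef.krr <- function(object, ...) object$dual_weights

#' @export
print.krr <- function(x, ...) {
  cat("Gaussian-kernel ridge regression\n")
  cat("  n =", nrow(x$x_train), " d =", ncol(x$x_train),
      " lambda =", format(x$lambda), " sigma =", format(x$sigma), "\n")
  invisible(x)
}

#' @export
summary.krr <- function(object, ...) {
  r <- residuals(object)
  out <- list(n = nrow(object$x_train), d = ncol(object$x_train),
              lambda = object$lambda, sigma = object$sigma,
              train_rmse = sqrt(mean(r^2)), labels = object$labels)
  class(out) <- "summary.krr"
  out
}

#' @export
print.summary.krr <- function(x, ...) {
  cat("Gaussian-kernel ridge regression\n")
  cat("  training points:", x$n, " features:", x$d, "\n")
  cat("  lambda:", format(x$lambda), " sigma:", format(x$sigma), "\n")
  cat("  training RMSE:", format(x$train_rmse, digits = 4), "vol %\n")
  if (!is.null(x$labels)) cat("  features:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Parity plot of a fitted model
#'
#' @param x A `krr` model.
#' @param newdata,actual Optional held-out features and targets added in red.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.krr <- function(x, newdata = NULL, actual = NULL, ...) {
  pred <- fitted(x)
  rng <- range(c(x$a, pred, actual))
  graphics::plot(x$a, pred, xlim = rng, ylim = rng, col = "blue",
                 xlab = "actual alcohol content (vol %)",
                 ylab = "predicted alcohol content (vol %)", ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(newdata)) {
    p2 <- predict(x, newdata)
    graphics::points(actual, p2, col = "red", pch = 19)
  }
  invisible(x)
}

#' Serialize / restore a fitted model as structured text
#'
#' Writes the training matrix, targets, hyperparameters, dual weights,
#' column labels and (if present) normalisation divisors to a plain-text
#' file readable by [read_krr()].
#'
#' @param model A `krr` model.
#' @param path File path.
#' @param normalization_sds Optional named vector of the feature scaling
#'   divisors used before fitting, stored alongside.
#' @return `read_krr()` returns the `krr` model (with attribute
#'   `normalization_sds` when stored).
#' @export
write_krr <- function(model, path, normalization_sds = NULL) {
  stopifnot(inherits(model, "krr"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  lines <- c(
    "# krr model",
    paste0("lambda\t", sprintf("%.17g", model$lambda)),
    paste0("sigma\t", sprintf("%.17g", model$sigma)),
    paste0("labels\t", paste(model$labels %||% character(0), collapse = "\t")),
    paste0("norm_sds\t", if (is.null(normalization_sds)) "" else num(normalization_sds)),
    paste0("a\t", num(model$a)),
    paste0("dual_weights\t", num(model$dual_weights)),
    "x_train:",
    vapply(seq_len(nrow(model$x_train)),
           function(i) num(model$x_train[i, ]), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_krr
#' @export
read_krr <- function(path) {
  lines <- readLines(path)
  fld <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, "\t"))][1]
    strsplit(sub(paste0("^", key, "\t"), "", ln), "\t")[[1]]
  }
  lambda <- as.numeric(fld("lambda"))
  sigma <- as.numeric(fld("sigma"))
  labels <- fld("labels")
  norm_raw <- suppressWarnings(as.numeric(fld("norm_sds")))
  a <- as.numeric(fld("a"))
  w <- as.numeric(fld("dual_weights"))
  xi <- which(lines == "x_train:")
  x <- do.call(rbind, lapply(lines[(xi + 1):length(lines)],
                             function(l) as.numeric(strsplit(l, "\t")[[1]])))
  if (length(labels) == ncol(x)) colnames(x) <- labels
  model <- structure(list(x_train = x, a = a, lambda = lambda, sigma = sigma,
                          dual_weights = w,
                          labels = if (length(labels)) labels else NULL),
                     class = "krr")
  if (length(norm_raw) && !all(is.na(norm_raw)))
    attr(model, "normalization_sds") <- norm_raw
  model
}
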