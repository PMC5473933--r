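#' Bitmask labelling of feature combinations
#'
#' A subset of the d features is labelled by the decimal integer whose i-th
#' binary digit (least significant first) is 1 when feature i is used. With
#' four features per channel, the combination using parameters 1, 3 and 4 is
#' 1101 in binary, i.e. label 13.
#'
#' @param parameters Integer vector of selected feature indices (1-based).
#' @param mask Positive integer in `[1, 2^d - 1]`.
#' @param d Number of features.
#' @return `encode_mask()` a positive integer; `decode_mask()` a sorted
#'   integer vector of indices.
#' @examples
#' encode_mask(c(1, 3, 4))  # 13
#' decode_mask(13, 4)       # 1 3 4
#' @export
encode_mask <- function(parameters) {
  parameters <- unique(as.integer(parameters))
  if (length(parameters) == 0) stop("empty feature subset")
  if (any(parameters < 1)) stop("feature indices are 1-based")
  sum(2^(parameters - 1))
}

#' @rdname encode_mask
#' @export
decode_mask <- function(mask, d) {
  mask <- as.numeric(mask)
  if (mask < 1 || mask >= 2^d) stop("mask must be in [1, 2^d - 1]")
  which(bitwAnd(as.integer(mask), as.integer(2^(seq_len(d) - 1))) > 0)
}

# Binary string of a mask in the display convention (feature d leftmost),
# e.g. mask 13, d = 4 -> "1101".
mask_bits <- function(mask, d) {
  paste(rev(as.integer(bitwAnd(as.integer(mask),
                               as.integer(2^(seq_len(d) - 1))) > 0)),
        collapse = "")
}

#' Enumerate all non-empty feature combinations
#'
#' @param d Number of features (>= 1).
#' @return Integer vector `1:(2^d - 1)` of combination masks.
#' @examples
#' length(enumerate_combinations(4))   # 15
#' length(enumerate_combinations(16))  # 65535
#' @export
enumerate_combinations <- function(d) {
  if (d < 1) stop("d must be >= 1")
  seq_len(2^d - 1)
}

#' Exhaustive feature-subset search
#'
#' For every combination mask, the feature matrix is restricted to the
#' selected columns, the (lambda, sigma) grid is minimised by S-fold
#' cross-validation, and the resulting prediction error Delta is recorded.
#' Results are ranked by ascending Delta, ties broken by the smaller mask.
#' The per-column squared-distance matrices are precomputed once and summed
#' per mask, so the grid search never recomputes pairwise distances.
#'
#' @param x Normalised feature matrix (training rows only), or a
#'   `feature_matrix` whose known rows are used.
#' @param a Target vector (taken from the `feature_matrix` if omitted).
#' @param folds A [make_folds()] assignment over the rows.
#' @param grid Hyperparameter grid (see [default_grid()]).
#' @param masks Integer masks to evaluate; default all `2^d - 1` non-empty
#'   combinations.
#' @return An object of class `subset_search`: a data.frame with columns
#'   `mask`, `bits`, `delta`, `lambda_star`, `sigma_star`, `rank` and
#'   `error` (NA unless that mask's grid search failed), ordered by rank,
#'   with attribute `labels` (the feature column labels).
#' @export
search_combinations <- function(x, a = NULL, folds, grid = default_grid(),
                                masks = NULL) {
  if (inherits(x, "feature_matrix")) {
    rows <- which(x$known)
    a <- a %||% x$a[rows]
    x <- x$x[rows, , drop = FALSE]
  }
  x <- as.matrix(x)
  d <- ncol(x)
  masks <- masks %||% enumerate_combinations(d)
  if (any(masks < 1 | masks >= 2^d)) stop("mask out of range for ", d, " features")
  labels <- colnames(x) %||% paste0("f", seq_len(d))
  d2_cols <- lapply(seq_len(d), function(j) outer(x[, j], x[, j], "-")^2)
  res <- data.frame(mask = masks,
                    bits = vapply(masks, mask_bits, "", d = d),
                    delta = NA_real_, lambda_star = NA_real_,
                    sigma_star = NA_real_, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(masks)) {
    cols <- decode_mask(masks[i], d)
    d2 <- Reduce(`+`, d2_cols[cols])
    cv <- tryCatch(
      optimize_hyperparameters(x[, cols, drop = FALSE], a, folds, grid, d2 = d2),
      error = function(e) e)
    if (inherits(cv, "error")) {
      res$error[i] <- conditionMessage(cv)
    } else {
      res$delta[i] <- cv$delta_star
      res$lambda_star[i] <- cv$lambda_star
      res$sigma_star[i] <- cv$sigma_star
    }
  }
  ord <- order(res$delta, res$mask, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "labels") <- labels
  class(res) <- c("subset_search", "data.frame")
  res
}

#' @export
print.subset_search <- function(x, n = 10, ...) {
  cat("Feature-subset search:", nrow(x), "combinations over",
      length(attr(x, "labels")), "features\n")
  cat("features:", paste(attr(x, "labels"), collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Usage rate of each feature among the top-ranked combinations
#'
#' The percentage of the `top_k` best-ranked masks that include each
#' feature — the standard summary of which channel/parameter pairs matter.
#'
#' @param results A `subset_search` result.
#' @param top_k How many top-ranked combinations to count over.
#' @return Data.frame with columns `feature` and `usage_rate` (percent).
#' @examples
#' # with two features the three masks are {1}, {2}, {1,2}: each feature
#' # appears in 2 of 3, so over all results both rates are 66.7 %
#' @export
usage_rates <- function(results, top_k) {
  stopifnot(inherits(results, "subset_search"))
  if (top_k < 1) stop("top_k must be >= 1")
  if (top_k > nrow(results)) stop("top_k exceeds the number of results")
  labels <- attr(results, "labels")
  d <- length(labels)
  top <- results$mask[results$rank <= top_k]
  rate <- vapply(seq_len(d), function(j)
    100 * mean(bitwAnd(as.integer(top), as.integer(2^(j - 1))) > 0), 0)
  data.frame(feature = labels, usage_rate = rate, stringsAsFactors = FALSE)
}

#' Predict held-out samples with a fitted model
#'
#' Produces one parity record (sample, cycle start, actual, predicted) per
#' held-out row. The rows must already carry the training normalisation
#' (they are scaled together with the training rows by
#' [normalize_features()], which uses known-row statistics only).
#'
#' @param model A fitted [krr()] model.
#' @param features A normalised `feature_matrix` containing the held-out
#'   rows.
#' @param rows Row indices to predict; default all rows with
#'   `known = FALSE`.
#' @param cols Column indices the model was fitted on (default: all).
#' @return Data.frame with columns `sample`, `t_a`, `actual`, `predicted`,
#'   `known`.
#' @export
evaluate_unknowns <- function(model, features, rows = NULL, cols = NULL) {
  stopifnot(inherits(model, "krr"), inherits(features, "feature_matrix"))
  if (is.null(features$normalization_sds))
    stop("features must be normalised before prediction")
  rows <- rows %||% which(!features$known)
  x <- features$x[rows, , drop = FALSE]
  if (!is.null(cols)) x <- x[, cols, drop = FALSE]
  data.frame(sample = features$sample[rows],
             t_a = features$t_a[rows],
             actual = features$a[rows],
             predicted = predict(model, x),
             known = features$known[rows],
             stringsAsFactors = FALSE)
}
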