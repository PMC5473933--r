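#' Rank correlation of each feature with alcohol content
#'
#' Spearman rank correlation of every feature column against the alcohol
#' content over all rows, the screening summary used to judge which cycle
#' parameters are informative before any model is fitted.
#'
#' @param features A `feature_matrix` (normalisation does not affect rank
#'   correlations).
#' @return Data.frame with columns `feature`, `channel`, `parameter`, `rho`;
#'   `rho` is NA for a constant column.
#' @export
correlation_summary <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  if (nrow(features$x) < 3) stop("need at least 3 rows")
  labels <- colnames(features$x)
  rho <- vapply(seq_len(ncol(features$x)), function(j) {
    v <- features$x[, j]
    if (sd_n(v) == 0) return(NA_real_)
    stats::cor(v, features$a, method = "spearman")
  }, 0)
  data.frame(feature = labels,
             channel = sub(":p[1-4]$", "", labels),
             parameter = as.integer(sub("^.*:p", "", labels)),
             rho = rho, stringsAsFactors = FALSE)
}

#' Principal-component scores of the feature matrix
#'
#' Column-centres the (already sd-scaled) feature matrix and projects it
#' onto the leading principal axes. The sign of each axis is fixed by making
#' its largest-magnitude loading positive, so scores are reproducible.
#'
#' @param features A `feature_matrix` or a plain numeric matrix.
#' @param n_components Number of components to return; must not exceed the
#'   rank of the centred matrix.
#' @return List with `scores` (N x n_components), `explained_variance`
#'   (fractions, nonincreasing) and `loadings`.
#' @export
pca_scores <- function(features, n_components = 2) {
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds the rank (", rank, ")")
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, keep, drop = FALSE], 2, flip, "*")
  list(scores = scores, explained_variance = ev[keep], loadings = loadings)
}
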