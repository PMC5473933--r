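#' Anchor points of one response cycle
#'
#' Reads the five anchor values of one injection/purge cycle starting at
#' `t_a`: `a`, `b`, `c`, `d` are the signal values at the sampling instants
#' nearest `t_a`, `t_a + 1`, `t_a + 10` and `t_a + 11` s, and `e` is the
#' maximum signal over the half-open cycle window `[t_a, t_a + period)`.
#' With the standard schedule, `t_a` is the injection onset, `c` sits at the
#' injection end and `d` one second into the purge.
#'
#' @param signal A `response_signal`.
#' @param t_a Cycle start time (s).
#' @param offset_b,offset_c,offset_d Offsets (s) of the `b`, `c`, `d` anchors
#'   from `t_a`; defaults 1, 10 and 11 s.
#' @return An object of class `cycle_points`: list with `t_a`, `t_b`, `t_c`,
#'   `t_d` and `a`, `b`, `c`, `d`, `e`.
#' @export
extract_cycle_points <- function(signal, t_a,
                                 offset_b = 1, offset_c = 10, offset_d = 11) {
  stopifnot(inherits(signal, "response_signal"))
  period <- signal$schedule$period
  times <- signal$times
  if (t_a < min(times) - 1e-9 || t_a + period > max(times) + 1 / signal$schedule$sampling_rate + 1e-9)
    stop("cycle window [", t_a, ", ", t_a + period, ") outside trace span")
  nearest <- function(t) which.min(abs(times - t))
  i_a <- nearest(t_a); i_b <- nearest(t_a + offset_b)
  i_c <- nearest(t_a + offset_c); i_d <- nearest(t_a + offset_d)
  win <- times >= t_a - 1e-9 & times < t_a + period - 1e-9
  if (!any(win)) stop("empty cycle window at t_a = ", t_a)
  structure(list(t_a = t_a, t_b = t_a + offset_b, t_c = t_a + offset_c,
                 t_d = t_a + offset_d,
                 a = signal$values[i_a], b = signal$values[i_b],
                 c = signal$values[i_c], d = signal$values[i_d],
                 e = max(signal$values[win])),
            class = "cycle_points")
}

#' Four kinetic parameters of one response cycle
#'
#' Computes the feature parameters of a cycle from its anchor points:
#' \describe{
#'   \item{p1}{`(b - a) / (t_b - t_a)` — initial-rise slope (adsorption).}
#'   \item{p2}{`(c - b) / (t_c - t_b)` — quasi-equilibrium slope.}
#'   \item{p3}{`(d - c) / (t_d - t_c)` — initial-decay slope (desorption).}
#'   \item{p4}{`e - a` — maximum height above the cycle's start value.}
#' }
#'
#' @param points A `cycle_points` object.
#' @return Named numeric vector `c(p1, p2, p3, p4)` (slopes in mV/s, height
#'   in mV).
#' @examples
#' pts <- structure(list(t_a = 0, t_b = 1, t_c = 10, t_d = 11,
#'                       a = 0, b = 1, c = 10, d = 9, e = 10),
#'                  class = "cycle_points")
#' compute_parameters(pts)  # 1 1 -1 10
#' @export
compute_parameters <- function(points) {
  stopifnot(inherits(points, "cycle_points"))
  dt1 <- points$t_b - points$t_a
  dt2 <- points$t_c - points$t_b
  dt3 <- points$t_d - points$t_c
  if (any(c(dt1, dt2, dt3) == 0)) stop("coincident anchor times")
  c(p1 = (points$b - points$a) / dt1,
    p2 = (points$c - points$b) / dt2,
    p3 = (points$d - points$c) / dt3,
    p4 = points$e - points$a)
}

#' Build the feature matrix from a collection of signals
#'
#' Extracts the four cycle parameters at each requested cycle start for every
#' channel, and assembles one observation row per (sample, cycle start).
#' Columns are ordered channel-major, parameter-minor and labelled
#' `"<channel>:p<k>"`. The default cycle starts 60, 80 and 100 s are the
#' last three of the standard five-cycle schedule, whose burn-in has settled.
#'
#' @param signals A `sensor_dataset` or a list of `response_signal`s.
#' @param metadata Data.frame with columns `sample`, `alcohol_content` and
#'   optionally `known`; taken from the dataset when `signals` is a
#'   `sensor_dataset`.
#' @param t_a Numeric vector of cycle start times (s).
#' @return An object of class `feature_matrix`: list with `x` (N x d
#'   matrix), `a` (alcohol contents, vol %), `sample`, `t_a`, `known`,
#'   `channels` and `normalization_sds` (NULL until normalised).
#' @examples
#' ds <- simulate_dataset(generator_config(seed = 1))
#' fm <- extract_features(ds)
#' dim(fm$x)  # 105 x 16
#' @export
extract_features <- function(signals, metadata = NULL, t_a = c(60, 80, 100)) {
  if (inherits(signals, "sensor_dataset")) {
    metadata <- metadata %||% signals$metadata
    signals <- signals$signals
  }
  if (is.null(metadata)) stop("metadata required when signals is a plain list")
  chans <- unique(vapply(signals, `[[`, "", "channel_name"))
  samp_of <- vapply(signals, `[[`, "", "sample_name")
  chan_of <- vapply(signals, `[[`, "", "channel_name")
  missing <- character(0)
  for (s in metadata$sample) {
    for (ch in chans) {
      if (!any(samp_of == s & chan_of == ch))
        missing <- c(missing, paste0(s, "/", ch))
    }
  }
  if (length(missing) > 0)
    stop("missing signals for: ", paste(missing, collapse = ", "))
  d <- 4L * length(chans)
  n <- nrow(metadata) * length(t_a)
  x <- matrix(NA_real_, n, d)
  colnames(x) <- paste0(rep(chans, each = 4), ":p", 1:4)
  samp_col <- character(n); ta_col <- numeric(n)
  row <- 1L
  for (i in seq_len(nrow(metadata))) {
    for (tt in t_a) {
      feats <- numeric(0)
      for (ch in chans) {
        sig <- signals[[which(samp_of == metadata$sample[i] & chan_of == ch)[1]]]
        feats <- c(feats, compute_parameters(extract_cycle_points(sig, tt)))
      }
      x[row, ] <- feats
      samp_col[row] <- metadata$sample[i]
      ta_col[row] <- tt
      row <- row + 1L
    }
  }
  known <- metadata$known %||% rep(TRUE, nrow(metadata))
  structure(list(
    x = x,
    a = rep(metadata$alcohol_content, each = length(t_a)),
    sample = samp_col,
    t_a = ta_col,
    known = rep(known, each = length(t_a)),
    channels = chans,
    normalization_sds = NULL
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "observations x", ncol(x$x), "features (",
      length(x$channels), "channels ),", sum(x$known), "known rows\n")
  if (!is.null(x$normalization_sds)) cat("  normalised (unit-sd columns over reference rows)\n")
  invisible(x)
}

#' Normalise feature columns by their training-set standard deviation
#'
#' Divides every column by its population (divisor-n) standard deviation
#' computed over the reference rows — by default the known (training)
#' samples — and records the divisors so the same scaling applies to
#' held-out rows. After normalisation each column has unit standard
#' deviation over the reference rows.
#'
#' @param features A `feature_matrix`.
#' @param reference_rows Integer indices of the rows defining the scale;
#'   default `which(features$known)`.
#' @return The `feature_matrix` with scaled `x` and `normalization_sds` set.
#' @export
normalize_features <- function(features, reference_rows = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  ref <- reference_rows %||% which(features$known)
  if (length(ref) < 2) stop("need at least 2 reference rows")
  sds <- apply(features$x[ref, , drop = FALSE], 2, sd_n)
  bad <- which(sds <= .Machine$double.eps^0.5 * pmax(1, abs(colMeans(features$x[ref, , drop = FALSE]))))
  if (length(bad) > 0)
    stop("zero-variance feature column(s): ",
         paste(colnames(features$x)[bad], collapse = ", "))
  features$x <- sweep(features$x, 2, sds, "/")
  features$normalization_sds <- sds
  features
}

#' Restrict a feature matrix to selected rows and/or columns
#'
#' @param features A `feature_matrix`.
#' @param rows,cols Index vectors (default: keep all).
#' @return A `feature_matrix` on the subset.
#' @export
subset_features <- function(features, rows = NULL, cols = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  rows <- rows %||% seq_len(nrow(features$x))
  cols <- cols %||% seq_len(ncol(features$x))
  features$x <- features$x[rows, cols, drop = FALSE]
  features$a <- features$a[rows]
  features$sample <- features$sample[rows]
  features$t_a <- features$t_a[rows]
  features$known <- features$known[rows]
  if (!is.null(features$normalization_sds))
    features$normalization_sds <- features$normalization_sds[cols]
  features$channels <- unique(sub(":p[1-4]$", "", colnames(features$x)))
  features
}
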