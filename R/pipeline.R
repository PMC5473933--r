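#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: the generator
#' configuration, which cycle starts to extract, the fold count and
#' grouping policy of the cross-validation, the hyperparameter grid, and
#' how many top combinations enter the usage-rate table. Everything
#' downstream is a deterministic function of this object.
#'
#' @param seed Master seed (drives the generator and the fold assignment).
#' @param schedule,channels,samples Passed to [generator_config()].
#' @param t_a Cycle start times (s) used for feature extraction.
#' @param s_folds Number of cross-validation folds.
#' @param grouping Fold grouping policy, `"sample"` (default; the three
#'   cycles of one liquid share a fold) or `"row"`.
#' @param grid Hyperparameter grid; [default_grid()] by default, use
#'   [small_grid()] for faster searches.
#' @param top_k Top-ranked combinations counted in the usage-rate table.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            schedule = acquisition_schedule(),
                            channels = default_channels(),
                            samples = default_sample_table(),
                            t_a = c(60, 80, 100),
                            s_folds = 24,
                            grouping = c("sample", "row"),
                            grid = default_grid(),
                            top_k = 10) {
  grouping <- match.arg(grouping)
  structure(list(
    generator = generator_config(schedule = schedule, channels = channels,
                                 samples = samples, seed = seed),
    seed = as.integer(seed), t_a = t_a, s_folds = s_folds,
    grouping = grouping, grid = grid, top_k = top_k
  ), class = "pipeline_config")
}

#' Run the full smell-analysis pipeline
#'
#' Simulates (or accepts) a sensor dataset, extracts and normalises the
#' cycle features, builds grouped cross-validation folds over the known
#' rows, runs the exhaustive per-channel feature-subset search, fits the
#' globally best model, predicts the held-out samples, and assembles
#' correlation, usage-rate and principal-component summaries. The whole
#' bundle is a deterministic function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional precomputed `sensor_dataset`; by default
#'   simulated from `config`.
#' @return An object of class `alcosense_report`: list with `features`
#'   (normalised), `folds`, `per_channel` (one `subset_search` per
#'   channel), `channel_optima` (data.frame channel/mask/delta), `best`
#'   (channel, mask, columns, lambda, sigma, delta), `model`, `parity`
#'   (known and unknown records), `unknown_mse`, `usage` (per-channel
#'   usage-rate tables), `correlations`, `pca`, `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(seed = 1, grid = small_grid()))
#' rep$best
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("simulate", dataset %||% simulate_dataset(config$generator))
  fm <- stage("extract", extract_features(ds, t_a = config$t_a))
  fm <- stage("normalize", normalize_features(fm))
  known_rows <- which(fm$known)
  folds <- stage("folds", make_folds(
    length(known_rows), config$s_folds, seed = config$seed + 1L,
    grouping = if (config$grouping == "sample") "sample" else "row",
    groups = if (config$grouping == "sample") fm$sample[known_rows] else NULL))

  x_known <- fm$x[known_rows, , drop = FALSE]
  a_known <- fm$a[known_rows]
  per_channel <- list()
  optima <- data.frame(channel = character(0), mask = numeric(0),
                       delta = numeric(0), lambda_star = numeric(0),
                       sigma_star = numeric(0), stringsAsFactors = FALSE)
  for (ch in fm$channels) {
    cols <- grep(paste0("^", ch, ":"), colnames(fm$x))
    res <- stage(paste0("search:", ch), search_combinations(
      x_known[, cols, drop = FALSE], a_known, folds, grid = config$grid))
    attr(res, "columns") <- cols
    per_channel[[ch]] <- res
    optima <- rbind(optima, data.frame(
      channel = ch, mask = res$mask[1], delta = res$delta[1],
      lambda_star = res$lambda_star[1], sigma_star = res$sigma_star[1],
      stringsAsFactors = FALSE))
  }
  best_i <- which.min(optima$delta)
  best_ch <- optima$channel[best_i]
  best_cols <- attr(per_channel[[best_ch]], "columns")[
    decode_mask(optima$mask[best_i], 4)]
  best <- list(channel = best_ch, mask = optima$mask[best_i],
               columns = colnames(fm$x)[best_cols],
               lambda = optima$lambda_star[best_i],
               sigma = optima$sigma_star[best_i],
               delta = optima$delta[best_i])

  model <- stage("fit", krr(x_known[, best_cols, drop = FALSE], a_known,
                            lambda = best$lambda, sigma = best$sigma))
  parity_known <- data.frame(sample = fm$sample[known_rows],
                             t_a = fm$t_a[known_rows],
                             actual = a_known,
                             predicted = fitted(model),
                             known = TRUE, stringsAsFactors = FALSE)
  unknown_rows <- which(!fm$known)
  parity_unknown <- if (length(unknown_rows) > 0) {
    stage("evaluate_unknowns",
          evaluate_unknowns(model, fm, rows = unknown_rows, cols = best_cols))
  } else {
    parity_known[0, ]
  }
  parity <- rbind(parity_known, parity_unknown)
  unknown_mse <- if (nrow(parity_unknown) > 0)
    mean((parity_unknown$actual - parity_unknown$predicted)^2) else NA_real_

  usage <- lapply(per_channel, function(res)
    usage_rates(res, top_k = min(config$top_k, nrow(res))))
  correlations <- stage("correlations", correlation_summary(fm))
  pca <- stage("pca", pca_scores(fm, n_components = 2))

  structure(list(features = fm, folds = folds, per_channel = per_channel,
                 channel_optima = optima, best = best, model = model,
                 parity = parity, unknown_mse = unknown_mse, usage = usage,
                 correlations = correlations, pca = pca, config = config),
            class = "alcosense_report")
}

#' @export
print.alcosense_report <- function(x, ...) {
  cat("Smell-analysis report (seed ", x$config$seed, ")\n", sep = "")
  cat("  per-channel optimal CV errors (squared vol %):\n")
  for (i in seq_len(nrow(x$channel_optima)))
    cat(sprintf("    %-16s mask %2d (%s)  Delta = %.4f\n",
                x$channel_optima$channel[i], x$channel_optima$mask[i],
                mask_bits(x$channel_optima$mask[i], 4),
                x$channel_optima$delta[i]))
  cat("  best: channel ", x$best$channel, ", mask ", x$best$mask,
      ", Delta = ", format(x$best$delta, digits = 5),
      " (lambda = ", format(x$best$lambda), ", sigma = ",
      format(x$best$sigma), ")\n", sep = "")
  if (!is.na(x$unknown_mse))
    cat("  held-out sample MSE:", format(x$unknown_mse, digits = 4),
        "(vol %)^2 over", sum(!x$parity$known), "records\n")
  invisible(x)
}

#' @export
plot.alcosense_report <- function(x, ...) {
  known <- x$parity[x$parity$known, ]
  unk <- x$parity[!x$parity$known, ]
  rng <- range(x$parity$actual, x$parity$predicted)
  graphics::plot(known$actual, known$predicted, col = "blue", xlim = rng,
                 ylim = rng, xlab = "actual alcohol content (vol %)",
                 ylab = "predicted alcohol content (vol %)", ...)
  if (nrow(unk) > 0) graphics::points(unk$actual, unk$predicted, col = "red",
                                      pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write a report bundle as delimited tables
#'
#' Emits the parity table, per-channel search tables, usage rates,
#' correlations and a key-value summary under `dir`.
#'
#' @param report An `alcosense_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "alcosense_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$parity, "parity.tsv")
  w(report$correlations, "correlations.tsv")
  w(report$channel_optima, "channel_optima.tsv")
  for (ch in names(report$per_channel)) {
    w(as.data.frame(report$per_channel[[ch]]),
      paste0("search_", gsub("[^A-Za-z0-9_]", "_", ch), ".tsv"))
    w(report$usage[[ch]],
      paste0("usage_", gsub("[^A-Za-z0-9_]", "_", ch), ".tsv"))
  }
  summary_lines <- c(
    paste0("seed\t", report$config$seed),
    paste0("s_folds\t", report$config$s_folds),
    paste0("grouping\t", report$config$grouping),
    paste0("grid_points\t", nrow(report$config$grid)),
    paste0("best_channel\t", report$best$channel),
    paste0("best_mask\t", report$best$mask),
    paste0("best_columns\t", paste(report$best$columns, collapse = ",")),
    paste0("lambda_star\t", sprintf("%.17g", report$best$lambda)),
    paste0("sigma_star\t", sprintf("%.17g", report$best$sigma)),
    paste0("delta_star\t", sprintf("%.17g", report$best$delta)),
    paste0("unknown_mse\t", sprintf("%.17g", report$unknown_mse))
  )
  writeLines(summary_lines, file.path(dir, "summary.tsv"))
  invisible(dir)
}
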