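# Shared fixtures, generated in code.

# Default simulated dataset, cached so several test files can reuse it.
.ds_cache <- new.env(parent = emptyenv())
default_dataset <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.ds_cache[[key]]))
    .ds_cache[[key]] <- simulate_dataset(generator_config(seed = seed))
  .ds_cache[[key]]
}

# A single-component channel with clean (noise/drift/instability free) output.
clean_channel <- function(s = 2, tau_ads = 3, tau_des = 6, name = "clean") {
  channel_model(name,
                sensitivity = c(comp = s),
                tau_ads = c(comp = tau_ads),
                tau_des = c(comp = tau_des),
                noise_sd = 0, drift_rate = 0, instability_factor = 1)
}

# Build a feature_matrix object directly from raw pieces.
make_fm <- function(x, a, known = rep(TRUE, nrow(x)),
                    sample = paste0("s", seq_len(nrow(x))),
                    t_a = rep(60, nrow(x))) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("ch:p", seq_len(ncol(x)))
  structure(list(x = x, a = a, sample = sample, t_a = t_a, known = known,
                 channels = unique(sub(":p[0-9]+$", "", colnames(x))),
                 normalization_sds = NULL),
            class = "feature_matrix")
}

# A hand-made response_signal carrying arbitrary values.
make_signal <- function(values, schedule, channel = "ch", sample = "s") {
  structure(list(channel_name = channel, sample_name = sample,
                 times = schedule$times[seq_along(values)], values = values,
                 schedule = schedule),
            class = "response_signal")
}

fold_assignment <- function(assignment, s = max(assignment),
                            grouping = "row") {
  structure(list(s = s, assignment = assignment, seed = NA_integer_,
                 grouping = grouping),
            class = "fold_assignment")
}
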