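#' Simulate one channel's response trace to one sample
#'
#' Integrates the channel's per-component first-order sorption kinetics over
#' the acquisition schedule and sums the components. During an injection
#' period each component signal relaxes towards `sensitivity * concentration`
#' with time constant `tau_ads`; during baseline and purge it decays with
#' `tau_des`. Because each regime is a linear constant-coefficient ODE, the
#' trace is propagated exactly from sample to sample with the analytic
#' exponential update, so the returned values equal the continuous solution
#' at the sampling instants.
#'
#' The first two cycles are treated as a burn-in: they are scaled by the
#' channel's `instability_factor`, and at the start of the third cycle each
#' component state is set to the fixed point of its per-cycle map, so the
#' remaining cycles are exactly periodic — the reproducible portion of the
#' trace from which features are extracted.
#'
#' @param concentrations Named nonnegative vector of component
#'   concentrations (one entry per channel component), or a single row of
#'   [sample_components()].
#' @param channel A [channel_model()].
#' @param schedule An [acquisition_schedule()].
#' @param seed Integer seed for the additive noise; `NULL` uses the current
#'   RNG stream.
#' @param sample_name Sample label stored in the result.
#' @return An object of class `response_signal`: list with `channel_name`,
#'   `sample_name`, `times` (s), `values` (mV) and `schedule`.
#' @examples
#' ch <- default_channels()[[1]]
#' conc <- sample_components(default_sample_table())["vodka", ]
#' sig <- simulate_response(conc, ch, acquisition_schedule(), seed = 1)
#' range(sig$values)
#' @export
simulate_response <- function(concentrations, channel, schedule,
                              seed = NULL, sample_name = "") {
  stopifnot(inherits(channel, "channel_model"),
            inherits(schedule, "acquisition_schedule"))
  comp <- names(channel$sensitivity)
  concentrations <- unlist(concentrations)
  if (!all(comp %in% names(concentrations)))
    stop("concentrations missing components: ",
         paste(setdiff(comp, names(concentrations)), collapse = ", "))
  c_j <- concentrations[comp]
  if (any(c_j < 0)) stop("negative concentration")
  if (any(channel$tau_ads <= 0) || any(channel$tau_des <= 0))
    stop("nonpositive time constant")

  times <- schedule$times
  dt <- 1 / schedule$sampling_rate
  n <- length(times)
  target <- channel$sensitivity * c_j
  k <- length(comp)

  # regime per step: injection if the step's left endpoint falls inside an
  # injection window (boundaries are aligned with the sampling grid)
  phase <- (times - schedule$baseline_duration) %% schedule$period
  injecting <- times >= schedule$baseline_duration - 1e-9 &
    times < schedule$baseline_duration +
      schedule$n_cycles * schedule$period - 1e-9 &
    phase < schedule$inject_duration - 1e-9

  decay_ads <- exp(-dt / channel$tau_ads)
  decay_des <- exp(-dt / channel$tau_des)

  # periodic fixed point of the per-cycle affine map for each component
  alpha <- exp(-schedule$inject_duration / channel$tau_ads)
  beta <- exp(-schedule$purge_duration / channel$tau_des)
  s_star <- target * (1 - alpha) * beta / (1 - alpha * beta)

  steady_time <- schedule$baseline_duration + 2 * schedule$period
  steady_idx <- if (schedule$n_cycles >= 3)
    which.min(abs(times - steady_time)) else NA_integer_

  s <- numeric(k)
  clean <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1) {
      if (injecting[i - 1]) {
        s <- target + (s - target) * decay_ads
      } else {
        s <- s * decay_des
      }
    }
    if (!is.na(steady_idx) && i == steady_idx) s <- s_star
    clean[i] <- sum(s)
  }

  if (!is.na(steady_idx) && channel$instability_factor != 1)
    clean[seq_len(steady_idx - 1)] <-
      clean[seq_len(steady_idx - 1)] * channel$instability_factor

  noise <- if (channel$noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(n, 0, channel$noise_sd)
    else with_seed(seed, stats::rnorm(n, 0, channel$noise_sd))
  } else rep(0, n)

  values <- clean + channel$drift_rate * times + noise
  structure(list(channel_name = channel$name, sample_name = sample_name,
                 times = times, values = values, schedule = schedule),
            class = "response_signal")
}

#' @export
print.response_signal <- function(x, ...) {
  cat("Response signal:", shQuote(x$sample_name), "on channel",
      shQuote(x$channel_name), "-", length(x$times), "samples over",
      x$schedule$total_duration, "s\n")
  invisible(x)
}

#' @export
plot.response_signal <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "signal (mV)",
                 main = paste(x$sample_name, "/", x$channel_name), ...)
  graphics::abline(v = x$schedule$injection_start_times, lty = 3, col = "grey")
  invisible(x)
}

#' Generator configuration
#'
#' Bundles the acquisition schedule, channel models, sample table and seed
#' that fully determine a simulated dataset.
#'
#' @param schedule An [acquisition_schedule()].
#' @param channels List of [channel_model()] objects.
#' @param samples Sample table, see [default_sample_table()].
#' @param seed Integer master seed; the flavour draw and every trace's noise
#'   are derived from it, so identical configurations give identical data.
#' @param components Optional precomputed component matrix (rows = samples);
#'   by default derived with [sample_components()] from `seed`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(schedule = acquisition_schedule(),
                             channels = default_channels(),
                             samples = default_sample_table(),
                             seed = 1, components = NULL) {
  stopifnot(inherits(schedule, "acquisition_schedule"), is.list(channels),
            is.data.frame(samples))
  if (anyDuplicated(samples$name)) stop("duplicate sample names")
  structure(list(schedule = schedule, channels = channels, samples = samples,
                 seed = as.integer(seed), components = components),
            class = "generator_config")
}

#' Simulate a full sensor-array dataset
#'
#' Generates one response trace per (sample, channel) pair under a fixed
#' configuration and seed. The result is deterministic: the same
#' configuration and seed always yield identical traces.
#'
#' @param config A [generator_config()].
#' @return An object of class `sensor_dataset`: list with `signals` (list of
#'   `response_signal`, sample-major), `metadata` (data.frame with `sample`,
#'   `alcohol_content`, `known`), `components` and `config`.
#' @examples
#' ds <- simulate_dataset(generator_config(seed = 7))
#' length(ds$signals)  # 35 samples x 4 channels = 140
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  samples <- config$samples
  comp <- config$components %||%
    sample_components(samples, seed = config$seed)
  signals <- vector("list", nrow(samples) * length(config$channels))
  idx <- 1L
  for (i in seq_len(nrow(samples))) {
    for (ch in config$channels) {
      signals[[idx]] <- simulate_response(
        comp[i, ], ch, config$schedule,
        seed = (config$seed + 7919L * idx) %% .Machine$integer.max,
        sample_name = samples$name[i])
      idx <- idx + 1L
    }
  }
  metadata <- data.frame(sample = samples$name,
                         alcohol_content = samples$alcohol_content,
                         known = samples$known %||% rep(TRUE, nrow(samples)),
                         stringsAsFactors = FALSE)
  structure(list(signals = signals, metadata = metadata, components = comp,
                 config = config),
            class = "sensor_dataset")
}

#' @export
print.sensor_dataset <- function(x, ...) {
  cat("Sensor dataset:", nrow(x$metadata), "samples x",
      length(x$config$channels), "channels =", length(x$signals),
      "traces (seed", x$config$seed, ")\n")
  invisible(x)
}
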