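#' Acquisition schedule of a sample-introduction / purge experiment
#'
#' Describes the valve timing of one headspace measurement: after an initial
#' baseline period of clean air, sample vapour and purge air are alternated in
#' fixed-length periods, and the whole injection/purge cycle is repeated
#' several times while the sensor output is sampled at a constant rate.
#' The defaults encode the standard protocol used throughout the package:
#' vapour and purge switched every 10 s, five cycles, 20 Hz sampling, with a
#' 20 s baseline so the cycles start at 20, 40, 60, 80 and 100 s.
#'
#' @param baseline_duration Seconds of clean-air baseline before the first
#'   injection.
#' @param inject_duration Seconds of sample-vapour introduction per cycle.
#' @param purge_duration Seconds of purge per cycle.
#' @param n_cycles Number of injection/purge cycles.
#' @param sampling_rate Sampling rate in Hz.
#'
#' @return An object of class `acquisition_schedule`: a list with the input
#'   fields plus `period` (cycle length, s), `injection_start_times` (s),
#'   `total_duration` (s) and `times` (all sampling instants, s).
#' @examples
#' sch <- acquisition_schedule()
#' sch$injection_start_times  # 20 40 60 80 100
#' @export
acquisition_schedule <- function(baseline_duration = 20,
                                 inject_duration = 10,
                                 purge_duration = 10,
                                 n_cycles = 5,
                                 sampling_rate = 20) {
  stopifnot(baseline_duration >= 0, inject_duration > 0, purge_duration > 0,
            n_cycles >= 1, sampling_rate > 0)
  period <- inject_duration + purge_duration
  total <- baseline_duration + n_cycles * period
  n <- round(total * sampling_rate)
  obj <- list(
    baseline_duration = baseline_duration,
    inject_duration = inject_duration,
    purge_duration = purge_duration,
    n_cycles = n_cycles,
    sampling_rate = sampling_rate,
    period = period,
    injection_start_times = baseline_duration + (seq_len(n_cycles) - 1) * period,
    total_duration = total,
    times = seq(0, by = 1 / sampling_rate, length.out = n)
  )
  class(obj) <- "acquisition_schedule"
  obj
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat("Acquisition schedule:", x$n_cycles, "cycles of",
      x$inject_duration, "s injection /", x$purge_duration, "s purge,",
      x$baseline_duration, "s baseline,", x$sampling_rate, "Hz\n")
  cat("  injections start at:", paste(x$injection_start_times, collapse = ", "), "s\n")
  cat("  trace length:", x$total_duration, "s (", length(x$times), "samples )\n")
  invisible(x)
}
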