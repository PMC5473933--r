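#' Read and write response signals as plain-text tables
#'
#' A trace is stored as a tab-delimited table with columns `time_s` and
#' `signal_mV`, preceded by `#`-prefixed header lines carrying the channel
#' name, sample name and acquisition schedule. Values are written with 12
#' significant digits, so a write/read round trip reproduces the trace to
#' well beyond 9 significant digits.
#'
#' @param signal A `response_signal` (see [simulate_response()]).
#' @param path File path.
#' @return `read_signal()` returns a `response_signal`; `write_signal()`
#'   returns `path` invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "response_signal"))
  sch <- signal$schedule
  hdr <- c(
    paste0("# channel: ", signal$channel_name),
    paste0("# sample: ", signal$sample_name),
    sprintf("# schedule: baseline=%g inject=%g purge=%g n_cycles=%d rate=%g",
            sch$baseline_duration, sch$inject_duration, sch$purge_duration,
            sch$n_cycles, sch$sampling_rate),
    "time_s\tsignal_mV"
  )
  body <- sprintf("%.12g\t%.12g", signal$times, signal$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty signal file: ", path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) stop("signal file has no data rows: ", path)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return("")
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  cols <- strsplit(body[1], "\t")[[1]]
  if (!all(c("time_s", "signal_mV") %in% cols))
    stop("signal file must have columns time_s and signal_mV")
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = cols, colClasses = "numeric")
  times <- dat$time_s
  values <- dat$signal_mV
  dts <- diff(times)
  if (length(dts) > 0 && (max(dts) - min(dts)) > 1e-9) {
    warning("non-uniform sampling in ", path, "; refusing to resample")
    stop("non-uniform sampling")
  }
  sch_line <- get_hdr("schedule")
  sch <- if (nzchar(sch_line)) {
    kv <- strsplit(strsplit(sch_line, " ")[[1]], "=")
    vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
    acquisition_schedule(vals[["baseline"]], vals[["inject"]],
                         vals[["purge"]], vals[["n_cycles"]], vals[["rate"]])
  } else {
    rate <- 1 / stats::median(dts)
    acquisition_schedule(baseline_duration = 0, n_cycles = 1,
                         inject_duration = max(times) / 2,
                         purge_duration = max(times) / 2,
                         sampling_rate = rate)
  }
  structure(list(channel_name = get_hdr("channel"),
                 sample_name = get_hdr("sample"),
                 times = times, values = values, schedule = sch),
            class = "response_signal")
}
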