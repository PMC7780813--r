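#' Construct an optical-mapping trace
#'
#' A trace is a uniformly sampled single-channel time series: fluorescence
#' counts or normalized units for either the voltage-sensitive or the
#' calcium-sensitive dye channel. Time is in milliseconds throughout the
#' package; timestamps mark the start of each frame and the first frame is
#' at t = 0 unless stated otherwise.
#'
#' @param time numeric vector of timestamps in ms, strictly increasing and
#'   uniformly spaced, length >= 2.
#' @param values numeric vector of the same length as `time`.
#' @param channel `"voltage"` or `"calcium"`.
#' @param frame_rate sampling rate in frames/s; derived from `time` when
#'   `NULL`.
#' @param meta named list of free-form metadata (well id, dose label, ...).
#' @return An object of class `om_trace`: a list with elements `time`,
#'   `values`, `channel`, `frame_rate`, `meta`.
#' @examples
#' tr <- om_trace(seq(0, 990, by = 10), sin(seq(0, 990, by = 10) / 50),
#'                channel = "voltage")
#' tr
#' @export
om_trace <- function(time, values, channel = c("voltage", "calcium"),
                     frame_rate = NULL, meta = list()) {
  channel <- match.arg(channel)
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) < 2L) stop("trace must have at least 2 samples")
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (anyNA(time) || anyNA(values)) stop("trace contains missing samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time base must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt)) stop("time base must be uniform")
  if (is.null(frame_rate)) frame_rate <- 1000 / mean(dt)
  structure(list(time = time, values = values, channel = channel,
                 frame_rate = frame_rate, meta = meta),
            class = "om_trace")
}

#' @export
print.om_trace <- function(x, ...) {
  cat(sprintf("<om_trace> %s channel: %d samples @ %.4g frames/s, %.4g-%.4g ms\n",
              x$channel, length(x$time), x$frame_rate,
              x$time[1], x$time[length(x$time)]))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = "/"),
                                ""), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.om_trace <- function(x, ...) {
  graphics::plot(x$time, x$values, type = "l",
                 xlab = "time (ms)",
                 ylab = if (x$channel == "voltage") "V signal" else "Ca signal",
                 ...)
  invisible(x)
}

# sampling interval in ms
trace_dt <- function(trace) 1000 / trace$frame_rate

#' Write a trace to delimited text
#'
#' Two-column comma-separated text with header `time_ms,value`, the
#' interchange format used for all trace files.
#'
#' @param trace an [om_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, value = trace$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from delimited text
#'
#' @param path file with header `time_ms,value` (comma-separated).
#' @param channel channel label to attach.
#' @param meta metadata list to attach.
#' @return An [om_trace].
#' @export
read_trace <- function(path, channel = c("voltage", "calcium"), meta = list()) {
  channel <- match.arg(channel)
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(df)))
    stop("trace file must have columns time_ms,value: ", path)
  om_trace(df$time_ms, df$value, channel = channel, meta = meta)
}

#' Describe a pacing protocol
#'
#' Fixed-rate pacing is a constant cycle length; a ramp steps the rate from
#' `bpm_start` to `bpm_end` in increments of `bpm_step` with
#' `beats_per_step` stimuli at each rate; spontaneous recordings carry no
#' stimulus times and beats are detected from the signal.
#'
#' @param mode `"fixed"`, `"ramp"`, or `"spontaneous"`.
#' @param rate_bpm fixed-rate pacing rate in beats per minute.
#' @param bpm_start,bpm_end,bpm_step ramp design in bpm.
#' @param beats_per_step stimuli delivered at each ramp rate.
#' @param discard_per_step leading beats of each ramp step treated as
#'   non-steady-state and excluded from restitution points.
#' @param n_beats number of stimuli for fixed mode (`NULL` = fill duration).
#' @param t0 time of the first stimulus in ms.
#' @param stimulus_times explicit stimulus times in ms, overriding the
#'   schedule fields.
#' @return An object of class `pacing_protocol`.
#' @examples
#' pacing_protocol("fixed", rate_bpm = 60, n_beats = 10)
#' pacing_protocol("ramp", bpm_start = 60, bpm_end = 200)
#' @export
pacing_protocol <- function(mode = c("fixed", "ramp", "spontaneous"),
                            rate_bpm = 60, bpm_start = 60, bpm_end = 200,
                            bpm_step = 10, beats_per_step = 8,
                            discard_per_step = 2, n_beats = NULL, t0 = 50,
                            stimulus_times = NULL) {
  mode <- match.arg(mode)
  p <- structure(list(mode = mode, rate_bpm = rate_bpm,
                      bpm_start = bpm_start, bpm_end = bpm_end,
                      bpm_step = bpm_step, beats_per_step = beats_per_step,
                      discard_per_step = discard_per_step,
                      n_beats = n_beats, t0 = t0,
                      stimulus_times = stimulus_times),
                 class = "pacing_protocol")
  if (!is.null(stimulus_times) && any(diff(stimulus_times) <= 0))
    stop("stimulus times must be strictly increasing")
  p
}

#' @export
print.pacing_protocol <- function(x, ...) {
  if (x$mode == "fixed")
    cat(sprintf("<pacing_protocol> fixed %g bpm\n", x$rate_bpm))
  else if (x$mode == "ramp")
    cat(sprintf("<pacing_protocol> ramp %g-%g bpm in %g bpm steps, %d beats/step\n",
                x$bpm_start, x$bpm_end, x$bpm_step, x$beats_per_step))
  else cat("<pacing_protocol> spontaneous\n")
  invisible(x)
}

#' Stimulus times of a protocol
#'
#' Expands a protocol into explicit stimulus times. For ramp mode the rate
#' increases from `bpm_start` to `bpm_end` in `bpm_step` increments with
#' `beats_per_step` stimuli per step; the per-step index of each stimulus
#' is returned as an attribute so downstream code can discard non-steady
#' beats.
#'
#' @param protocol a [pacing_protocol].
#' @param duration recording duration in ms; stimuli beyond it are dropped.
#' @return numeric vector of stimulus times (ms) with attributes
#'   `cycle_length` (ms, per stimulus) and, for ramps, `step` and
#'   `beat_in_step`.
#' @export
stimulus_times <- function(protocol, duration = Inf) {
  if (!is.null(protocol$stimulus_times)) {
    st <- protocol$stimulus_times
    cl <- c(NA_real_, diff(st))
    attr(st, "cycle_length") <- cl
    return(st[st <= duration])
  }
  if (protocol$mode == "spontaneous") return(numeric(0))
  if (protocol$mode == "fixed") {
    cl <- 60000 / protocol$rate_bpm
    n <- protocol$n_beats
    if (is.null(n)) {
      if (!is.finite(duration)) stop("fixed protocol needs n_beats or a finite duration")
      n <- floor((duration - protocol$t0) / cl) + 1L
    }
    st <- protocol$t0 + cl * (seq_len(n) - 1L)
    keep <- st <= duration
    st <- st[keep]
    attr(st, "cycle_length") <- rep(cl, length(st))
    return(st)
  }
  # ramp: bpm_start..bpm_end inclusive
  rates <- seq(protocol$bpm_start, protocol$bpm_end, by = protocol$bpm_step)
  st <- numeric(0); cls <- numeric(0); steps <- integer(0); bis <- integer(0)
  t <- protocol$t0
  for (s in seq_along(rates)) {
    cl <- 60000 / rates[s]
    for (b in seq_len(protocol$beats_per_step)) {
      st <- c(st, t); cls <- c(cls, cl)
      steps <- c(steps, s); bis <- c(bis, b)
      t <- t + cl
    }
  }
  keep <- st <= duration
  st <- st[keep]
  attr(st, "cycle_length") <- cls[keep]
  attr(st, "step") <- steps[keep]
  attr(st, "beat_in_step") <- bis[keep]
  st
}
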