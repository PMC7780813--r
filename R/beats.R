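#' Segment a conditioned trace into beats
#'
#' Under fixed-rate or ramp pacing each protocol stimulus opens a
#' stimulus-aligned analysis window reaching to the next stimulus; a short
#' pre-stimulus margin supplies the diastolic baseline. In spontaneous
#' mode activations are found from threshold crossings of the first
#' difference with a refractory lockout. Windows whose amplitude is below
#' `min_amplitude` times the trace's robust amplitude are marked as not
#' captured (e.g. a stimulus that failed to elicit a beat); beats cut off
#' by the end of the recording are flagged `truncated`. Both are excluded
#' from metrics.
#'
#' @param trace a conditioned [om_trace] (see [condition_trace()]).
#' @param protocol a [pacing_protocol].
#' @param min_amplitude capture threshold as a fraction of the robust
#'   (1st-99th percentile) trace amplitude.
#' @param deriv_frac spontaneous mode: detection threshold as a fraction
#'   of the maximal derivative.
#' @param refractory_ms spontaneous mode: lockout after each detection.
#' @param pre_ms baseline margin before each stimulus; default
#'   `min(100, 0.25 * cycle length)`.
#' @return A data.frame of class `om_beats`, one row per window:
#'   `beat, t_start, t_end, stim_time, cycle_length, activation_time,
#'   peak_time, baseline, amplitude, captured, truncated`. Empty (with a
#'   warning) when nothing is detected.
#' @export
detect_beats <- function(trace, protocol, min_amplitude = 0.2,
                         deriv_frac = 0.5, refractory_ms = 200,
                         pre_ms = NULL) {
  stopifnot(inherits(trace, "om_trace"), inherits(protocol, "pacing_protocol"))
  t <- trace$time; v <- trace$values
  t_end_rec <- t[length(t)]
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  glob_amp <- q[2] - q[1]

  if (protocol$mode == "spontaneous") {
    d <- diff(v) / diff(t)
    dmax <- max(d)
    if (glob_amp <= 0 || dmax <= 0) {
      warning("no beats found")
      return(empty_beats())
    }
    thr <- deriv_frac * dmax
    up <- which(d[-1] >= thr & d[-length(d)] < thr) + 1L
    acts <- numeric(0)
    last <- -Inf
    for (i in up) {
      tm <- (t[i] + t[i + 1]) / 2
      if (tm - last >= refractory_ms) { acts <- c(acts, tm); last <- tm }
    }
    if (!length(acts)) {
      warning("no beats found")
      return(empty_beats())
    }
    # window bounds midway between activations
    mids <- if (length(acts) > 1) (acts[-1] + acts[-length(acts)]) / 2 else numeric(0)
    starts <- c(max(t[1], acts[1] - 0.5 * stats::median(diff(acts), na.rm = TRUE)),
                mids)
    if (length(acts) == 1) starts <- max(t[1], acts[1] - 250)
    ends <- c(mids, t_end_rec)
    stims <- rep(NA_real_, length(acts))
    cls <- c(NA_real_, diff(acts))
  } else {
    st <- stimulus_times(protocol, t_end_rec)
    if (!length(st)) {
      warning("no stimuli inside the recording")
      return(empty_beats())
    }
    cls <- attr(st, "cycle_length")
    if (is.null(cls)) cls <- c(NA_real_, diff(st))
    starts <- as.numeric(st)
    ends <- c(starts[-1], t_end_rec)
    stims <- starts
  }

  n <- length(starts)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    pre <- pre_ms %||% min(100, 0.25 * (ends[k] - starts[k]))
    # margin inclusive of the stimulus sample: keeps the median of a
    # monotone diastolic tail centred on the margin midpoint
    base_sel <- t >= (starts[k] - pre) & t <= starts[k]
    win <- t >= starts[k] & t < ends[k]
    if (sum(win) < 3) next
    baseline <- if (any(base_sel)) stats::median(v[base_sel]) else v[win][1]
    pk <- peak_time_refined(t[win], v[win])
    amplitude <- pk$value - baseline
    captured <- glob_amp > 0 && amplitude >= min_amplitude * glob_amp
    act <- if (captured) max_deriv_time(t[win], v[win])$time else NA_real_
    truncated <- (k == n) &&
      v[length(v)] > baseline + 0.2 * max(amplitude, 0) &&
      abs(ends[k] - t_end_rec) < trace_dt(trace)
    rows[[k]] <- data.frame(
      beat = k, t_start = starts[k] - pre, t_end = ends[k],
      stim_time = stims[k], cycle_length = cls[k],
      activation_time = act, peak_time = pk$time,
      baseline = baseline, amplitude = amplitude,
      captured = captured, truncated = truncated)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("no beats found")
    return(empty_beats())
  }
  out <- do.call(rbind, rows)
  class(out) <- c("om_beats", "data.frame")
  out
}

empty_beats <- function() {
  out <- data.frame(beat = integer(0), t_start = numeric(0),
                    t_end = numeric(0), stim_time = numeric(0),
                    cycle_length = numeric(0), activation_time = numeric(0),
                    peak_time = numeric(0), baseline = numeric(0),
                    amplitude = numeric(0), captured = logical(0),
                    truncated = logical(0))
  class(out) <- c("om_beats", "data.frame")
  out
}

beat_window <- function(trace, beat) {
  sel <- trace$time >= beat$t_start & trace$time < beat$t_end
  list(t = trace$time[sel], v = trace$values[sel])
}

usable_beat <- function(beat) {
  isTRUE(beat$captured) && !isTRUE(beat$truncated) &&
    !is.na(beat$amplitude) && beat$amplitude > 0
}

#' Action-potential duration at a repolarization level
#'
#' Time from the activation (maximal upstroke derivative) to the first
#' subsequent downward crossing of
#' `baseline + (1 - level_pct/100) * amplitude`, with linear interpolation
#' between samples. `NA` (flagged, never an error) when repolarization does
#' not reach the level inside the beat window.
#'
#' @param trace a conditioned voltage [om_trace].
#' @param beat one row of the [detect_beats()] table.
#' @param level_pct repolarization level in percent (20, 50, 80, 90, ...).
#' @return Duration in ms, or `NA_real_`.
#' @export
apd <- function(trace, beat, level_pct = 80) {
  if (!usable_beat(beat)) return(NA_real_)
  w <- beat_window(trace, beat)
  duration_at_level(w$t, w$v, beat$activation_time, level_pct,
                    beat$baseline, beat$amplitude,
                    peak_time = beat$peak_time)
}

# 10% upstroke crossing: the activation reference for CaT metrics.
cat_onset <- function(trace, beat) {
  w <- beat_window(trace, beat)
  cross_up(w$t, w$v, beat$baseline + 0.1 * beat$amplitude,
           before = beat$peak_time)
}

#' Calcium-transient duration at a recovery level
#'
#' Same construction as [apd()] but referenced to the transient onset (10%
#' upstroke crossing), the field convention for CaT timing.
#'
#' @inheritParams apd
#' @return Duration in ms, or `NA_real_`.
#' @export
catd <- function(trace, beat, level_pct = 80) {
  if (!usable_beat(beat)) return(NA_real_)
  on <- cat_onset(trace, beat)
  if (is.na(on)) return(NA_real_)
  w <- beat_window(trace, beat)
  duration_at_level(w$t, w$v, on, level_pct, beat$baseline, beat$amplitude,
                    peak_time = beat$peak_time)
}

#' Time to peak of a calcium transient
#'
#' Refined peak time minus the 10% upstroke crossing. For multi-peaked
#' beats the first global maximum is used (an ambiguity flag is attached
#' as an attribute).
#'
#' @inheritParams apd
#' @return TTP in ms, or `NA_real_`.
#' @export
time_to_peak <- function(trace, beat) {
  if (!usable_beat(beat)) return(NA_real_)
  on <- cat_onset(trace, beat)
  if (is.na(on)) return(NA_real_)
  w <- beat_window(trace, beat)
  pk <- peak_time_refined(w$t, w$v)
  near_max <- w$v >= beat$baseline + 0.98 * beat$amplitude
  runs <- rle(near_max)
  multi <- sum(runs$values) > 1
  out <- pk$time - on
  attr(out, "ambiguous") <- multi
  out
}

#' Mono-exponential decay time constant of a calcium transient
#'
#' Nonlinear least-squares fit of `A * exp(-t / tau) + C` over the decay
#' segment from 90% down to 10% of the beat amplitude, initialized from a
#' log-linear regression and bounded to `tau` in (1 ms, 10 x segment
#' length). The first `peak_gap` ms after the peak are excluded from the
#' segment: the release-to-decay transition there is not yet
#' mono-exponential, and on noisy traces the inflated peak estimate would
#' otherwise pull the 90% crossing into it and bias tau upward.
#' Non-convergence is reported (`converged = FALSE`, `tau = NA`), never
#' silently replaced by the initializer.
#'
#' @inheritParams apd
#' @param min_points minimum number of samples in the decay segment.
#' @param peak_gap ms after the peak excluded from the fit.
#' @return list with `tau` (ms), `rmse`, `converged`.
#' @export
decay_tau <- function(trace, beat, min_points = 10, peak_gap = 50) {
  bad <- list(tau = NA_real_, rmse = NA_real_, converged = FALSE)
  if (!usable_beat(beat)) return(bad)
  w <- beat_window(trace, beat)
  hi <- beat$baseline + 0.9 * beat$amplitude
  lo <- beat$baseline + 0.1 * beat$amplitude
  t90 <- cross_down(w$t, w$v, hi, from = beat$peak_time)
  if (is.na(t90)) return(bad)
  t90 <- max(t90, beat$peak_time + peak_gap)
  t10 <- cross_down(w$t, w$v, lo, from = t90)
  if (is.na(t10)) t10 <- max(w$t)
  sel <- w$t >= t90 & w$t <= t10
  if (sum(sel) < min_points) return(bad)
  ts <- w$t[sel] - t90; ys <- w$v[sel]
  seg_len <- max(ts)
  # log-linear initializer (assumes C near baseline)
  pos <- ys - beat$baseline > 1e-6 * beat$amplitude
  if (sum(pos) < 3) return(bad)
  init_fit <- stats::lm(log(ys[pos] - beat$baseline) ~ ts[pos])
  tau0 <- -1 / stats::coef(init_fit)[2]
  A0 <- exp(stats::coef(init_fit)[1])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- seg_len / 2
  tau0 <- min(max(tau0, 1.5), 10 * seg_len * 0.99)
  try_fit <- function(A_s, tau_s) tryCatch(
    minpack.lm::nlsLM(ys ~ A * exp(-ts / tau) + C,
                      start = list(A = A_s, tau = tau_s, C = beat$baseline),
                      lower = c(A = 0, tau = 1, C = -Inf),
                      upper = c(A = Inf, tau = 10 * seg_len, C = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  fit <- try_fit(ys[1] - beat$baseline, tau0)
  if (is.null(fit)) {
    # the optimizer can fail on (near-)zero-residual data; if the
    # log-linear solution already reproduces the segment to numerical
    # precision it *is* the least-squares fit
    pred <- A0 * exp(-ts / tau0) + beat$baseline
    rmse0 <- sqrt(mean((ys - pred)^2))
    if (is.finite(rmse0) && rmse0 < 1e-5 * beat$amplitude)
      return(list(tau = unname(tau0), rmse = rmse0, converged = TRUE))
    fit <- try_fit(1.1 * (ys[1] - beat$baseline), 1.3 * tau0)
  }
  if (is.null(fit)) return(bad)
  tau_hat <- stats::coef(fit)[["tau"]]
  list(tau = tau_hat,
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       converged = TRUE)
}

#' Maximal upstroke derivative and resting level
#'
#' The maximum of the finite-difference derivative inside the beat window
#' (normalized units per ms), and the resting level as the median of the
#' diastolic samples in the pre-stimulus margin (`NA`, flagged, when no
#' diastolic epoch exists, e.g. fusion beats).
#'
#' @inheritParams apd
#' @return list with `max_upstroke` and `resting_level`.
#' @export
upstroke_and_rest <- function(trace, beat) {
  if (!usable_beat(beat))
    return(list(max_upstroke = NA_real_, resting_level = NA_real_))
  w <- beat_window(trace, beat)
  mu <- max_deriv_time(w$t, w$v)$slope
  ref <- if (is.na(beat$stim_time)) beat$activation_time else beat$stim_time
  sel <- trace$time >= beat$t_start & trace$time < ref
  rest <- if (any(sel, na.rm = TRUE)) stats::median(trace$values[sel]) else NA_real_
  list(max_upstroke = mu, resting_level = rest)
}

#' Average beating rate
#'
#' `60000 / mean inter-activation interval`, in beats per minute.
#'
#' @param beats an `om_beats` table (at least 2 captured beats).
#' @return bpm, or `NA_real_` with a warning when fewer than 2 beats.
#' @export
beating_rate <- function(beats) {
  acts <- beats$activation_time[beats$captured & !is.na(beats$activation_time)]
  if (length(acts) < 2) {
    warning("beating rate undefined with fewer than 2 beats")
    return(NA_real_)
  }
  60000 / mean(diff(acts))
}

#' Per-beat metrics table
#'
#' Runs beat detection and all per-beat measurements over a voltage trace
#' and (optionally) its paired calcium trace, producing one row per beat:
#' APD20/50/80/90, max upstroke and resting level from the voltage
#' channel; CaTD20/50/80, TTP and decay tau from the calcium channel;
#' plus the instantaneous pacing rate and validity flags. This is the
#' input for the restitution and dose-response stages.
#'
#' @param v_trace conditioned voltage [om_trace].
#' @param ca_trace optional conditioned calcium [om_trace] on the same
#'   protocol.
#' @param protocol a [pacing_protocol].
#' @param well,dose optional labels copied into every row.
#' @param ... passed to [detect_beats()].
#' @return data.frame of class `beat_metrics`.
#' @export
beat_metrics <- function(v_trace, ca_trace = NULL, protocol,
                         well = NA_character_, dose = NA_real_, ...) {
  vb <- detect_beats(v_trace, protocol, ...)
  cb <- if (!is.null(ca_trace)) detect_beats(ca_trace, protocol, ...) else NULL
  n <- nrow(vb)
  out <- vb[, c("beat", "stim_time", "cycle_length", "activation_time",
                "amplitude", "captured", "truncated")]
  out$rate_bpm <- ifelse(is.na(vb$cycle_length), NA, 60000 / vb$cycle_length)
  for (L in c(20, 50, 80, 90))
    out[[paste0("apd", L)]] <-
      vapply(seq_len(n), function(i) apd(v_trace, vb[i, ], L), 0)
  ur <- lapply(seq_len(n), function(i) upstroke_and_rest(v_trace, vb[i, ]))
  out$max_upstroke <- vapply(ur, `[[`, 0, "max_upstroke")
  out$resting_level <- vapply(ur, `[[`, 0, "resting_level")
  if (!is.null(cb) && nrow(cb)) {
    m <- match(out$beat, cb$beat)
    for (L in c(20, 50, 80))
      out[[paste0("catd", L)]] <- vapply(seq_len(n), function(i) {
        j <- m[i]
        if (is.na(j)) NA_real_ else catd(ca_trace, cb[j, ], L)
      }, 0)
    out$ttp <- vapply(seq_len(n), function(i) {
      j <- m[i]
      if (is.na(j)) NA_real_ else as.numeric(time_to_peak(ca_trace, cb[j, ]))
    }, 0)
    out$tau <- vapply(seq_len(n), function(i) {
      j <- m[i]
      if (is.na(j)) NA_real_ else decay_tau(ca_trace, cb[j, ])$tau
    }, 0)
  }
  out$well <- well
  out$dose <- dose
  class(out) <- c("beat_metrics", "data.frame")
  out
}
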