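#' Cell-type waveform parameters
#'
#' Parameters of the synthetic action-potential and Ca2+-transient
#' waveforms for one cell type. The AP is the product of a logistic
#' upstroke (time constant `ap_upstroke_tau`) and a two-phase
#' repolarization envelope: a fraction `ap_plateau_fraction` of the
#' amplitude is held through a plateau of `ap_plateau_dur` ms and then
#' decays exponentially with `ap_repol_tau`, while the remaining
#' (1 - fraction) decays from the peak immediately. An atrial-like cell
#' has a small plateau fraction (short, triangular AP); a ventricular-like
#' cell a large one (long plateau). The CaT rises smoothly over `cat_ttp`
#' (measured 10% upstroke to peak) and decays mono-exponentially with
#' `cat_decay_tau`, starting `cat_onset_delay` ms after the stimulus.
#'
#' @param label `"atrial"` or `"ventricular"`.
#' @param ap_upstroke_tau logistic upstroke time constant, ms.
#' @param ap_plateau_fraction fraction of amplitude held during the
#'   plateau, in `[0, 1]`.
#' @param ap_plateau_dur plateau duration, ms.
#' @param ap_repol_tau repolarization time constant, ms.
#' @param cat_ttp CaT time-to-peak (10% upstroke to peak), ms.
#' @param cat_decay_tau CaT mono-exponential decay constant, ms.
#' @param cat_onset_delay Ca onset after voltage activation, ms.
#' @param amplitude,resting_level signal scale and offset, arbitrary units.
#' @return An object of class `cell_type_params`.
#' @seealso [cell_preset()] for the calibrated atrial/ventricular presets.
#' @export
cell_type_params <- function(label = c("atrial", "ventricular"),
                             ap_upstroke_tau = 6, ap_plateau_fraction = 0.55,
                             ap_plateau_dur = 95, ap_repol_tau = 75,
                             cat_ttp = 116, cat_decay_tau = 350,
                             cat_onset_delay = 20,
                             amplitude = 1, resting_level = 0) {
  label <- match.arg(label)
  stopifnot(ap_upstroke_tau > 0, ap_repol_tau > 0, ap_plateau_dur >= 0,
            cat_ttp > 0, cat_decay_tau > 0, cat_onset_delay >= 0,
            amplitude >= 0)
  if (ap_plateau_fraction < 0 || ap_plateau_fraction > 1)
    stop("ap_plateau_fraction must be in [0, 1]")
  structure(list(label = label, ap_upstroke_tau = ap_upstroke_tau,
                 ap_plateau_fraction = ap_plateau_fraction,
                 ap_plateau_dur = ap_plateau_dur, ap_repol_tau = ap_repol_tau,
                 cat_ttp = cat_ttp, cat_decay_tau = cat_decay_tau,
                 cat_onset_delay = cat_onset_delay,
                 amplitude = amplitude, resting_level = resting_level),
            class = "cell_type_params")
}

#' @export
print.cell_type_params <- function(x, ...) {
  cat(sprintf(paste0("<cell_type_params> %s: upstroke tau %g ms, plateau %g%% x %g ms,",
                     " repol tau %g ms; CaT ttp %g ms, decay tau %g ms\n"),
              x$label, x$ap_upstroke_tau, 100 * x$ap_plateau_fraction,
              x$ap_plateau_dur, x$ap_repol_tau, x$cat_ttp, x$cat_decay_tau))
  invisible(x)
}

#' Calibrated atrial / ventricular presets
#'
#' Waveform presets tuned so that the dense-grid ground truth reproduces
#' the optical phenotype of paced cardiomyocyte monolayers: atrial-like
#' APD80 near 179 ms with a small plateau, ventricular-like APD80 near
#' 251 ms with a prolonged plateau; CaT time-to-peak 116 vs 246 ms and
#' decay tau 350 vs 400 ms. The ventricular decay constant is set so that
#' the transient recovers within a 1 Hz cycle, which a strictly
#' mono-exponential decay of several-hundred-ms tau requires; see the
#' methods vignette.
#'
#' @param label `"atrial"` or `"ventricular"`.
#' @return A [cell_type_params] object.
#' @examples
#' cell_preset("atrial")
#' @export
cell_preset <- function(label = c("atrial", "ventricular")) {
  label <- match.arg(label)
  if (label == "atrial")
    cell_type_params("atrial", ap_upstroke_tau = 6, ap_plateau_fraction = 0.55,
                     ap_plateau_dur = 95, ap_repol_tau = 75.61,
                     cat_ttp = 116, cat_decay_tau = 350)
  else
    cell_type_params("ventricular", ap_upstroke_tau = 6,
                     ap_plateau_fraction = 0.80, ap_plateau_dur = 140,
                     ap_repol_tau = 91.01,
                     cat_ttp = 246, cat_decay_tau = 400)
}

#' Restitution presets for the ramp generator
#'
#' Generator-side electrical restitution: the target APD80 of each beat is
#' `a - b * exp(-DI / c)` of the preceding diastolic interval. The presets
#' are tuned so that the ventricular-like curve is steeper than the
#' atrial-like one at the shortest diastolic intervals reached by a
#' 60-200 bpm ramp, mirroring the ordering seen in optical recordings.
#'
#' @param label `"atrial"` or `"ventricular"`.
#' @return list with elements `a`, `b`, `c` (ms).
#' @export
restitution_preset <- function(label = c("atrial", "ventricular")) {
  label <- match.arg(label)
  if (label == "atrial") list(a = 179, b = 880, c = 60)
  else list(a = 251, b = 405, c = 70)
}

# ---- waveform algebra (internal) -------------------------------------------

# AP shape at local time tau (>= 0 after the stimulus), unit amplitude.
# `scale` stretches the repolarization envelope (plateau + decay) in time,
# leaving the upstroke untouched; used for generator-side restitution.
ap_shape <- function(tau, params, scale = 1) {
  u <- params$ap_upstroke_tau
  f <- params$ap_plateau_fraction
  d <- params$ap_plateau_dur * scale
  r <- params$ap_repol_tau * scale
  U <- stats::plogis((tau - 5 * u) / u)
  g <- ifelse(tau < d, 1, exp(-(tau - d) / r))
  s <- U * ((1 - f) * exp(-tau / r) + f * g)
  s[tau < 0] <- 0
  s
}

# CaT shape at local time tau after transient onset: cosine-bell rise over
# rise_dur, then mono-exponential decay; a softplus blend of width `w`
# keeps the peak smooth (C1) so sub-sample peak refinement is unbiased,
# while the decay segment remains exactly exponential with cat_decay_tau.
cat_shape <- function(tau, rise_dur, decay_tau, w = 8) {
  rise <- ifelse(tau <= 0, 0,
                 ifelse(tau < rise_dur, (1 - cos(pi * tau / rise_dur)) / 2, 1))
  x <- (tau - rise_dur) / w
  sp <- w * ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  rise * exp(-sp / decay_tau)
}

# Dense-grid oracle: measure AP metrics of a single beat waveform evaluated
# on a 0.01 ms grid over [0, horizon]. Returns activation offset (from the
# stimulus), APD at the requested levels, and the 99%-repolarization time.
measure_ap_dense <- function(params, scale = 1, horizon = 1500,
                             levels = c(20, 50, 80, 90), grid_dt = 0.01) {
  tg <- seq(0, horizon, by = grid_dt)
  y <- ap_shape(tg, params, scale)
  amp <- max(y)
  if (amp <= 0) {
    out <- rep(NA_real_, length(levels))
    names(out) <- paste0("apd", levels)
    return(c(list(act = NA_real_, t99 = NA_real_), as.list(out)))
  }
  act <- max_deriv_time(tg, y)$time
  pk <- peak_time_refined(tg, y)$time
  out <- vapply(levels, function(L)
    duration_at_level(tg, y, act, L, 0, amp, peak_time = pk), 0)
  names(out) <- paste0("apd", levels)
  t99 <- duration_at_level(tg, y, act, 99, 0, amp, peak_time = pk)
  c(list(act = act, t99 = t99), as.list(out))
}

# Calibrated CaT rise duration: root-solve so the dense-grid measured
# time-to-peak (10% upstroke to refined peak) equals params$cat_ttp.
# Memoised per (ttp, decay_tau) pair within a session.
.cat_rise_cache <- new.env(parent = emptyenv())
cat_rise_duration <- function(params) {
  key <- paste(params$cat_ttp, params$cat_decay_tau, sep = "|")
  hit <- .cat_rise_cache[[key]]
  if (!is.null(hit)) return(hit)
  k10 <- acos(0.8) / pi
  T0 <- params$cat_ttp / (1 - k10)
  tg <- seq(0, T0 * 3 + 6 * params$cat_decay_tau, by = 0.01)
  f <- function(Tr) {
    y <- cat_shape(tg, Tr, params$cat_decay_tau)
    amp <- max(y)
    pk <- peak_time_refined(tg, y)$time
    on <- cross_up(tg, y, 0.1 * amp, before = pk)
    (pk - on) - params$cat_ttp
  }
  Tr <- stats::uniroot(f, c(T0 * 0.7, T0 * 1.4), tol = 1e-5)$root
  .cat_rise_cache[[key]] <- Tr
  Tr
}

# Dense-grid oracle for one CaT beat: onset (10% crossing) offset from the
# transient start, time-to-peak, CaTD at the requested levels, 99% recovery.
measure_cat_dense <- function(params, horizon = 2500, levels = c(20, 50, 80),
                              grid_dt = 0.01) {
  Tr <- cat_rise_duration(params)
  tg <- seq(0, horizon, by = grid_dt)
  y <- cat_shape(tg, Tr, params$cat_decay_tau)
  amp <- max(y)
  pk <- peak_time_refined(tg, y)$time
  onset <- cross_up(tg, y, 0.1 * amp, before = pk)
  out <- vapply(levels, function(L)
    duration_at_level(tg, y, onset, L, 0, amp, peak_time = pk), 0)
  names(out) <- paste0("catd", levels)
  t99 <- duration_at_level(tg, y, onset, 99, 0, amp, peak_time = pk)
  c(list(onset = onset, peak = pk, ttp = pk - onset, t99 = t99), as.list(out))
}

# Convention-aligned dense measurement of one AP beat in pacing context:
# the analysis window runs from the stimulus to the next stimulus, the
# baseline is the median over the pre-stimulus margin (which holds the
# previous beat's repolarization tail), and activation/peak/crossings are
# defined exactly as in the beats module. This is what the ground-truth
# manifest reports, so that recovery error on sampled traces measures
# sampling/interpolation error rather than a baseline-convention mismatch.
measure_ap_context <- function(params, s, nxt, scale = 1, prev = NULL,
                               grid_dt = 0.01, levels = c(20, 50, 80, 90)) {
  pre <- min(100, 0.25 * (nxt - s))
  t0 <- max(s - pre, 0)
  tg <- seq(t0, nxt, by = grid_dt)
  y <- numeric(length(tg))
  m <- tg < s
  if (!is.null(prev) && any(m))
    y[m] <- ap_shape(tg[m] - prev$s, params, prev$scale)
  y[!m] <- ap_shape(tg[!m] - s, params, scale)
  baseline <- if (any(m)) stats::median(y[tg <= s]) else 0
  win <- !m
  if (sum(win) < 3 || max(y[win]) <= baseline) {
    out <- as.list(rep(NA_real_, length(levels)))
    names(out) <- paste0("apd", levels)
    return(c(list(act_abs = NA_real_, t99 = NA_real_, baseline = baseline,
                  amplitude = 0), out))
  }
  act_abs <- max_deriv_time(tg[win], y[win])$time
  pk <- peak_time_refined(tg[win], y[win])
  amp <- pk$value - baseline
  out <- vapply(levels, function(L)
    duration_at_level(tg, y, act_abs, L, baseline, amp, peak_time = pk$time), 0)
  names(out) <- paste0("apd", levels)
  t99 <- duration_at_level(tg, y, act_abs, 99, baseline, amp,
                           peak_time = pk$time)
  c(list(act_abs = act_abs, t99 = t99, baseline = baseline, amplitude = amp),
    as.list(out))
}

# Map from repolarization time-scale to dense APD80 for one parameter set,
# used to invert restitution targets. Monotone spline over a scale grid.
ap_scale_map <- function(params, scale_range = c(0.12, 1.8)) {
  sg <- exp(seq(log(scale_range[1]), log(scale_range[2]), length.out = 13))
  a80 <- vapply(sg, function(s) measure_ap_dense(params, s)$apd80, 0)
  fun <- stats::splinefun(sg, a80, method = "hyman")
  list(fun = fun, range = range(a80))
}

# ---- generators ------------------------------------------------------------

#' Generate a synthetic voltage (action-potential) trace
#'
#' Renders one AP per captured stimulus of the pacing protocol. Each beat's
#' waveform occupies the window up to the next stimulus (a new activation
#' takes over the membrane). When `restitution` is supplied, the target
#' APD80 of beat *n* is `a - b * exp(-DI_n / c)` with
#' `DI_n = activation_n - (activation_(n-1) + APD80_(n-1))`, implemented by
#' stretching the repolarization envelope; a stimulus arriving inside the
#' refractory window (`di_min_capture` after the preceding APD80 point)
#' fails to capture and generates no beat, as in tissue.
#'
#' The returned trace carries a ground-truth manifest (`meta$manifest`):
#' per-beat activation time, APD20/50/80/90 measured on a 0.01 ms grid,
#' overlap and clamping flags, and the stimulus bookkeeping.
#'
#' @param params a [cell_type_params].
#' @param protocol a [pacing_protocol].
#' @param frame_rate sampling rate, frames/s.
#' @param duration recording length, ms.
#' @param restitution `NULL` or `list(a, b, c)` in ms (see
#'   [restitution_preset()]).
#' @param apd_floor minimum admissible target APD80 under restitution, ms;
#'   shorter targets are clamped and flagged.
#' @param di_min_capture refractory margin, ms: stimuli closer than this to
#'   the preceding APD80 point do not capture.
#' @return An [om_trace] (channel `"voltage"`) with `meta$manifest` (a
#'   data.frame) and `meta$params`.
#' @examples
#' tr <- generate_ap_trace(cell_preset("atrial"),
#'                         pacing_protocol("fixed", rate_bpm = 60, n_beats = 3),
#'                         duration = 3200)
#' tr$meta$manifest$apd80
#' @export
generate_ap_trace <- function(params, protocol, frame_rate = 100,
                              duration = 10000, restitution = NULL,
                              apd_floor = 60, di_min_capture = 40) {
  stopifnot(inherits(params, "cell_type_params"),
            inherits(protocol, "pacing_protocol"), frame_rate > 0)
  st <- stimulus_times(protocol, duration)
  if (length(st) && (min(st) < 0 || max(st) > duration))
    stop("stimulus times must fall inside [0, duration]")
  dt <- 1000 / frame_rate
  time <- seq(0, duration - dt, by = dt)
  values <- rep(params$resting_level, length(time))
  flat <- params$amplitude == 0

  smap <- if (!is.null(restitution)) ap_scale_map(params) else NULL
  base0 <- if (!flat) measure_ap_dense(params, 1) else NULL
  rows <- list(); skipped <- numeric(0)
  prev <- NULL        # last captured beat: s, scale, end_dyn, t99_abs
  captured <- list()

  for (k in seq_along(st)) {
    s <- st[k]
    nxt <- if (k < length(st)) st[k + 1] else duration
    if (flat) {
      rows[[length(rows) + 1L]] <- data.frame(
        beat = k, stim_time = s, di = NA_real_, scale = 1,
        target_apd80 = NA_real_, act_time = NA_real_,
        baseline = params$resting_level, amplitude = 0,
        apd20 = NA_real_, apd50 = NA_real_, apd80 = NA_real_,
        apd90 = NA_real_, overlap = FALSE, clamped = FALSE)
      next
    }
    ref_end <- if (is.null(prev)) -Inf else prev$end_dyn
    if (s - ref_end < di_min_capture) { skipped <- c(skipped, s); next }
    # DI referenced to the incoming activation (stimulus + upstroke
    # latency), matching DI = CL - APD80 under stimulus-aligned analysis
    di <- (s + base0$act) - ref_end   # Inf before the first beat
    scale <- 1; clamped <- FALSE; target <- NA_real_
    if (!is.null(restitution)) {
      target <- restitution$a - restitution$b * exp(-di / restitution$c)
      if (target < apd_floor) { target <- apd_floor; clamped <- TRUE }
      target <- min(max(target, smap$range[1] + 1e-6), smap$range[2] - 1e-6)
      scale <- stats::uniroot(function(x) smap$fun(x) - target,
                              c(0.12, 1.8), tol = 1e-6)$root
      # refine against the convention-aligned contextual measurement so
      # that the *measured* APD80 lands on the prescribed curve
      f <- function(sc) measure_ap_context(params, s, nxt, sc, prev,
                                           grid_dt = 0.05)$apd80
      a0 <- f(scale)
      if (!is.na(a0) && abs(a0 - target) > 0.05) {
        sc1 <- scale * max(min(target / a0, 1.5), 0.5)
        a1 <- f(sc1)
        for (it in 1:3) {
          if (is.na(a1) || abs(a1 - target) <= 0.05 || a1 == a0) break
          sc2 <- sc1 + (target - a1) * (sc1 - scale) / (a1 - a0)
          sc2 <- max(min(sc2, 1.8), 0.12)
          scale <- sc1; a0 <- a1
          sc1 <- sc2; a1 <- f(sc1)
        }
        if (!is.na(a1)) scale <- sc1
      }
    }
    truth <- measure_ap_context(params, s, nxt, scale, prev)
    overlap <- !is.null(prev) && (is.na(prev$t99_abs) || s < prev$t99_abs)
    rows[[length(rows) + 1L]] <- data.frame(
      beat = k, stim_time = s, di = ifelse(is.finite(di), di, NA_real_),
      scale = scale, target_apd80 = target,
      act_time = truth$act_abs, baseline = truth$baseline,
      amplitude = truth$amplitude,
      apd20 = truth$apd20, apd50 = truth$apd50,
      apd80 = truth$apd80, apd90 = truth$apd90,
      overlap = overlap, clamped = clamped)
    end_meas <- if (!is.na(truth$apd80)) truth$act_abs + truth$apd80 else NA_real_
    end_dyn <- if (!is.na(end_meas)) end_meas else
      s + base0$act + (if (!is.null(smap)) smap$fun(scale) else base0$apd80)
    t99_abs <- if (!is.na(truth$t99) && !is.na(truth$act_abs))
      truth$act_abs + truth$t99 else NA_real_
    prev <- list(s = s, scale = scale, end_dyn = end_dyn, t99_abs = t99_abs)
    captured[[length(captured) + 1L]] <- list(s = s, scale = scale)
  }

  # render: each captured beat owns the samples up to the next captured beat
  if (!flat && length(captured)) {
    cs <- vapply(captured, `[[`, 0, "s")
    ends <- c(cs[-1], duration)
    for (j in seq_along(captured)) {
      in_win <- time >= cs[j] & time < ends[j]
      values[in_win] <- params$resting_level +
        params$amplitude * ap_shape(time[in_win] - cs[j], params,
                                    captured[[j]]$scale)
    }
  }

  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beat = integer(0))
  om_trace(time, values, channel = "voltage", frame_rate = frame_rate,
           meta = list(manifest = manifest, params = params,
                       skipped_stimuli = skipped,
                       stimulus_times = as.numeric(st),
                       restitution = restitution))
}

#' Generate a synthetic calcium-transient trace
#'
#' One Ca2+ transient per stimulus: onset `cat_onset_delay` ms after the
#' stimulus, smooth rise calibrated so the true time-to-peak (10% upstroke
#' to peak) equals `cat_ttp`, then mono-exponential decay with
#' `cat_decay_tau`. The ground-truth manifest records per-beat onset, peak,
#' TTP, decay tau, and CaTD20/50/80 measured on a 0.01 ms grid.
#'
#' @inheritParams generate_ap_trace
#' @return An [om_trace] (channel `"calcium"`) with `meta$manifest` and
#'   `meta$params`.
#' @examples
#' tr <- generate_cat_trace(cell_preset("atrial"),
#'                          pacing_protocol("fixed", rate_bpm = 60, n_beats = 3),
#'                          duration = 3200)
#' tr$meta$manifest$ttp
#' @export
generate_cat_trace <- function(params, protocol, frame_rate = 100,
                               duration = 10000) {
  stopifnot(inherits(params, "cell_type_params"),
            inherits(protocol, "pacing_protocol"), frame_rate > 0)
  st <- stimulus_times(protocol, duration)
  if (length(st) && (min(st) < 0 || max(st) > duration))
    stop("stimulus times must fall inside [0, duration]")
  dt <- 1000 / frame_rate
  time <- seq(0, duration - dt, by = dt)
  values <- rep(params$resting_level, length(time))
  flat <- params$amplitude == 0
  tau <- params$cat_decay_tau
  if (!flat) {
    Tr <- cat_rise_duration(params)
    support <- Tr + 12 * tau   # beyond this a transient's tail is negligible
    onsets <- as.numeric(st) + params$cat_onset_delay
    # additive transient summation: diastolic Ca accumulates at fast rates
    summed <- function(tg) {
      y <- numeric(length(tg))
      for (on in onsets) {
        sel <- tg >= on & tg < on + support
        if (any(sel)) y[sel] <- y[sel] + cat_shape(tg[sel] - on, Tr, tau)
      }
      params$amplitude * y
    }
    values <- params$resting_level + summed(time)
  }

  rows <- list(); prev_t99_abs <- NA_real_; first_done <- FALSE
  for (k in seq_along(st)) {
    s <- st[k]
    nxt <- if (k < length(st)) st[k + 1] else duration
    if (flat) {
      rows[[k]] <- data.frame(
        beat = k, stim_time = s, onset_time = NA_real_, peak_time = NA_real_,
        ttp = NA_real_, tau = NA_real_, catd20 = NA_real_, catd50 = NA_real_,
        catd80 = NA_real_, baseline = params$resting_level, amplitude = 0,
        overlap = FALSE)
      next
    }
    pre <- min(100, 0.25 * (nxt - s))
    tg <- seq(max(s - pre, 0), nxt, by = 0.01)
    y <- summed(tg)
    m <- tg < s
    baseline <- if (any(m)) stats::median(y[tg <= s]) else params$resting_level
    win <- !m
    pk <- peak_time_refined(tg[win], y[win])
    amp <- pk$value - baseline
    onset10 <- if (amp > 0) cross_up(tg, y, baseline + 0.1 * amp,
                                     before = pk$time) else NA_real_
    if (!is.na(onset10)) {
      cds <- vapply(c(20, 50, 80), function(L)
        duration_at_level(tg, y, onset10, L, baseline, amp,
                          peak_time = pk$time), 0)
      t99 <- duration_at_level(tg, y, onset10, 99, baseline, amp,
                               peak_time = pk$time)
      ttp <- pk$time - onset10
    } else {
      cds <- rep(NA_real_, 3); t99 <- NA_real_; ttp <- NA_real_
    }
    overlap <- first_done && (is.na(prev_t99_abs) || s < prev_t99_abs)
    rows[[k]] <- data.frame(
      beat = k, stim_time = s, onset_time = onset10, peak_time = pk$time,
      ttp = ttp, tau = tau, catd20 = cds[1], catd50 = cds[2],
      catd80 = cds[3], baseline = baseline, amplitude = amp,
      overlap = overlap)
    prev_t99_abs <- if (!is.na(t99) && !is.na(onset10)) onset10 + t99 else NA_real_
    first_done <- TRUE
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(beat = integer(0))
  om_trace(time, values, channel = "calcium", frame_rate = frame_rate,
           meta = list(manifest = manifest, params = params,
                       stimulus_times = as.numeric(st)))
}

# ---- drug and noise models -------------------------------------------------

#' Saturating dose-effect model for a drug
#'
#' Each effect entry targets one duration-controlling waveform parameter
#' (or the convenience groups `"apd"` = plateau + repolarization tau and
#' `"catd"` = CaT decay tau) and scales it by
#' `1 + emax * dose^n / (dose^n + ec50^n)` - a Hill curve with signed
#' maximal fractional change `emax`.
#'
#' @param name drug label.
#' @param effects list of `list(param=, emax=, ec50=, hill_n=, group=)`
#'   entries; `hill_n` defaults to 1. An entry with a `group` field
#'   (`"atrial"` or `"ventricular"`) applies only to that cell type,
#'   which is how chamber-selective pharmacology is expressed.
#' @return An object of class `drug_model`.
#' @examples
#' dofetilide_like <- drug_model("dofetilide-like",
#'   list(list(param = "apd", emax = 1.2, ec50 = 12),
#'        list(param = "catd", emax = 0.5, ec50 = 12)))
#' @export
drug_model <- function(name, effects) {
  ok_params <- c("apd", "catd", "ap_plateau_dur", "ap_repol_tau",
                 "cat_decay_tau", "cat_ttp")
  for (e in effects) {
    if (!e$param %in% ok_params)
      stop("unknown drug target parameter: ", e$param)
    if (is.null(e$hill_n)) e$hill_n <- 1
    if (e$ec50 <= 0) stop("ec50 must be > 0")
    if ((e$hill_n %||% 1) <= 0) stop("hill_n must be > 0")
  }
  structure(list(name = name, effects = effects), class = "drug_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("<drug_model> %s: %d effect(s)\n", x$name, length(x$effects)))
  for (e in x$effects)
    cat(sprintf("  %s: emax %+.2f, ec50 %g, hill %g\n",
                e$param, e$emax, e$ec50, e$hill_n %||% 1))
  invisible(x)
}

#' Apply a drug dose to waveform parameters
#'
#' Scales each targeted duration parameter by the Hill factor
#' `1 + emax * dose^n / (dose^n + ec50^n)`; untargeted parameters are
#' unchanged and dose 0 is an exact identity.
#'
#' @param params a [cell_type_params].
#' @param drug a [drug_model].
#' @param dose concentration, same units as the model's `ec50`; must be
#'   >= 0.
#' @return A modified [cell_type_params].
#' @examples
#' p <- apply_drug_effect(cell_preset("atrial"),
#'   drug_model("d", list(list(param = "apd", emax = 1, ec50 = 10))), 10)
#' p$ap_repol_tau / cell_preset("atrial")$ap_repol_tau  # 1.5 at ec50
#' @export
apply_drug_effect <- function(params, drug, dose) {
  stopifnot(inherits(params, "cell_type_params"), inherits(drug, "drug_model"))
  if (dose < 0) stop("dose must be >= 0")
  groups <- list(apd = c("ap_plateau_dur", "ap_repol_tau"),
                 catd = "cat_decay_tau")
  for (e in drug$effects) {
    if (!is.null(e$group) && e$group != params$label) next
    n <- e$hill_n %||% 1
    fac <- 1 + e$emax * dose^n / (dose^n + e$ec50^n)
    targets <- groups[[e$param]] %||% e$param
    for (p in targets) params[[p]] <- params[[p]] * fac
  }
  params
}

#' Acquisition noise model
#'
#' Additive Gaussian noise plus a slow linear baseline drift emulating
#' photobleaching, both expressed as fractions of the clean signal
#' amplitude. A fixed seed makes the generated noise bit-reproducible.
#'
#' @param gaussian_sd per-sample noise SD, fraction of amplitude.
#' @param drift_slope baseline drift, fraction of amplitude per second
#'   (positive or negative).
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 0.03, drift_slope = -0.008, seed = 1L) {
  stopifnot(gaussian_sd >= 0)
  structure(list(gaussian_sd = gaussian_sd, drift_slope = drift_slope,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# run `expr` under a private seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add acquisition noise and drift to a trace
#'
#' @param trace an [om_trace].
#' @param noise a [noise_model].
#' @return The trace with noise and drift added; the clean amplitude used
#'   for scaling is `max - min` of the input values.
#' @export
add_noise <- function(trace, noise) {
  stopifnot(inherits(trace, "om_trace"), inherits(noise, "noise_model"))
  amp <- diff(range(trace$values))
  if (amp == 0) amp <- 1
  n <- length(trace$values)
  eps <- with_seed(noise$seed, stats::rnorm(n, 0, noise$gaussian_sd * amp))
  drift <- noise$drift_slope * amp * (trace$time - trace$time[1]) / 1000
  trace$values <- trace$values + eps + drift
  trace$meta$noise <- noise
  trace
}
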