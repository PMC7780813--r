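# Shared fixtures, generated once per test run and cached: several test
# files reuse the same noiseless paced recordings and their ground-truth
# manifests.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- maker()
  .fx_cache[[name]]
}

pro_1hz <- function(n = 9) pacing_protocol("fixed", rate_bpm = 60, n_beats = n)

fx_paced <- function(ct) {
  fx(paste0("paced_", ct), function() {
    v <- generate_ap_trace(cell_preset(ct), pro_1hz(), duration = 10000)
    ca <- generate_cat_trace(cell_preset(ct), pro_1hz(), duration = 10000)
    list(v = v, ca = ca,
         v_cond = condition_trace(v),
         ca_cond = condition_trace(ca, polarity = "positive"))
  })
}

fx_metrics <- function(ct) {
  fx(paste0("metrics_", ct), function() {
    p <- fx_paced(ct)
    beat_metrics(p$v_cond, p$ca_cond, pro_1hz())
  })
}

# retained (analyzable) beats of a metrics table
ok_rows <- function(m) m$captured & !m$truncated

# a simple triangular AP sampled at 1 kHz: instant upstroke at t = 100 ms,
# then linear repolarization over `fall` ms
triangle_trace <- function(fall = 400, dt = 1, t_up = 100, total = 1000) {
  t <- seq(0, total, by = dt)
  y <- ifelse(t < t_up, 0, pmax(1 - (t - t_up) / fall, 0))
  om_trace(t, y, channel = "voltage")
}

# ramp recording -> restitution fit for a preset, cached
fx_ramp_fit <- function(ct) {
  fx(paste0("rampfit_", ct), function() {
    rp <- pacing_protocol("ramp", bpm_start = 60, bpm_end = 200)
    v <- generate_ap_trace(cell_preset(ct), rp,
                           duration = max(stimulus_times(rp)) + 1500,
                           restitution = restitution_preset(ct))
    m <- beat_metrics(condition_trace(v), NULL, rp)
    pts <- compute_di(m, rp)
    list(fit = fit_restitution(pts), pts = pts, metrics = m, trace = v,
         protocol = rp)
  })
}

one_beat <- function(trace, stim = 50) {
  pro <- pacing_protocol(stimulus_times = stim)
  b <- detect_beats(trace, pro)
  b[1, ]
}
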