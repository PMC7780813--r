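# Low-level measurement primitives shared by the beat-metrics module and the
# synthetic generator's dense-grid ground truth. All operate on plain
# (time, values) vectors so the same definitions apply to a 0.01 ms oracle
# grid and to 10 ms camera sampling.

# Time of maximal upstroke derivative. Finite differences are centred on
# sample midpoints; the discrete maximum is refined by a quadratic fit to
# the three neighbouring derivative values (ties broken by earliest time,
# which is what which.max does).
max_deriv_time <- function(time, values) {
  dy <- diff(values) / diff(time)
  i <- which.max(dy)
  tm <- (time[i] + time[i + 1]) / 2
  if (i > 1L && i < length(dy)) {
    ts <- (time[i + 0:2] + time[i + (-1):1]) / 2
    ys <- dy[(i - 1):(i + 1)]
    dd <- ys[1] - 2 * ys[2] + ys[3]
    if (dd < 0) {
      off <- 0.5 * (ys[1] - ys[3]) / dd * (ts[2] - ts[1])
      if (abs(off) <= (ts[2] - ts[1])) tm <- ts[2] + off
    }
  }
  list(time = tm, slope = max(dy))
}

# Peak location with quadratic sub-sample refinement (first global max).
peak_time_refined <- function(time, values) {
  i <- which.max(values)
  tp <- time[i]
  if (i > 1L && i < length(values)) {
    dd <- values[i - 1] - 2 * values[i] + values[i + 1]
    if (dd < 0) {
      off <- 0.5 * (values[i - 1] - values[i + 1]) / dd * (time[i] - time[i - 1])
      if (abs(off) <= (time[i] - time[i - 1])) tp <- time[i] + off
    }
  }
  list(time = tp, index = i, value = values[i])
}

# First downward crossing of `level` at or after `from`; linear
# interpolation between samples. NA if never crossed.
cross_down <- function(time, values, level, from = -Inf) {
  n <- length(values)
  idx <- which(values[-n] > level & values[-1] <= level)
  idx <- idx[time[idx] >= from | time[idx + 1] >= from]
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  time[i] + (values[i] - level) / (values[i] - values[i + 1]) * (time[i + 1] - time[i])
}

# First upward crossing of `level` at or before `before` (search from the
# start); linear interpolation. NA if never crossed.
cross_up <- function(time, values, level, before = Inf) {
  n <- length(values)
  idx <- which(values[-n] < level & values[-1] >= level)
  idx <- idx[time[idx] <= before]
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  time[i] + (level - values[i]) / (values[i + 1] - values[i]) * (time[i + 1] - time[i])
}

# Duration from a reference time to the downward crossing of
# baseline + (1 - level_pct/100) * amplitude. NA (undefined, flagged by
# callers) when repolarization never reaches the level in the window.
duration_at_level <- function(time, values, ref_time, level_pct, baseline,
                              amplitude, peak_time = ref_time) {
  lev <- baseline + (1 - level_pct / 100) * amplitude
  tc <- cross_down(time, values, lev, from = max(ref_time, peak_time))
  if (is.na(tc)) return(NA_real_)
  tc - ref_time
}
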