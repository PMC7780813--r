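# Electrical restitution: DI construction, curve fitting, maximum slope.

ramp_points <- function(ct, res, bpm_end = 200) {
  rp <- pacing_protocol("ramp", bpm_start = 60, bpm_end = bpm_end)
  v <- generate_ap_trace(cell_preset(ct), rp,
                         duration = max(stimulus_times(rp)) + 1500,
                         restitution = res)
  m <- beat_metrics(condition_trace(v), NULL, rp)
  list(pts = compute_di(m, rp), metrics = m, trace = v, protocol = rp)
}

test_that("DI arithmetic: cycle length minus the preceding APD80", {
  m <- data.frame(beat = 1:3, activation_time = c(1000, 2000, 3000),
                  apd80 = c(250, 250, 250), captured = TRUE,
                  truncated = FALSE, stim_time = c(970, 1970, 2970))
  pro <- pacing_protocol("ramp", bpm_start = 60, bpm_end = 80,
                         stimulus_times = c(970, 1970, 2970))
  pts <- compute_di(m, pro)
  expect_equal(pts$di, c(750, 750))
  expect_error(compute_di(m, pacing_protocol("fixed")), "ramp")
})

test_that("rate-independent synthetic APD yields a flat curve with near-zero slope", {
  di <- seq(100, 700, by = 25)
  pts <- data.frame(di = di, apd80 = rep(200, length(di)))
  fit <- fit_restitution(pts)
  expect_lt(fit$max_slope, 0.05)
  # with sub-ms jitter the flat-curve property still holds
  pts$apd80 <- 200 + 0.3 * sin(di)
  expect_lt(fit_restitution(pts)$max_slope, 0.05)
})

test_that("exact exponential points recover the generator parameters and closed-form slope", {
  a <- 300; b <- 150; cc <- 100
  di <- seq(50, 650, by = 25)
  pts <- data.frame(di = di, apd80 = a - b * exp(-di / cc))
  fit <- fit_restitution(pts)
  expect_lt(abs(coef(fit)[["a"]] / a - 1), 0.01)
  expect_lt(abs(coef(fit)[["b"]] / b - 1), 0.01)
  expect_lt(abs(coef(fit)[["c"]] / cc - 1), 0.01)
  closed <- (b / cc) * exp(-50 / cc)  # 1.5 * exp(-0.5) = 0.9098
  expect_lt(abs(fit$max_slope / closed - 1), 0.01)
  expect_equal(closed, 0.9098, tolerance = 1e-4)
})

test_that("ramp recordings with generator restitution land on the prescribed curve", {
  res <- list(a = 300, b = 150, c = 100)
  out <- ramp_points("ventricular", res, bpm_end = 150)
  pts <- out$pts
  expect_gt(nrow(pts), 40)
  resid <- pts$apd80 - (res$a - res$b * exp(-pts$di / res$c))
  expect_lt(max(abs(resid)), 3)
  fit <- fit_restitution(pts)
  expect_lt(abs(coef(fit)[["b"]] / res$b - 1), 0.05)
  # by construction APD80 + DI of the next beat reproduces the cycle length
  m <- out$metrics
  okm <- m[ok_rows(m) & !is.na(m$apd80), ]
  pair <- match(pts$beat, okm$beat)
  cl <- okm$cycle_length[pair]
  prev_apd <- okm$apd80[pair - 1]
  expect_lt(stats::median(abs(pts$di + prev_apd - cl), na.rm = TRUE), 2)
})

test_that("preset tuning preserves the ventricular > atrial slope ordering", {
  fit_a <- fx_ramp_fit("atrial")$fit
  fit_v <- fx_ramp_fit("ventricular")$fit
  expect_gt(fit_v$max_slope, fit_a$max_slope)
  expect_lt(abs(fit_a$max_slope - 0.91), 0.15)
  expect_lt(abs(fit_v$max_slope - 1.26), 0.2)
  # slope is invariant to affine transforms of the fluorescence values
  rp <- pacing_protocol("ramp", bpm_start = 60, bpm_end = 200)
  v <- generate_ap_trace(cell_preset("atrial"), rp,
                         duration = max(stimulus_times(rp)) + 1500,
                         restitution = restitution_preset("atrial"))
  aff <- v; aff$values <- 40 * v$values + 3
  m_aff <- beat_metrics(condition_trace(aff), NULL, rp)
  fit_aff <- fit_restitution(compute_di(m_aff, rp))
  expect_equal(fit_aff$max_slope, fit_a$max_slope, tolerance = 1e-4)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_restitution(data.frame(di = c(100, 200), apd80 = c(1, 2))),
               "at least 5")
  expect_error(fit_restitution(data.frame(di = seq(100, 140, 10),
                                          apd80 = 200 + 1:5)),
               "100 ms")
})
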