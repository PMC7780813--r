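# Beat segmentation and per-beat AP / CaT metrics.

test_that("stimulus-aligned detection yields one beat per stimulus", {
  p <- fx_paced("atrial")
  b <- detect_beats(p$v_cond, pro_1hz(9))
  expect_equal(nrow(b), 9)
  expect_true(all(b$captured))
  expect_true(all(b$t_start < b$activation_time &
                    b$activation_time <= b$peak_time &
                    b$peak_time < b$t_end, na.rm = TRUE))
})

test_that("a flat trace yields zero beats with a warning, not an error", {
  t <- seq(0, 5000, by = 10)
  flat <- om_trace(t, rep(0.5, length(t)), channel = "voltage")
  expect_warning(b <- detect_beats(flat, pacing_protocol("spontaneous")),
                 "no beats")
  expect_equal(nrow(b), 0)
})

test_that("spontaneous detection recovers known event times and rate", {
  events <- c(300, 1250, 2300, 3250, 4300, 5250, 6300)
  gen <- generate_ap_trace(cell_preset("atrial"),
                           pacing_protocol(stimulus_times = events),
                           duration = 7500)
  cond <- condition_trace(gen)
  b <- detect_beats(cond, pacing_protocol("spontaneous"))
  expect_equal(nrow(b), length(events))
  man <- gen$meta$manifest
  expect_lt(max(abs(b$activation_time - man$act_time)), 10)  # one sample
  rate <- beating_rate(b)
  true_rate <- 60000 / mean(diff(man$act_time))
  expect_lt(abs(rate - true_rate) / true_rate, 0.01)
})

test_that("beating rate follows the inter-activation interval", {
  mk <- function(gaps) {
    acts <- cumsum(c(500, gaps))
    data.frame(activation_time = acts, captured = TRUE)
  }
  expect_equal(beating_rate(mk(rep(1000, 5))), 60)
  expect_equal(beating_rate(mk(rep(500, 5))), 120)
  expect_warning(r <- beating_rate(mk(numeric(0))), "fewer than 2")
  expect_true(is.na(r))
})

test_that("square pulses give level-independent durations", {
  t <- seq(0, 2000, by = 10)
  y <- as.numeric(t >= 200 & t < 500)  # 300 ms pulse
  tr <- om_trace(t, y, channel = "voltage")
  b <- one_beat(tr, stim = 190)
  for (L in c(20, 50, 80, 90))
    expect_lt(abs(apd(tr, b, L) - 300), 11)
  ca <- om_trace(t, as.numeric(t >= 200 & t < 700), channel = "calcium")
  bc <- one_beat(ca, stim = 190)
  for (L in c(20, 50, 80))
    expect_lt(abs(catd(ca, bc, L) - 500), 11)
  # flat-top peak: parabolic refinement may move the vertex ~half a sample
  expect_lt(abs(time_to_peak(ca, bc)), 16)
})

test_that("triangular repolarization yields APDx = 4 x level", {
  tr <- triangle_trace(fall = 400, dt = 1)
  b <- one_beat(tr, stim = 95)
  expect_lt(abs(apd(tr, b, 20) - 80), 2)
  expect_lt(abs(apd(tr, b, 50) - 200), 2)
  expect_lt(abs(apd(tr, b, 80) - 320), 2)
})

test_that("instant-rise exponential decay matches closed-form CaTD crossings", {
  t <- seq(0, 2500, by = 1)
  tau <- 300
  y <- ifelse(t < 400, 0, exp(-(t - 400) / tau))
  tr <- om_trace(t, y, channel = "calcium")
  b <- one_beat(tr, stim = 395)
  expect_lt(abs(catd(tr, b, 50) - tau * log(2)), 2)    # 207.9 ms
  expect_lt(abs(catd(tr, b, 80) - tau * log(5)), 2)    # 482.8 ms
  ft <- decay_tau(tr, b)
  expect_true(ft$converged)
  expect_lt(abs(ft$tau - tau), 1)
})

test_that("time to peak of a linear 100 ms rise is 90 ms from the 10% crossing", {
  t <- seq(0, 1500, by = 1)
  y <- ifelse(t < 200, 0, ifelse(t < 300, (t - 200) / 100,
                                 exp(-(t - 300) / 250)))
  tr <- om_trace(t, y, channel = "calcium")
  b <- one_beat(tr, stim = 195)
  expect_lt(abs(time_to_peak(tr, b) - 90), 2)
})

test_that("max upstroke and resting level are read from the expected segments", {
  t <- seq(0, 1000, by = 1)
  y <- ifelse(t < 300, 0, ifelse(t < 400, (t - 300) * 0.004, 0.4 * exp(-(t - 400) / 150)))
  tr <- om_trace(t, y, channel = "voltage")
  b <- one_beat(tr, stim = 295)
  ur <- upstroke_and_rest(tr, b)
  expect_equal(ur$max_upstroke, 0.004, tolerance = 1e-6)
  expect_equal(ur$resting_level, 0)
  # synthetic preset: derivative maximum at the manifest activation time
  p <- fx_paced("atrial")
  bb <- detect_beats(p$v_cond, pro_1hz())
  man <- p$v$meta$manifest
  expect_lt(max(abs(bb$activation_time - man$act_time), na.rm = TRUE), 10)
})

test_that("noiseless preset recovery stays within 2 ms of the dense-grid manifest", {
  for (ct in c("atrial", "ventricular")) {
    p <- fx_paced(ct)
    m <- fx_metrics(ct)
    man <- p$v$meta$manifest
    cman <- p$ca$meta$manifest
    ok <- ok_rows(m)
    iv <- match(m$beat[ok], man$beat)
    ic <- match(m$beat[ok], cman$beat)
    for (L in c(20, 50, 80, 90))
      expect_lt(max(abs(m[[paste0("apd", L)]][ok] -
                          man[[paste0("apd", L)]][iv])), 2)
    for (L in c(20, 50, 80))
      expect_lt(max(abs(m[[paste0("catd", L)]][ok] -
                          cman[[paste0("catd", L)]][ic])), 2)
    expect_lt(max(abs(m$ttp[ok] - cman$ttp[ic])), 2)
    expect_lt(max(abs(m$tau[ok] / cman$tau[ic] - 1)), 0.01)
  }
})

test_that("recovery error shrinks with sampling rate", {
  pro <- pro_1hz(4)
  v_hi <- generate_ap_trace(cell_preset("atrial"), pro, frame_rate = 1000,
                            duration = 5000)
  m <- beat_metrics(condition_trace(v_hi), NULL, pro)
  man <- v_hi$meta$manifest
  ok <- ok_rows(m)
  expect_lt(max(abs(m$apd80[ok] - man$apd80[match(m$beat[ok], man$beat)])),
            0.2)
})

test_that("decay tau is robust to 5% noise across replicate beats", {
  ca <- fx_paced("atrial")$ca
  taus <- numeric(0)
  for (s in 1:10) {
    noisy <- add_noise(ca, noise_model(gaussian_sd = 0.05, drift_slope = 0,
                                       seed = 100 + s))
    cc <- condition_trace(noisy, polarity = "positive", smooth = TRUE)
    b <- detect_beats(cc, pro_1hz())
    ok <- which(b$captured & !b$truncated)
    taus <- c(taus, vapply(ok, function(i) decay_tau(cc, b[i, ])$tau, 0))
  }
  taus <- taus[!is.na(taus)]
  expect_gte(length(taus), 80)
  expect_lt(abs(mean(taus) - 350) / 350, 0.03)
})

test_that("metrics are invariant to positive affine transforms and time shifts", {
  p <- fx_paced("atrial")
  m0 <- fx_metrics("atrial")
  aff <- p$v; aff$values <- 250 * p$v$values + 1000
  ca_aff <- p$ca; ca_aff$values <- 31 * p$ca$values + 7
  m1 <- beat_metrics(condition_trace(aff),
                     condition_trace(ca_aff, polarity = "positive"), pro_1hz())
  ok <- ok_rows(m0)
  expect_equal(m0$apd80[ok], m1$apd80[ok], tolerance = 1e-6)
  expect_equal(m0$catd80[ok], m1$catd80[ok], tolerance = 1e-6)
  # time shift: same waveform delayed by 2 cycles, protocol shifted with it
  pro_shift <- pacing_protocol("fixed", rate_bpm = 60, n_beats = 9, t0 = 2050)
  v_shift <- generate_ap_trace(cell_preset("atrial"), pro_shift,
                               duration = 12000)
  m2 <- beat_metrics(condition_trace(v_shift), NULL, pro_shift)
  ok2 <- ok_rows(m2)
  expect_equal(mean(m2$apd80[ok2]), mean(m0$apd80[ok]), tolerance = 1e-3)
})

test_that("undefined metrics are flagged missing, never zero", {
  # repolarization cut off by the end of the recording
  pro <- pacing_protocol("fixed", rate_bpm = 60, n_beats = 3)
  v <- generate_ap_trace(cell_preset("ventricular"), pro, duration = 2300)
  cc <- condition_trace(v)
  b <- detect_beats(cc, pro)
  last <- b[nrow(b), ]
  expect_true(last$truncated)
  expect_true(is.na(apd(cc, last, 80)))
  expect_false(any(stats::na.omit(c(b$amplitude)) == 0))
})
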