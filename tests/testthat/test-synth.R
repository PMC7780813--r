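# Synthetic generator: waveform identities, ground-truth manifests, drug
# and noise models.

test_that("zero-amplitude parameters give flat traces equal to the resting level", {
  p <- cell_preset("atrial")
  p$amplitude <- 0
  p$resting_level <- 0.37
  v <- generate_ap_trace(p, pro_1hz(3), duration = 3200)
  ca <- generate_cat_trace(p, pro_1hz(3), duration = 3200)
  expect_equal(v$values, rep(0.37, length(v$time)))
  expect_equal(ca$values, rep(0.37, length(ca$time)))
  expect_true(all(is.na(v$meta$manifest$apd80)))
})

test_that("manifest APD levels are monotone and presets hit the target phenotype", {
  for (ct in c("atrial", "ventricular")) {
    man <- fx_paced(ct)$v$meta$manifest
    expect_true(all(man$apd20 <= man$apd50 & man$apd50 <= man$apd80 &
                      man$apd80 <= man$apd90, na.rm = TRUE))
  }
  man_a <- fx_paced("atrial")$v$meta$manifest
  man_v <- fx_paced("ventricular")$v$meta$manifest
  # calibrated preset targets: atrial-like ~179 ms, ventricular-like ~251 ms
  expect_lt(abs(mean(man_a$apd80) - 179), 1.5)
  expect_lt(abs(mean(man_v$apd80) - 251), 1.5)
  # atrial shorter at every level, smaller plateau fraction
  expect_true(mean(man_a$apd20) < mean(man_v$apd20))
  expect_true(mean(man_a$apd80) < mean(man_v$apd80))
  expect_lt(cell_preset("atrial")$ap_plateau_fraction,
            cell_preset("ventricular")$ap_plateau_fraction)
})

test_that("CaT manifest carries the exact decay tau and calibrated time-to-peak", {
  man_a <- fx_paced("atrial")$ca$meta$manifest
  man_v <- fx_paced("ventricular")$ca$meta$manifest
  expect_equal(unique(man_a$tau), 350)
  expect_equal(unique(man_v$tau), 400)
  # rise calibration: the dense-grid TTP of an isolated transient equals the
  # preset parameter; in-train values shift only slightly with accumulation
  iso <- generate_cat_trace(cell_preset("atrial"),
                            pacing_protocol(stimulus_times = 100),
                            duration = 3000)
  expect_lt(abs(iso$meta$manifest$ttp[1] - 116), 0.1)
  expect_true(all(man_a$catd20 <= man_a$catd50 & man_a$catd50 <= man_a$catd80,
                  na.rm = TRUE))
  expect_true(mean(man_a$catd80, na.rm = TRUE) <
                mean(man_v$catd80, na.rm = TRUE))
  expect_true(mean(man_a$ttp, na.rm = TRUE) < mean(man_v$ttp, na.rm = TRUE))
})

test_that("isolated-transient CaT durations match the exponential closed form", {
  iso <- generate_cat_trace(cell_preset("atrial"),
                            pacing_protocol(stimulus_times = 100),
                            duration = 3000)
  man <- iso$meta$manifest[1, ]
  # both crossings sit in the purely exponential region, so their spacing
  # is exactly tau * log(5/2) whatever the peak-blend origin offset is
  expect_lt(abs((man$catd80 - man$catd50) - 350 * log(5 / 2)), 0.5)
  # absolute values agree with the from-peak closed form up to the ~9 ms
  # smooth-peak offset
  expect_lt(abs(man$catd50 - (man$ttp + 350 * log(2))), 12)
  expect_lt(abs(man$catd80 - (man$ttp + 350 * log(5))), 12)
})

test_that("drug effects follow the Hill curve and dose 0 is the identity", {
  d <- drug_model("test", list(list(param = "apd", emax = 0.8, ec50 = 12,
                                    hill_n = 1)))
  p0 <- cell_preset("atrial")
  expect_identical(apply_drug_effect(p0, d, 0), p0)
  # at ec50 the scaling is exactly 1 + emax/2
  p_mid <- apply_drug_effect(p0, d, 12)
  expect_equal(p_mid$ap_repol_tau, p0$ap_repol_tau * 1.4)
  expect_equal(p_mid$ap_plateau_dur, p0$ap_plateau_dur * 1.4)
  expect_equal(p_mid$cat_decay_tau, p0$cat_decay_tau)  # untargeted
  # saturation: at >= 100x ec50 the factor is within 1% of 1 + emax
  p_sat <- apply_drug_effect(p0, d, 1200)
  expect_lt(abs(p_sat$ap_repol_tau / p0$ap_repol_tau - 1.8), 0.01 * 1.8)
  expect_error(apply_drug_effect(p0, d, -1), "dose")
  # group-restricted effects leave the other cell type untouched
  ds <- drug_model("sel", list(list(param = "apd", emax = 1, ec50 = 10,
                                    group = "atrial")))
  expect_identical(apply_drug_effect(cell_preset("ventricular"), ds, 10),
                   cell_preset("ventricular"))
})

test_that("seeded noise is bit-reproducible and seed-sensitive", {
  v <- fx_paced("atrial")$v
  n1 <- add_noise(v, noise_model(seed = 11))
  n2 <- add_noise(v, noise_model(seed = 11))
  n3 <- add_noise(v, noise_model(seed = 12))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  # the injected noise is zero-mean around the clean trace
  expect_lt(abs(mean(n3$values - v$values) -
                  mean(noise_model()$drift_slope * diff(range(v$values)) *
                         v$time / 1000)), 0.02)
})

test_that("overlap regime is flagged, not an error", {
  # 250 ms cycle length forces stimuli inside the previous repolarization
  pro <- pacing_protocol("fixed", rate_bpm = 240, n_beats = 8)
  v <- generate_ap_trace(cell_preset("ventricular"), pro, duration = 2200)
  man <- v$meta$manifest
  expect_true(any(man$overlap) || length(v$meta$skipped_stimuli) > 0)
})

test_that("movie rendering is an exact identity without noise and digitization", {
  p <- fx_paced("atrial")
  spec <- movie_spec(height = 4, width = 4, gain = 1, offset = 0,
                     voltage_polarity = "positive")
  mv <- render_movie(p$v, p$ca, spec)
  n <- length(p$v$time)
  expect_equal(dim(mv$frames), c(4, 4, 2 * n))
  roi <- roi_spec(rows = c(1, 4), cols = c(1, 4))
  tv <- extract_roi_trace(mv$frames[, , seq(1, 2 * n, 2)], roi, 100, "voltage")
  expect_equal(tv$values, p$v$values, tolerance = 1e-12)
})

test_that("10 s at 100 frames/s renders 1000 frames per channel", {
  p <- fx_paced("atrial")  # 10 s recordings
  mv <- render_movie(p$v, p$ca, movie_spec(height = 2, width = 2))
  expect_equal(dim(mv$frames)[3], 2000)
})

test_that("seeded movie rendering is bit-identical across runs", {
  p <- fx_paced("atrial")
  spec <- movie_spec(height = 3, width = 3)
  nm <- noise_model(seed = 5)
  m1 <- render_movie(p$v, p$ca, spec, nm)
  m2 <- render_movie(p$v, p$ca, spec, nm)
  expect_identical(m1$frames, m2$frames)
})
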