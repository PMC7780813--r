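# Dose-response statistics: percent change, group summaries, Welch tests,
# ANOVA + Dunnett many-to-one comparisons, screen assembly.

test_that("percent change reproduces the printed worked examples", {
  expect_equal(percent_change(182, 355), 95.05, tolerance = 1e-3)
  expect_equal(percent_change(238, 319), 34.03, tolerance = 1e-3)
  expect_equal(percent_change(136, 188), 38.24, tolerance = 1e-3)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(200, 150), -25)  # shortening is negative
  expect_error(percent_change(0, 100), "baseline")
  expect_error(percent_change(-3, 100), "baseline")
})

test_that("forward and backward percent changes are asymmetric away from zero", {
  # multiplicative factors always invert each other exactly ...
  q1 <- percent_change(100, 150); q2 <- percent_change(150, 100)
  expect_equal((1 + q1 / 100) * (1 + q2 / 100), 1)
  # ... but the percent values themselves only mirror (q1 = -q2) at zero
  expect_false(isTRUE(all.equal(q1, -q2)))
  p0 <- percent_change(150, 150)
  expect_equal(p0, -percent_change(150, 150))
})

make_table <- function(values_by_dose, group = "atrial", metric = "apd80") {
  rows <- do.call(rbind, lapply(names(values_by_dose), function(d) {
    v <- values_by_dose[[d]]
    data.frame(well = paste0("w", seq_along(v)), group = group,
               dose = as.numeric(d), metric = metric, value = v)
  }))
  dose_response_table(rows)
}

test_that("dose tables enforce one baseline per well and zero baseline change", {
  tab <- make_table(list(`0` = c(100, 110, 120), `1` = c(150, 165, 180)))
  expect_equal(tab$pct_change[tab$dose == 0], c(0, 0, 0))
  expect_equal(tab$pct_change[tab$dose == 1], c(50, 50, 50))
  bad <- data.frame(well = "w1", group = "atrial", dose = 1,
                    metric = "apd80", value = 100)
  expect_error(dose_response_table(bad), "baseline")
})

test_that("group summaries report mean, SEM = sd/sqrt(n), and n", {
  tab <- make_table(list(`0` = c(1, 1, 1), `1` = c(10, 20, 30)))
  s <- summarize_groups(tab)
  r <- s[s$dose == 1, ]
  expect_equal(r$mean_value, 20)
  expect_equal(r$sem_value, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(r$n, 3)
  same <- make_table(list(`0` = c(2, 2), `1` = c(5, 5)))
  expect_equal(summarize_groups(same)$sem_value, c(0, 0))
})

test_that("between-group Welch test matches the closed-form example", {
  rows <- rbind(
    data.frame(well = paste0("a", 1:3), group = "atrial", dose = 1,
               metric = "apd80", value = c(1, 2, 3)),
    data.frame(well = paste0("v", 1:3), group = "ventricular", dose = 1,
               metric = "apd80", value = c(4, 5, 6)))
  out <- compare_groups(structure(rows, class = c("dose_response_table",
                                                  "data.frame")),
                        dose = 1, metric = "apd80", on = "value")
  expect_equal(out$statistic, -3.674, tolerance = 1e-3)
  expect_equal(out$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(out$stars, "*")
  # identical samples: t = 0, p = 1
  rows$value <- rep(c(1, 2, 3), 2)
  out0 <- compare_groups(structure(rows, class = c("dose_response_table",
                                                   "data.frame")),
                         dose = 1, metric = "apd80", on = "value")
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
})

test_that("Dunnett critical value matches the equicorrelated integral and reduces to t for k = 1", {
  expect_equal(dunnett_crit(1, 10), qt(0.975, 10))
  # textbook-scale check, also verified against a 1e6-draw Monte-Carlo
  # oracle in the acceptance suite
  expect_equal(dunnett_crit(4, 20), 2.651, tolerance = 1e-3)
  expect_equal(dunnett_crit(2, 30), 2.3215, tolerance = 3e-3)
})

test_that("Dunnett adjusted p exceeds the raw p and grows with the family size", {
  set.seed(31)
  g <- factor(rep(0:3, each = 5))
  y <- rnorm(20) + 0.8 * (g == "2")
  dn <- dunnett_test(y, g, control = "0")
  for (i in seq_len(nrow(dn))) {
    raw <- 2 * pt(-abs(dn$statistic[i]), dn$df[i])
    expect_gte(dn$p_adj[i] + 1e-9, raw)
  }
  # same contrast embedded in a larger family is adjusted at least as hard
  p_k2 <- cardiomap:::dunnett_adj_p(2.1, k = 2, df = 20)
  p_k4 <- cardiomap:::dunnett_adj_p(2.1, k = 4, df = 20)
  p_k6 <- cardiomap:::dunnett_adj_p(2.1, k = 6, df = 20)
  expect_true(p_k2 < p_k4 && p_k4 < p_k6)
})

test_that("k = 1 Dunnett equals the unpaired two-sided t test", {
  set.seed(5)
  y <- c(rnorm(6), rnorm(6) + 1)
  g <- factor(rep(c("0", "1"), each = 6))
  dn <- dunnett_test(y, g, control = "0")
  tt <- t.test(y[g == "1"], y[g == "0"], var.equal = TRUE)
  expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(abs(dn$statistic), abs(unname(tt$statistic)), tolerance = 1e-9)
})

test_that("dose trend on identical dose groups gives F = 0 and adjusted p = 1", {
  tab <- make_table(list(`0` = c(10, 11, 12, 13),
                         `1` = c(10, 11, 12, 13),
                         `3` = c(10, 11, 12, 13)))
  tr <- dose_trend(tab, "atrial", "apd80", on = "value")
  expect_equal(tr$anova$F, 0)
  expect_true(all(tr$dunnett$p_adj > 0.999))
})

test_that("a simulated atrial-selective screen shows the expected report structure", {
  drug <- drug_model("atrial-selective",
    list(list(param = "apd", emax = 1.0, ec50 = 10, group = "atrial"),
         list(param = "apd", emax = 0.3, ec50 = 10, group = "ventricular")))
  tab <- simulate_screen(drug, doses = c(3, 10, 30, 100), seed = 21)
  rep <- assemble_screen_report(list(drug = tab))
  s <- rep$summaries
  # atrial mean percent change exceeds ventricular at every nonzero dose
  for (dz in c(3, 10, 30, 100)) {
    a <- s$mean_pct[s$dose == dz & s$group == "atrial" & s$metric == "apd80"]
    v <- s$mean_pct[s$dose == dz & s$group == "ventricular" &
                      s$metric == "apd80"]
    expect_gt(a, v)
  }
  # the separation is starred at the saturating doses
  b <- rep$between_group
  expect_true(all(b$stars[b$metric == "apd80" & b$dose >= 10] != ""))
  expect_error(assemble_screen_report(list()), "empty")
})

test_that("sign and ordering of recovered effects match the generator truth", {
  drug <- drug_model("mixed",
    list(list(param = "apd", emax = 0.6, ec50 = 10),
         list(param = "catd", emax = -0.3, ec50 = 10)))
  tab <- simulate_screen(drug, doses = c(3, 10, 30, 100), seed = 9)
  truth <- attr(tab, "truth")$atrial
  s <- summarize_groups(tab)
  noise_sem <- 5  # percent; well_cv/meas_cv defaults
  for (m in c("apd80", "catd80")) {
    for (dz in c(10, 30, 100)) {
      true_pct <- 100 * (truth[as.character(dz), m] - 1)
      if (abs(true_pct) > 2 * noise_sem) {
        got <- s$mean_pct[s$dose == dz & s$group == "atrial" & s$metric == m]
        expect_equal(sign(got), sign(true_pct))
      }
    }
  }
})

test_that("drugs without a baseline are excluded with a diagnostic", {
  tab <- make_table(list(`0` = c(1, 2, 3), `1` = c(2, 3, 4)))
  nb <- tab[tab$dose != 0, ]
  rep <- assemble_screen_report(list(good = tab, broken = nb))
  expect_equal(rep$excluded, "broken")
})
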