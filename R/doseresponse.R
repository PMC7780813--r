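#' Percent change from predrug baseline
#'
#' `100 * (post - pre) / pre`, signed: prolongation positive, shortening
#' negative.
#'
#' @param pre predrug baseline value (> 0).
#' @param post post-drug value.
#' @return percent change (vectorized).
#' @examples
#' percent_change(182, 355)  # +95.05
#' @export
percent_change <- function(pre, post) {
  if (any(pre <= 0)) stop("baseline value must be > 0")
  100 * (post - pre) / pre
}

#' Assemble a dose-response table
#'
#' Takes per-well raw metric values across the dosing schedule and adds
#' the percent change from each well's own predrug (dose 0) baseline.
#' Every well must have exactly one baseline record per metric.
#'
#' @param data data.frame with columns `well`, `group`, `dose`, `metric`,
#'   `value`.
#' @return The table (class `dose_response_table`) with a `pct_change`
#'   column; baseline rows have `pct_change = 0` identically.
#' @export
dose_response_table <- function(data) {
  need <- c("well", "group", "dose", "metric", "value")
  if (!all(need %in% names(data)))
    stop("need columns: ", paste(need, collapse = ", "))
  data <- as.data.frame(data)
  key <- interaction(data$well, data$metric, drop = TRUE)
  data$pct_change <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    base <- data$value[sel & data$dose == 0]
    if (length(base) != 1)
      stop("well/metric ", k, " needs exactly one baseline (dose 0) record, ",
           "found ", length(base))
    data$pct_change[sel] <- percent_change(base, data$value[sel])
  }
  class(data) <- c("dose_response_table", "data.frame")
  data
}

#' Group summaries (mean, SEM, n)
#'
#' Per (group, dose, metric): mean, standard error of the mean and n for
#' both the raw values and the per-well percent changes. Percent changes
#' are computed per well first and then averaged across wells, so the SEM
#' describes well-to-well variability.
#'
#' @param table a [dose_response_table()].
#' @return data.frame with `group, dose, metric, n, mean_value, sem_value,
#'   mean_pct, sem_pct`. SEM is `NA` when n = 1.
#' @export
summarize_groups <- function(table) {
  sp <- split(table, interaction(table$group, table$dose, table$metric,
                                 drop = TRUE))
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- sum(!is.na(d$value))
    sem <- function(x) if (n >= 2) stats::sd(x, na.rm = TRUE) / sqrt(n) else NA_real_
    data.frame(group = d$group[1], dose = d$dose[1], metric = d$metric[1],
               n = n,
               mean_value = mean(d$value, na.rm = TRUE),
               sem_value = sem(d$value),
               mean_pct = mean(d$pct_change, na.rm = TRUE),
               sem_pct = sem(d$pct_change))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$dose, out$group), ]
}

#' Between-group comparison at one dose
#'
#' Two-sample t test (Welch by default, pooled-variance Student by flag)
#' of the per-well percent changes of the two groups at one dose and
#' metric; significance stars at .05 / .01 / .001.
#'
#' @param table a [dose_response_table()].
#' @param dose,metric the cell to compare.
#' @param var_equal `TRUE` for the pooled-variance Student variant.
#' @param on `"pct_change"` (default) or `"value"`.
#' @return data.frame row: `dose, metric, statistic, df, p_value, stars`,
#'   plus the group means. `NA` statistics (with a diagnostic attribute)
#'   when either group has n < 2.
#' @export
compare_groups <- function(table, dose, metric, var_equal = FALSE,
                           on = c("pct_change", "value")) {
  on <- match.arg(on)
  d <- table[table$dose == dose & table$metric == metric & !is.na(table[[on]]), ]
  gs <- unique(d$group)
  if (length(gs) != 2) stop("need exactly two groups at this dose, found ",
                            length(gs))
  x <- d[[on]][d$group == gs[1]]
  y <- d[[on]][d$group == gs[2]]
  if (length(x) < 2 || length(y) < 2) {
    out <- data.frame(dose = dose, metric = metric, statistic = NA_real_,
                      df = NA_real_, p_value = NA_real_, stars = "",
                      mean_1 = mean(x), mean_2 = mean(y))
    attr(out, "diagnostic") <- "insufficient n (need >= 2 per group)"
    return(out)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  data.frame(dose = dose, metric = metric,
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stars = star_string(tt$p.value),
             mean_1 = mean(x), mean_2 = mean(y))
}

#' Within-group dose trend: one-way ANOVA + Dunnett
#'
#' For one group and metric, tests the dose-dependence of the response:
#' one-way ANOVA F across dose levels (baseline included), then Dunnett
#' many-to-one comparisons of every dose against the predrug baseline with
#' familywise-adjusted p values ([dunnett_test()]). On the percent-change
#' scale the baseline group is identically 0 (see the methods vignette for
#' the calibration consequences); raw values are available via `on`.
#'
#' @param table a [dose_response_table()].
#' @param group,metric the stratum to analyze.
#' @param on `"pct_change"` (default) or `"value"`.
#' @param alpha familywise level for the reported critical value.
#' @return list with `anova` (data.frame: F, df, p) and `dunnett`
#'   (data.frame from [dunnett_test()] with a `dose` column). Dose levels
#'   with n < 2 are skipped with a diagnostic.
#' @export
dose_trend <- function(table, group, metric, on = c("pct_change", "value"),
                       alpha = 0.05) {
  on <- match.arg(on)
  d <- table[table$group == group & table$metric == metric &
               !is.na(table[[on]]), ]
  if (!any(d$dose == 0)) stop("no baseline (dose 0) records for group ", group)
  ns <- base::table(d$dose)
  skipped <- names(ns)[ns < 2]
  if (length(skipped))
    d <- d[!d$dose %in% as.numeric(skipped), ]
  doses <- sort(unique(d$dose))
  if (length(doses) < 2)
    stop("need baseline plus at least one dose with n >= 2")
  fdose <- factor(d$dose, levels = doses)
  av <- stats::anova(stats::aov(d[[on]] ~ fdose))
  an <- data.frame(F = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
                   p_value = av$`Pr(>F)`[1])
  dn <- dunnett_test(d[[on]], fdose, control = as.character(doses[1]),
                     alpha = alpha)
  dn$dose <- as.numeric(sub(" -.*$", "", dn$comparison))
  out <- list(anova = an, dunnett = dn, on = on,
              skipped_doses = as.numeric(skipped))
  class(out) <- "dose_trend"
  out
}

#' @export
print.dose_trend <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  print(x$dunnett[, c("comparison", "estimate", "statistic", "p_adj", "stars")],
        row.names = FALSE)
  invisible(x)
}

#' Assemble a multi-drug screen report
#'
#' Per drug: baseline values, per-dose raw and percent-change group
#' summaries, between-group comparison stars at each dose, and
#' within-group Dunnett stars versus baseline. Drugs lacking a baseline
#' are excluded with a diagnostic.
#'
#' @param tables named list of [dose_response_table()]s, one per drug.
#' @param metrics metrics to report; default: all present.
#' @return Object of class `screen_report`: list with `summaries`
#'   (long data.frame), `between_group` (data.frame of t tests),
#'   `dose_trends` (data.frame of Dunnett rows), `excluded` (character).
#' @export
assemble_screen_report <- function(tables, metrics = NULL) {
  if (!length(tables)) stop("empty drug table list")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (one entry per drug)")
  summaries <- list(); between <- list(); trends <- list(); excluded <- character(0)
  for (drug in names(tables)) {
    tab <- tables[[drug]]
    if (!any(tab$dose == 0)) {
      excluded <- c(excluded, drug)
      next
    }
    mets <- metrics %||% unique(tab$metric)
    s <- summarize_groups(tab[tab$metric %in% mets, ])
    s$drug <- drug
    summaries[[drug]] <- s
    doses <- sort(setdiff(unique(tab$dose), 0))
    for (m in mets) {
      for (dz in doses) {
        bg <- tryCatch(compare_groups(tab, dz, m), error = function(e) NULL)
        if (!is.null(bg)) { bg$drug <- drug; between[[paste(drug, m, dz)]] <- bg }
      }
      for (g in unique(tab$group)) {
        tr <- tryCatch(dose_trend(tab, g, m), error = function(e) NULL)
        if (!is.null(tr)) {
          dd <- tr$dunnett
          dd$drug <- drug; dd$group <- g; dd$metric <- m
          dd$anova_F <- tr$anova$F; dd$anova_p <- tr$anova$p_value
          trends[[paste(drug, g, m)]] <- dd
        }
      }
    }
  }
  if (!length(summaries)) stop("no drug had a usable baseline")
  structure(list(summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 between_group = do.call(rbind, c(between, make.row.names = FALSE)),
                 dose_trends = do.call(rbind, c(trends, make.row.names = FALSE)),
                 excluded = excluded),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  drugs <- unique(x$summaries$drug)
  cat("<screen_report>", length(drugs), "drug(s):",
      paste(drugs, collapse = ", "), "\n")
  for (drug in drugs) {
    cat("\n==", drug, "==\n")
    s <- x$summaries[x$summaries$drug == drug & x$summaries$dose != 0, ]
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-12s %-6s dose %-8g %+6.1f%% +/- %4.1f%% (n=%d)\n",
                  s$metric[i], as.character(s$group[i]), s$dose[i],
                  s$mean_pct[i], s$sem_pct[i], s$n[i]))
    b <- x$between_group[x$between_group$drug == drug & x$between_group$stars != "", ]
    if (nrow(b))
      cat("  between-group differences:",
          paste(sprintf("%s@%g%s", b$metric, b$dose, b$stars), collapse = " "),
          "\n")
  }
  if (length(x$excluded))
    cat("excluded (no baseline):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a well-level drug screen
#'
#' Generates per-well metric values for a sequential-dose screen of an
#' atrial and a ventricular cohort: each well draws a lognormal baseline
#' around the cell-type preset's true metric values (well-to-well
#' coefficient of variation `well_cv`), each dose scales the targeted
#' metrics by the drug's Hill factor, and every recorded value carries
#' multiplicative measurement noise (`meas_cv`). Used for statistical
#' validation of the dose-response stage; the trace-level route
#' ([run_pipeline()]) exercises the same statistics end-to-end.
#'
#' @param drug a [drug_model()]; effect entries targeting `"apd"` scale
#'   the APD metrics, `"catd"` the CaTD metrics, `"cat_ttp"` the TTP and
#'   `"cat_decay_tau"` the decay tau.
#' @param doses dose levels (baseline 0 is added automatically).
#' @param n_wells wells per cohort.
#' @param well_cv,meas_cv lognormal coefficients of variation.
#' @param metrics metric names to simulate.
#' @param seed RNG seed.
#' @return A [dose_response_table()] with a `truth` attribute holding the
#'   true per-dose scaling factors per metric.
#' @export
simulate_screen <- function(drug, doses = c(1, 3, 10, 30), n_wells = 6,
                            well_cv = 0.08, meas_cv = 0.05,
                            metrics = c("apd20", "apd50", "apd80",
                                        "catd20", "catd50", "catd80"),
                            seed = 1L) {
  stopifnot(inherits(drug, "drug_model"))
  base_truth <- function(label) {
    ap <- measure_ap_dense(cell_preset(label))
    ca <- measure_cat_dense(cell_preset(label))
    c(apd20 = ap$apd20, apd50 = ap$apd50, apd80 = ap$apd80, apd90 = ap$apd90,
      catd20 = ca$catd20, catd50 = ca$catd50, catd80 = ca$catd80,
      ttp = ca$ttp, tau = cell_preset(label)$cat_decay_tau)
  }
  metric_groups <- list(apd = c("apd20", "apd50", "apd80", "apd90"),
                        catd = c("catd20", "catd50", "catd80"),
                        cat_ttp = "ttp", cat_decay_tau = "tau",
                        ap_repol_tau = c("apd20", "apd50", "apd80", "apd90"),
                        ap_plateau_dur = c("apd20", "apd50", "apd80", "apd90"))
  scale_for <- function(metric, dose, group) {
    f <- 1
    for (e in drug$effects) {
      if (!is.null(e$group) && e$group != group) next
      targets <- metric_groups[[e$param]] %||% character(0)
      if (metric %in% targets) {
        n <- e$hill_n %||% 1
        f <- f * (1 + e$emax * dose^n / (dose^n + e$ec50^n))
      }
    }
    f
  }
  all_doses <- c(0, sort(doses))
  truth <- lapply(c(atrial = "atrial", ventricular = "ventricular"),
                  function(g) {
                    tr <- sapply(metrics, function(m)
                      sapply(all_doses, scale_for, metric = m, group = g))
                    rownames(tr) <- all_doses
                    tr
                  })
  rows <- with_seed(seed, {
    out <- list()
    for (g in c("atrial", "ventricular")) {
      bt <- base_truth(g)
      for (wl in seq_len(n_wells)) {
        wf <- exp(stats::rnorm(length(metrics), 0, well_cv))
        names(wf) <- metrics
        for (dz in all_doses) {
          mf <- exp(stats::rnorm(length(metrics), 0, meas_cv))
          names(mf) <- metrics
          for (m in metrics) {
            out[[length(out) + 1L]] <- data.frame(
              well = paste0(substr(g, 1, 1), wl), group = g, dose = dz,
              metric = m,
              value = bt[[m]] * wf[[m]] * scale_for(m, dz, g) * mf[[m]])
          }
        }
      }
    }
    out
  })
  tab <- dose_response_table(do.call(rbind, rows))
  attr(tab, "truth") <- truth
  tab
}
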