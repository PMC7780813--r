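# Dunnett many-to-one comparisons against a shared control, built on the
# multivariate-t representation of the joint null of the k contrast
# t-statistics: correlation rho_ij = sqrt(lambda_i * lambda_j) with
# lambda_i = n_i / (n_i + n0), which is the equicorrelated 1/2 case for
# balanced designs. Tail probabilities and equicoordinate quantiles are
# evaluated by numerical integration (mvtnorm); the integration uses a
# fixed internal seed so results are reproducible to ~1e-4.

dunnett_corr <- function(n_control, n_groups) {
  lam <- sqrt(n_groups / (n_groups + n_control))
  R <- outer(lam, lam)
  diag(R) <- 1
  R
}

# critical values are design constants: memoise per (k, df, alpha, sizes)
.dunnett_cache <- new.env(parent = emptyenv())

#' Dunnett two-sided critical value
#'
#' Equicoordinate critical value `q` such that
#' `P(max_i |T_i| <= q) = 1 - alpha` under the joint null of the `k`
#' treatment-vs-control t statistics with `df` error degrees of freedom.
#' Balanced designs give the classical equicorrelation 1/2.
#'
#' @param k number of treatment groups compared to the control.
#' @param df error degrees of freedom of the pooled variance.
#' @param alpha familywise two-sided level.
#' @param n_control,n_groups group sizes for unbalanced designs (defaults
#'   give equicorrelation 1/2).
#' @return The critical value (numeric scalar).
#' @examples
#' dunnett_crit(k = 4, df = 20)  # ~ 2.65
#' @export
dunnett_crit <- function(k, df, alpha = 0.05,
                         n_control = NULL, n_groups = NULL) {
  stopifnot(k >= 1, df > 0)
  key <- paste("crit", k, df, alpha, paste(n_control, collapse = "_"),
               paste(n_groups, collapse = "_"), sep = "|")
  hit <- .dunnett_cache[[key]]
  if (!is.null(hit)) return(hit)
  R <- if (is.null(n_control)) {
    m <- matrix(0.5, k, k); diag(m) <- 1; m
  } else dunnett_corr(n_control, n_groups)
  out <- if (k == 1) stats::qt(1 - alpha / 2, df) else
    with_seed(290873L,
      mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df, corr = R,
                    algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                   maxpts = 100000))$quantile)
  .dunnett_cache[[key]] <- out
  out
}

# Familywise-adjusted two-sided p for one contrast statistic t0 among k
# correlated contrasts: P(max_i |T_i| >= |t0|) under the joint null.
dunnett_adj_p <- function(t0, k, df, n_control = NULL, n_groups = NULL) {
  if (is.na(t0)) return(NA_real_)
  R <- if (is.null(n_control)) {
    m <- matrix(0.5, k, k); diag(m) <- 1; m
  } else dunnett_corr(n_control, n_groups)
  if (k == 1) return(2 * stats::pt(-abs(t0), df))
  p_in <- with_seed(290873L,
    mvtnorm::pmvt(lower = rep(-abs(t0), k), upper = rep(abs(t0), k),
                  df = as.integer(round(df)), corr = R,
                  algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                 maxpts = 25000)))
  min(max(1 - as.numeric(p_in), 0), 1)
}

#' Dunnett many-to-one test
#'
#' One-way layout: compares every treatment level of `group` against the
#' `control` level using the pooled-variance t statistics and
#' familywise-adjusted p values from the equicorrelated multivariate-t
#' distribution.
#'
#' @param values numeric response vector.
#' @param group factor (or coercible) of group labels.
#' @param control the control level (default: first level).
#' @param alpha familywise level used for the reported critical value.
#' @return data.frame with one row per comparison: `comparison`,
#'   `estimate`, `se`, `statistic`, `df`, `p_adj`, `crit`, `stars`.
#' @examples
#' set.seed(1)
#' g <- rep(c("ctl", "d1", "d2"), each = 5)
#' dunnett_test(rnorm(15) + (g == "d2"), g, control = "ctl")
#' @export
dunnett_test <- function(values, group, control = NULL, alpha = 0.05) {
  group <- factor(group)
  if (is.null(control)) control <- levels(group)[1]
  if (!control %in% levels(group)) stop("control level not found: ", control)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  ns <- table(group)
  if (any(ns < 2)) stop("every group needs n >= 2")
  trt <- setdiff(levels(group), control)
  k <- length(trt)
  if (k < 1) stop("no treatment groups to compare")
  N <- length(values)
  means <- tapply(values, group, mean)
  s2 <- sum(tapply(values, group, function(x) sum((x - mean(x))^2))) /
    (N - k - 1)
  df <- N - k - 1
  n0 <- ns[[control]]
  ng <- as.numeric(ns[trt])
  est <- means[trt] - means[[control]]
  se <- sqrt(s2 * (1 / ng + 1 / n0))
  tstat <- est / se
  balanced <- length(unique(c(n0, ng))) == 1
  p_adj <- vapply(tstat, function(tt)
    if (balanced) dunnett_adj_p(tt, k, df)
    else dunnett_adj_p(tt, k, df, n_control = n0, n_groups = ng), 0)
  crit <- if (balanced) dunnett_crit(k, df, alpha)
          else dunnett_crit(k, df, alpha, n_control = n0, n_groups = ng)
  data.frame(comparison = paste(trt, "-", control),
             estimate = as.numeric(est), se = as.numeric(se),
             statistic = as.numeric(tstat), df = df,
             p_adj = p_adj, crit = crit, stars = star_string(p_adj),
             row.names = NULL)
}

# significance stars: * <.05, ** <.01, *** <.001
star_string <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("")
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*" else ""
  }, "")
}
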