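#' Diastolic-interval / APD80 pairs from a ramp recording
#'
#' Builds the dynamic-restitution point cloud: for consecutive analyzed
#' beats, `DI_n = activation_n - (activation_(n-1) + APD80_(n-1))` (the
#' recovery time between the end of one action potential, taken at APD80,
#' and the next activation) paired with `APD80_n`. The first
#' `discard_per_step` beats of each ramp step are treated as non-steady
#' and dropped; beats with undefined APD80 are dropped and counted.
#'
#' @param metrics a [beat_metrics()] table from a ramp recording.
#' @param protocol the [pacing_protocol] used (must be `ramp` mode, or an
#'   explicit stimulus list).
#' @param discard_per_step leading beats of each rate step to drop;
#'   default from the protocol.
#' @return data.frame with `di`, `apd80`, `beat`; attribute `n_dropped`
#'   counts beats lost to undefined APD80 or non-positive DI.
#' @export
compute_di <- function(metrics, protocol, discard_per_step = NULL) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  if (protocol$mode == "fixed")
    stop("restitution needs a variable-rate (ramp) recording; ",
         "for fixed-rate metrics use the beats module directly")
  discard_per_step <- discard_per_step %||% protocol$discard_per_step
  ok <- metrics$captured & !metrics$truncated & !is.na(metrics$apd80) &
    !is.na(metrics$activation_time)
  m <- metrics[ok, ]
  m <- m[order(m$activation_time), ]
  if (nrow(m) < 2) {
    out <- data.frame(di = numeric(0), apd80 = numeric(0), beat = integer(0))
    attr(out, "n_dropped") <- sum(!ok)
    return(out)
  }
  di <- m$activation_time[-1] -
    (m$activation_time[-nrow(m)] + m$apd80[-nrow(m)])
  pts <- data.frame(di = di, apd80 = m$apd80[-1], beat = m$beat[-1])
  # a pair is only a true diastolic interval if no *captured* beat fell
  # between its two beats (a failed stimulus is genuine diastole; a
  # captured beat whose APD80 was unmeasurable is not)
  cap <- metrics$beat[metrics$captured]
  b_lo <- m$beat[-nrow(m)]; b_hi <- m$beat[-1]
  ok_pair <- vapply(seq_along(b_lo), function(i)
    !any(cap > b_lo[i] & cap < b_hi[i]), TRUE)
  pts <- pts[ok_pair, ]
  # discard non-steady leading beats of each ramp step
  if (protocol$mode == "ramp" && is.null(protocol$stimulus_times)) {
    st <- stimulus_times(protocol)
    bis <- attr(st, "beat_in_step")
    bin <- bis[match(m$stim_time[-1], st)]
    keep <- is.na(bin) | bin > discard_per_step
    pts <- pts[keep, ]
  }
  bad <- pts$di <= 0
  pts <- pts[!bad, ]
  attr(pts, "n_dropped") <- sum(!ok) + sum(bad)
  pts
}

#' Fit an electrical restitution curve
#'
#' Least-squares fit of the saturating monoexponential
#' `APD80(DI) = a - b * exp(-DI / c)` to the (DI, APD80) points, with the
#' maximum slope `(b/c) * exp(-DI_min / c)` evaluated at the smallest
#' retained diastolic interval (the steep end of the curve). When the
#' parametric fit fails or misfits (RMSE above `rmse_threshold`), the
#' maximum slope falls back to the steepest local linear regression over a
#' sliding window of `fallback_window` DI-sorted points.
#'
#' @param points data.frame with `di` and `apd80` (from [compute_di()]),
#'   at least 5 points spanning at least 100 ms of DI.
#' @param rmse_threshold ms; above this the fallback slope is used.
#' @param fallback_window points per local regression window.
#' @return Object of class `restitution_fit`: list with `points`,
#'   `coefficients` (a, b, c), `max_slope`, `di_min`, `fit_rmse`,
#'   `method` (`"exponential"` or `"local"`), `converged`.
#' @examples
#' di <- seq(60, 600, by = 20)
#' pts <- data.frame(di = di, apd80 = 300 - 150 * exp(-di / 100))
#' fit <- fit_restitution(pts)
#' coef(fit); fit$max_slope
#' @export
fit_restitution <- function(points, rmse_threshold = 8, fallback_window = 5) {
  pts <- points[!is.na(points$di) & !is.na(points$apd80), ]
  if (nrow(pts) < 5) stop("restitution fit needs at least 5 points")
  if (diff(range(pts$di)) < 100)
    stop("restitution fit needs points spanning at least 100 ms of DI")
  di_min <- min(pts$di)

  flat <- stats::var(pts$apd80) < 1  # < 1 ms^2: flat curve, slope ~ 0
  fit <- NULL
  if (!flat) {
    a0 <- max(pts$apd80)
    b0 <- max(a0 - min(pts$apd80), 1)
    c0 <- max(diff(range(pts$di)) / 3, 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(apd80 ~ a - b * exp(-di / c), data = pts,
                        start = list(a = a0, b = b0, c = c0),
                        lower = c(a = 0, b = 0, c = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  local_slope <- function() {
    o <- pts[order(pts$di), ]
    n <- nrow(o); wlen <- min(fallback_window, n)
    slopes <- vapply(seq_len(n - wlen + 1), function(i) {
      w <- o[i:(i + wlen - 1), ]
      if (diff(range(w$di)) < 1e-9) return(NA_real_)
      stats::coef(stats::lm(apd80 ~ di, data = w))[2]
    }, 0)
    smax <- suppressWarnings(max(slopes, na.rm = TRUE))
    if (!is.finite(smax)) NA_real_ else max(smax, 0)
  }

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (rmse <= rmse_threshold) {
      slope <- (cf[["b"]] / cf[["c"]]) * exp(-di_min / cf[["c"]])
      return(structure(list(points = pts, coefficients = cf,
                            max_slope = slope, di_min = di_min,
                            fit_rmse = rmse, method = "exponential",
                            converged = TRUE),
                       class = "restitution_fit"))
    }
    slope <- local_slope()
    return(structure(list(points = pts, coefficients = cf, max_slope = slope,
                          di_min = di_min, fit_rmse = rmse,
                          method = "local", converged = TRUE),
                     class = "restitution_fit"))
  }
  slope <- if (flat) max(local_slope(), 0) else local_slope()
  if (flat && is.na(slope)) slope <- 0
  structure(list(points = pts,
                 coefficients = c(a = mean(pts$apd80), b = 0, c = NA_real_),
                 max_slope = slope, di_min = di_min,
                 fit_rmse = stats::sd(pts$apd80), method = "local",
                 converged = FALSE),
            class = "restitution_fit")
}

#' @export
print.restitution_fit <- function(x, ...) {
  cat("<restitution_fit>", nrow(x$points), "points, method:", x$method, "\n")
  if (x$converged && x$method == "exponential")
    cat(sprintf("  APD80(DI) = %.1f - %.1f * exp(-DI / %.1f) ms, RMSE %.2f ms\n",
                x$coefficients[["a"]], x$coefficients[["b"]],
                x$coefficients[["c"]], x$fit_rmse))
  cat(sprintf("  max slope %.3f at DI = %.1f ms\n",
              x$max_slope, x$di_min))
  invisible(x)
}

#' @export
coef.restitution_fit <- function(object, ...) object$coefficients

#' @export
predict.restitution_fit <- function(object, newdata = NULL, ...) {
  di <- if (is.null(newdata)) object$points$di else newdata$di
  cf <- object$coefficients
  if (any(is.na(cf))) return(rep(cf[["a"]], length(di)))
  cf[["a"]] - cf[["b"]] * exp(-di / cf[["c"]])
}

#' @export
residuals.restitution_fit <- function(object, ...) {
  object$points$apd80 - predict(object)
}

#' @export
plot.restitution_fit <- function(x, ...) {
  graphics::plot(x$points$di, x$points$apd80, xlab = "DI (ms)",
                 ylab = "APD80 (ms)", ...)
  o <- order(x$points$di)
  graphics::lines(x$points$di[o], predict(x)[o], col = 2)
  invisible(x)
}
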