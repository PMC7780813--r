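#' Remove slow baseline drift
#'
#' Default method tracks the diastolic baseline with a rolling low
#' percentile (20th) over a window that should span at least two beats,
#' and subtracts it; this is robust to beat shape and removes the linear
#' photobleaching-like drift the generator emulates. A global polynomial
#' baseline (order 2 by default) is available as an alternative; it is
#' re-anchored to the diastolic level so diastole sits near 0 afterwards.
#'
#' @param trace an [om_trace].
#' @param method `"percentile"` or `"polynomial"`.
#' @param window_ms rolling-window length in ms (percentile method).
#' @param prob percentile tracked as baseline.
#' @param order polynomial order (polynomial method).
#' @param cycle_length optional pacing cycle length in ms; when given, a
#'   window shorter than one beat is an error and the default window is
#'   two cycle lengths.
#' @return The detrended [om_trace] (diastole near 0).
#' @export
detrend <- function(trace, method = c("percentile", "polynomial"),
                    window_ms = NULL, prob = 0.2, order = 2,
                    cycle_length = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "om_trace"))
  v <- trace$values
  if (method == "percentile") {
    if (is.null(window_ms))
      window_ms <- if (!is.null(cycle_length)) 2 * cycle_length else 2000
    if (!is.null(cycle_length) && window_ms < cycle_length)
      stop("detrend window (", window_ms, " ms) is shorter than one beat (",
           cycle_length, " ms)")
    w <- round(window_ms / trace_dt(trace))
    if (w < 3) stop("detrend window must span at least 3 samples")
    w <- min(w, length(v))
    # rolling low percentile tracks the diastolic floor; a robust
    # (Theil-Sen) straight line through it captures the slow linear
    # drift without warping beat-scale structure, and shrugs off the
    # floor dipping at the quiet start/end of a recording. Only tilt
    # matters downstream: per-beat baselines absorb any constant offset.
    base <- as.numeric(zoo::rollapply(zoo::zoo(v), width = w,
                                      FUN = stats::quantile, probs = prob,
                                      names = FALSE, align = "center"))
    n_lead <- (w - 1L) %/% 2L
    tc <- trace$time[n_lead + seq_along(base)]
    if (length(base) > 400) {  # thin deterministically: pairwise slopes are O(n^2)
      idx <- unique(round(seq(1, length(base), length.out = 400)))
      base_f <- base[idx]; tc_f <- tc[idx]
    } else { base_f <- base; tc_f <- tc }
    if (length(base_f) < 2) {
      slope <- 0
    } else {
      dslope <- outer(base_f, base_f, "-") / outer(tc_f, tc_f, "-")
      slope <- stats::median(dslope[upper.tri(dslope)], na.rm = TRUE)
      if (!is.finite(slope)) slope <- 0
    }
    intercept <- stats::median(base_f - slope * tc_f)
    resid <- v - (intercept + slope * trace$time)
    # re-anchor: diastole sits at the tracked percentile, so subtract it
    trace$values <- resid - stats::quantile(resid, prob, names = FALSE)
  } else {
    fit <- stats::lm(v ~ stats::poly(trace$time, order))
    resid <- v - stats::fitted(fit)
    trace$values <- resid - stats::quantile(resid, prob, names = FALSE)
  }
  trace
}

#' Orient and normalize a trace
#'
#' Makes the depolarization / Ca-rise positive-going and rescales the
#' trace to approximately `[0, 1]` using robust (1st/99th percentile)
#' extremes, so the result is invariant to positive affine transforms of
#' the raw counts. With `polarity = "auto"` the orientation is decided by
#' the skewness of the first difference: an upright transient produces a
#' few large positive increments (steep upstroke) and many small negative
#' ones, so negative skewness flags an inverted trace.
#'
#' @param trace an [om_trace].
#' @param polarity `"auto"`, `"positive"` (leave as is), or `"inverted"`
#'   (flip).
#' @return The normalized [om_trace]; `meta$flipped` records the decision.
#' @export
normalize_and_orient <- function(trace,
                                 polarity = c("auto", "positive", "inverted")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(trace, "om_trace"))
  v <- trace$values
  if (diff(range(v)) == 0) stop("cannot normalize a constant trace")
  flip <- switch(polarity,
    positive = FALSE,
    inverted = TRUE,
    auto = {
      d <- diff(v)
      s <- stats::sd(d)
      if (s == 0) FALSE else mean(((d - mean(d)) / s)^3) < 0
    })
  if (flip) v <- -v
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q <- range(v)
  trace$values <- (v - q[1]) / (q[2] - q[1])
  trace$meta$flipped <- flip
  trace
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; the default 5-sample cubic
#' window attenuates the upstroke by well under 5% at 100 frames/s while
#' contracting white noise.
#'
#' @param trace an [om_trace].
#' @param window_ms window length in ms (rounded to an odd number of
#'   samples, minimum 3).
#' @param polyorder polynomial order; must be smaller than the window
#'   sample count.
#' @return The smoothed [om_trace].
#' @export
smooth_trace <- function(trace, window_ms = 50, polyorder = 3) {
  stopifnot(inherits(trace, "om_trace"))
  n <- round(window_ms / trace_dt(trace))
  if (n %% 2 == 0) n <- n + 1
  if (n < 3) stop("smoothing window must span at least 3 samples")
  if (polyorder >= n)
    stop("polyorder (", polyorder, ") must be smaller than the window (",
         n, " samples)")
  trace$values <- as.numeric(signal::sgolayfilt(trace$values, p = polyorder,
                                                n = n))
  trace
}

#' Full conditioning pipeline
#'
#' Detrend, orient/normalize, and optionally smooth, in that order: the
#' standard preparation of a raw ROI trace for beat analysis. Downstream
#' metrics are invariant to positive affine transforms of the input.
#'
#' @param trace an [om_trace].
#' @param polarity passed to [normalize_and_orient()].
#' @param detrend_method passed to [detrend()].
#' @param cycle_length optional pacing cycle length (ms) for the detrend
#'   window.
#' @param smooth `TRUE` to apply [smooth_trace()].
#' @param window_ms smoothing window, ms.
#' @return The conditioned [om_trace].
#' @export
condition_trace <- function(trace, polarity = "auto",
                            detrend_method = "percentile",
                            cycle_length = NULL, smooth = FALSE,
                            window_ms = 50) {
  tr <- detrend(trace, method = detrend_method, cycle_length = cycle_length)
  tr <- normalize_and_orient(tr, polarity)
  if (smooth) tr <- smooth_trace(tr, window_ms = window_ms)
  tr
}
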