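#' Movie geometry and acquisition spec
#'
#' Describes how dual-channel traces are rendered into (or read from) a
#' multi-page image stack. `interleaved` alternates voltage and calcium
#' frames (V, Ca, V, Ca, ...); `stacked` stores all voltage frames first.
#' `voltage_polarity = "inverted"` mirrors voltage-sensitive-dye recordings
#' in which depolarization darkens the image: the voltage signal is negated
#' about its baseline before digitization.
#'
#' @param height,width frame size in pixels.
#' @param frame_rate per-channel frame rate, frames/s.
#' @param channel_layout `"interleaved"` or `"stacked"`.
#' @param gain counts per unit signal (non-zero).
#' @param offset counts added to every pixel.
#' @param voltage_polarity `"positive"` or `"inverted"`.
#' @return An object of class `movie_spec`.
#' @export
movie_spec <- function(height = 32, width = 32, frame_rate = 100,
                       channel_layout = c("interleaved", "stacked"),
                       gain = 20000, offset = 2000,
                       voltage_polarity = c("inverted", "positive")) {
  channel_layout <- match.arg(channel_layout)
  voltage_polarity <- match.arg(voltage_polarity)
  stopifnot(height >= 1, width >= 1, frame_rate > 0)
  if (gain == 0) stop("gain must be non-zero")
  structure(list(height = height, width = width, frame_rate = frame_rate,
                 channel_layout = channel_layout, gain = gain,
                 offset = offset, voltage_polarity = voltage_polarity),
            class = "movie_spec")
}

#' Render paired traces into a synthetic dual-channel movie
#'
#' Every pixel of a frame carries `offset + gain * signal`, plus optional
#' per-pixel Gaussian noise and a linear baseline drift (both scaled by the
#' clean signal amplitude, see [noise_model()]). The voltage channel is
#' negated about its baseline when the spec declares inverted polarity.
#' The traces' ground-truth manifests travel with the movie.
#'
#' @param v_trace,ca_trace voltage and calcium [om_trace]s on the same time
#'   base, matching `spec$frame_rate`.
#' @param spec a [movie_spec].
#' @param noise a [noise_model], or `NULL` for a noiseless render.
#' @return An object of class `om_movie`: list with `frames` (array
#'   `height x width x 2n`, counts), `spec`, `frame_rate`, `manifest`.
#' @examples
#' pro <- pacing_protocol("fixed", rate_bpm = 60, n_beats = 2)
#' v <- generate_ap_trace(cell_preset("atrial"), pro, duration = 2000)
#' ca <- generate_cat_trace(cell_preset("atrial"), pro, duration = 2000)
#' mv <- render_movie(v, ca, movie_spec(height = 4, width = 4))
#' dim(mv$frames)
#' @export
render_movie <- function(v_trace, ca_trace, spec, noise = NULL) {
  stopifnot(inherits(v_trace, "om_trace"), inherits(ca_trace, "om_trace"),
            inherits(spec, "movie_spec"))
  if (length(v_trace$time) != length(ca_trace$time))
    stop("voltage and calcium traces have different lengths")
  if (abs(v_trace$frame_rate - spec$frame_rate) > 1e-6 ||
      abs(ca_trace$frame_rate - spec$frame_rate) > 1e-6)
    stop("trace frame rate does not match the movie spec")
  n <- length(v_trace$time)
  h <- spec$height; w <- spec$width

  vsig <- v_trace$values
  if (spec$voltage_polarity == "inverted")
    vsig <- max(vsig) + min(vsig) - vsig
  casig <- ca_trace$values

  build <- function(sig, seed_off) {
    amp <- diff(range(sig)); if (amp == 0) amp <- 1
    counts <- spec$offset + spec$gain * sig
    arr <- array(rep(counts, each = h * w), dim = c(h, w, n))
    if (!is.null(noise)) {
      drift <- noise$drift_slope * spec$gain * amp *
        (v_trace$time - v_trace$time[1]) / 1000
      arr <- arr + rep(drift, each = h * w)
      eps <- with_seed(noise$seed + seed_off,
                       stats::rnorm(h * w * n, 0,
                                    noise$gaussian_sd * spec$gain * amp))
      arr <- arr + array(eps, dim = c(h, w, n))
    }
    arr
  }
  va <- build(vsig, 0L)
  ca <- build(casig, 1L)

  frames <- array(0, dim = c(h, w, 2 * n))
  if (spec$channel_layout == "interleaved") {
    frames[, , seq(1, 2 * n, by = 2)] <- va
    frames[, , seq(2, 2 * n, by = 2)] <- ca
  } else {
    frames[, , 1:n] <- va
    frames[, , (n + 1):(2 * n)] <- ca
  }
  structure(list(frames = frames, spec = spec, frame_rate = spec$frame_rate,
                 manifest = list(voltage = v_trace$meta$manifest,
                                 calcium = ca_trace$meta$manifest,
                                 stimulus_times = v_trace$meta$stimulus_times)),
            class = "om_movie")
}

#' @export
print.om_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<om_movie> %dx%d px, %d frames (%s), %g frames/s per channel\n",
              d[1], d[2], d[3], x$spec$channel_layout, x$frame_rate))
  invisible(x)
}

#' Write a movie as 16-bit multi-page TIFF plus a sidecar manifest
#'
#' Counts are clipped to `[0, 65535]` and stored as unsigned 16-bit; the
#' channel layout, frame rate and digitization parameters go to a YAML
#' sidecar (`<path>.yml`) so the stack is self-describing.
#'
#' @param movie an [om_movie].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "om_movie"))
  d <- dim(movie$frames)
  pages <- lapply(seq_len(d[3]), function(i) {
    m <- movie$frames[, , i]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- list(channel_layout = movie$spec$channel_layout,
               frame_rate = movie$frame_rate,
               height = d[1], width = d[2], n_pages = d[3],
               gain = movie$spec$gain, offset = movie$spec$offset,
               voltage_polarity = movie$spec$voltage_polarity)
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Load a dual-channel movie from a multi-page stack
#'
#' Reads a multi-page TIFF and splits it into the two channel frame
#' sequences according to the declared layout. Layout metadata is taken
#' from the YAML sidecar written by [write_movie()] when present, or can
#' be passed explicitly.
#'
#' @param path TIFF path.
#' @param layout `"interleaved"` or `"stacked"`; default from the sidecar.
#' @param frame_rate per-channel frame rate, frames/s; default from the
#'   sidecar.
#' @param split_index for `stacked` layout, the number of leading frames
#'   belonging to the voltage channel (default: half the stack).
#' @return list with `voltage` and `calcium` (arrays `h x w x n`, counts),
#'   `frame_rate`, and the sidecar metadata under `info`.
#' @export
load_movie <- function(path, layout = NULL, frame_rate = NULL,
                       split_index = NULL) {
  side_path <- paste0(path, ".yml")
  info <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  layout <- layout %||% info$channel_layout
  frame_rate <- frame_rate %||% info$frame_rate
  if (is.null(layout)) stop("channel layout not declared (no sidecar, no argument)")
  if (!layout %in% c("interleaved", "stacked"))
    stop("unknown channel layout: ", layout)
  if (is.null(frame_rate)) stop("frame rate not declared")
  pages <- tiff::readTIFF(path, all = TRUE)
  n_all <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  stack <- array(unlist(pages, use.names = FALSE) * 65535,
                 dim = c(h, w, n_all))
  if (layout == "interleaved") {
    if (n_all %% 2L != 0L)
      stop("interleaved stack has an odd frame count: ", n_all)
    v <- stack[, , seq(1, n_all, by = 2), drop = FALSE]
    ca <- stack[, , seq(2, n_all, by = 2), drop = FALSE]
  } else {
    si <- split_index %||% (n_all %/% 2L)
    if (si < 1 || si >= n_all) stop("invalid split index: ", si)
    v <- stack[, , 1:si, drop = FALSE]
    ca <- stack[, , (si + 1):n_all, drop = FALSE]
  }
  list(voltage = v, calcium = ca, frame_rate = frame_rate, info = info)
}

#' Region of interest
#'
#' A rectangle (1-based pixel bounds, inclusive) or an explicit logical
#' mask over the frame.
#'
#' @param rows,cols integer ranges `c(from, to)` for a rectangular ROI.
#' @param mask optional logical matrix (overrides the rectangle).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(rows = NULL, cols = NULL, mask = NULL) {
  if (is.null(mask) && (is.null(rows) || is.null(cols)))
    stop("give either a mask or both row and column ranges")
  structure(list(rows = rows, cols = cols, mask = mask), class = "roi_spec")
}

#' Average a region of interest into a trace
#'
#' Per-frame mean over the ROI pixels; the time base comes from the frame
#' rate (100 frames/s gives a 10 ms sampling interval, frame 0 at t = 0).
#'
#' @param frames array `h x w x n` of one channel (from [load_movie()] or
#'   an [om_movie] channel).
#' @param roi an [roi_spec].
#' @param frame_rate frames/s.
#' @param channel channel label for the resulting trace.
#' @param meta metadata list.
#' @return An [om_trace] of the ROI-averaged counts.
#' @export
extract_roi_trace <- function(frames, roi, frame_rate,
                              channel = c("voltage", "calcium"),
                              meta = list()) {
  channel <- match.arg(channel)
  stopifnot(inherits(roi, "roi_spec"), length(dim(frames)) == 3)
  h <- dim(frames)[1]; w <- dim(frames)[2]; n <- dim(frames)[3]
  if (!is.null(roi$mask)) {
    if (!all(dim(roi$mask) == c(h, w))) stop("ROI mask does not match frame size")
    if (!any(roi$mask)) stop("empty ROI")
    vals <- apply(frames, 3, function(f) mean(f[roi$mask]))
  } else {
    r <- roi$rows; cc <- roi$cols
    if (r[1] < 1 || r[2] > h || cc[1] < 1 || cc[2] > w || r[1] > r[2] ||
        cc[1] > cc[2])
      stop("ROI out of frame bounds")
    sub <- frames[r[1]:r[2], cc[1]:cc[2], , drop = FALSE]
    vals <- apply(sub, 3, mean)
  }
  dt <- 1000 / frame_rate
  om_trace((seq_len(n) - 1L) * dt, vals, channel = channel,
           frame_rate = frame_rate, meta = meta)
}
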