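#' Validate a run configuration
#'
#' Checks the structural requirements of a pipeline configuration before
#' any computation; violations are reported with their field path.
#'
#' @param config a list (or path to a YAML file).
#' @return The validated config list, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fail <- function(path, why) stop("config field `", path, "`: ", why,
                                   call. = FALSE)
  if (is.null(config$seed)) fail("seed", "missing")
  if (!is.numeric(config$seed)) fail("seed", "must be an integer")
  if (is.null(config$out_dir)) fail("out_dir", "missing")
  if (is.null(config$protocol)) fail("protocol", "missing")
  if (is.null(config$protocol$mode)) fail("protocol.mode", "missing")
  if (!config$protocol$mode %in% c("fixed", "ramp", "spontaneous"))
    fail("protocol.mode", "must be fixed, ramp or spontaneous")
  if (!is.null(config$dose)) {
    if (is.null(config$dose$doses)) fail("dose.doses", "missing")
    if (is.null(config$dose$drug)) fail("dose.drug", "missing")
    if (is.null(config$dose$drug$effects)) fail("dose.drug.effects", "missing")
  }
  if (!is.null(config$movie) && !is.null(config$movie$channel_layout) &&
      !config$movie$channel_layout %in% c("interleaved", "stacked"))
    fail("movie.channel_layout", "must be interleaved or stacked")
  invisible(config)
}

protocol_from_config <- function(pc) {
  pacing_protocol(mode = pc$mode,
                  rate_bpm = pc$rate_bpm %||% 60,
                  bpm_start = pc$bpm_start %||% 60,
                  bpm_end = pc$bpm_end %||% 200,
                  bpm_step = pc$bpm_step %||% 10,
                  beats_per_step = pc$beats_per_step %||% 8,
                  discard_per_step = pc$discard_per_step %||% 2,
                  n_beats = pc$n_beats, t0 = pc$t0 %||% 50)
}

drug_from_config <- function(dc) {
  drug_model(dc$name %||% "drug", dc$effects)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes, as configured: synthetic recording generation (traces and
#' optionally a rendered movie), ROI extraction, conditioning, per-beat
#' metrics, restitution analysis, and the dose-response screen. All
#' tabular outputs are written as delimited text under `out_dir` together
#' with a log (package version, seed, timings) and the echoed
#' configuration; a run is reproducible bit-for-bit from (config, seed).
#'
#' @param config list or path to a YAML configuration. Fields: `seed`,
#'   `out_dir`, `protocol` (mode and schedule), optional `cell_types`,
#'   `duration`, `frame_rate`, `noise` (gaussian_sd, drift_slope),
#'   `movie` (height, width, channel_layout, gain, offset,
#'   voltage_polarity, roi), `analyze` (polarity, detrend, smooth),
#'   `restitution` (ramp fields), `dose` (drug, doses, n_wells).
#' @param verbose print progress lines.
#' @return list with the computed objects: `metrics`, `restitution`,
#'   `screen`, and `paths` of everything written.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  t_start <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  seed <- as.integer(config$seed)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  protocol <- protocol_from_config(config$protocol)
  cell_types <- config$cell_types %||% c("atrial", "ventricular")
  duration <- config$duration %||% 10000
  frame_rate <- config$frame_rate %||% 100
  analyze_cfg <- config$analyze %||% list()

  noise <- if (!is.null(config$noise))
    noise_model(config$noise$gaussian_sd %||% 0.03,
                config$noise$drift_slope %||% -0.008,
                seed = seed) else NULL

  metrics_all <- list()
  for (ct in cell_types) {
    say("simulate + analyze: ", ct)
    params <- cell_preset(ct)
    v <- generate_ap_trace(params, protocol, frame_rate, duration)
    ca <- generate_cat_trace(params, protocol, frame_rate, duration)
    manifest_v <- v$meta$manifest

    if (!is.null(config$movie)) {
      mc <- config$movie
      spec <- movie_spec(mc$height %||% 16, mc$width %||% 16, frame_rate,
                         mc$channel_layout %||% "interleaved",
                         mc$gain %||% 20000, mc$offset %||% 2000,
                         mc$voltage_polarity %||% "inverted")
      mv <- render_movie(v, ca, spec, noise)
      tif <- file.path(out_dir, paste0(ct, "_movie.tif"))
      write_movie(mv, tif)
      paths <- c(paths, tif)
      ld <- load_movie(tif)
      roi <- roi_spec(rows = mc$roi$rows %||% c(1, spec$height),
                      cols = mc$roi$cols %||% c(1, spec$width))
      v_raw <- extract_roi_trace(ld$voltage, roi, ld$frame_rate, "voltage")
      ca_raw <- extract_roi_trace(ld$calcium, roi, ld$frame_rate, "calcium")
    } else {
      v_raw <- if (!is.null(noise)) add_noise(v, noise) else v
      ca_raw <- if (!is.null(noise))
        add_noise(ca, noise_model(noise$gaussian_sd, noise$drift_slope,
                                  noise$seed + 1L)) else ca
    }
    write_trace(v_raw, file.path(out_dir, paste0(ct, "_voltage.csv")))
    write_trace(ca_raw, file.path(out_dir, paste0(ct, "_calcium.csv")))
    yaml::write_yaml(lapply(manifest_v, I),
                     file.path(out_dir, paste0(ct, "_truth.yml")))

    cl <- if (protocol$mode == "fixed") 60000 / protocol$rate_bpm else NULL
    v_c <- condition_trace(v_raw, polarity = analyze_cfg$polarity %||% "auto",
                           detrend_method = analyze_cfg$detrend %||% "percentile",
                           cycle_length = cl,
                           smooth = isTRUE(analyze_cfg$smooth))
    ca_c <- condition_trace(ca_raw, polarity = "positive",
                            detrend_method = analyze_cfg$detrend %||% "percentile",
                            cycle_length = cl,
                            smooth = isTRUE(analyze_cfg$smooth))
    m <- beat_metrics(v_c, ca_c, protocol, well = ct)
    m$cell_type <- ct
    metrics_all[[ct]] <- m
  }
  metrics <- do.call(rbind, metrics_all)
  wr(metrics, "beat_metrics.csv")

  resti <- NULL
  if (!is.null(config$restitution)) {
    say("restitution")
    rp <- protocol_from_config(utils::modifyList(list(mode = "ramp"),
                                                 config$restitution))
    fits <- list()
    for (ct in cell_types) {
      v <- generate_ap_trace(cell_preset(ct), rp, frame_rate,
                             duration = max(stimulus_times(rp)) + 1500,
                             restitution = restitution_preset(ct))
      v_c <- condition_trace(if (!is.null(noise)) add_noise(v, noise) else v)
      m <- beat_metrics(v_c, NULL, rp, well = ct)
      pts <- compute_di(m, rp)
      fits[[ct]] <- fit_restitution(pts)
    }
    resti <- data.frame(cell_type = names(fits),
                        max_slope = vapply(fits, `[[`, 0, "max_slope"),
                        di_min = vapply(fits, `[[`, 0, "di_min"),
                        a = vapply(fits, function(f) f$coefficients[["a"]], 0),
                        b = vapply(fits, function(f) f$coefficients[["b"]], 0),
                        c = vapply(fits, function(f) f$coefficients[["c"]], 0),
                        rmse = vapply(fits, `[[`, 0, "fit_rmse"))
    wr(resti, "restitution.csv")
  }

  screen <- NULL
  if (!is.null(config$dose)) {
    say("dose-response screen")
    dc <- config$dose
    drug <- drug_from_config(dc$drug)
    tab <- simulate_screen(drug, doses = unlist(dc$doses),
                           n_wells = dc$n_wells %||% 6, seed = seed)
    wr(as.data.frame(tab), "dose_table.csv")
    screen <- assemble_screen_report(stats::setNames(list(tab), drug$name))
    wr(screen$summaries, "dose_summaries.csv")
    wr(screen$between_group, "dose_between_group.csv")
    wr(screen$dose_trends, "dose_dunnett.csv")
  }

  log <- list(package = "cardiomap",
              version = as.character(utils::packageVersion("cardiomap")),
              r_version = R.version.string,
              seed = seed,
              elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
              config = config)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yml"))
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yml"))
  say("done")
  invisible(list(metrics = metrics, restitution = resti, screen = screen,
                 paths = paths))
}

#' Write the canonical synthetic fixture set
#'
#' Generates the reference fixtures exercised by the test suite and the
#' worked examples: noiseless atrial and ventricular paced traces with
#' ground-truth manifests, a small noisy dual-channel movie, a ramp
#' (restitution) recording, and three 4-dose screens (a prolonging drug,
#' a shortening drug, and a null drug) with their true effect sizes.
#'
#' @param seed integer seed controlling all randomness.
#' @param dir output directory.
#' @return Named list of written paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  pro <- pacing_protocol("fixed", rate_bpm = 60, n_beats = 10)
  for (ct in c("atrial", "ventricular")) {
    v <- generate_ap_trace(cell_preset(ct), pro, duration = 10000)
    ca <- generate_cat_trace(cell_preset(ct), pro, duration = 10000)
    paths[[paste0(ct, "_v")]] <-
      write_trace(v, file.path(dir, paste0(ct, "_voltage.csv")))
    paths[[paste0(ct, "_ca")]] <-
      write_trace(ca, file.path(dir, paste0(ct, "_calcium.csv")))
    yaml::write_yaml(lapply(v$meta$manifest, I),
                     file.path(dir, paste0(ct, "_v_truth.yml")))
    yaml::write_yaml(lapply(ca$meta$manifest, I),
                     file.path(dir, paste0(ct, "_ca_truth.yml")))
  }
  # noisy movie, 2 s
  pro2 <- pacing_protocol("fixed", rate_bpm = 60, n_beats = 2)
  v <- generate_ap_trace(cell_preset("atrial"), pro2, duration = 2000)
  ca <- generate_cat_trace(cell_preset("atrial"), pro2, duration = 2000)
  mv <- render_movie(v, ca, movie_spec(height = 8, width = 8),
                     noise_model(seed = seed))
  paths$movie <- write_movie(mv, file.path(dir, "atrial_movie.tif"))
  # ramp recording
  rp <- pacing_protocol("ramp", bpm_start = 60, bpm_end = 200)
  vr <- generate_ap_trace(cell_preset("ventricular"), rp,
                          duration = max(stimulus_times(rp)) + 1500,
                          restitution = restitution_preset("ventricular"))
  paths$ramp <- write_trace(vr, file.path(dir, "ventricular_ramp.csv"))
  yaml::write_yaml(lapply(vr$meta$manifest, I),
                   file.path(dir, "ventricular_ramp_truth.yml"))
  # dose screens
  drugs <- list(
    prolonging = drug_model("prolonging",
      list(list(param = "apd", emax = 1.0, ec50 = 10, hill_n = 1,
                group = "atrial"),
           list(param = "apd", emax = 0.35, ec50 = 10, hill_n = 1,
                group = "ventricular"),
           list(param = "catd", emax = 0.4, ec50 = 10, hill_n = 1))),
    shortening = drug_model("shortening",
      list(list(param = "apd", emax = -0.4, ec50 = 10, hill_n = 1))),
    null = drug_model("null", list()))
  for (nm in names(drugs)) {
    tab <- simulate_screen(drugs[[nm]], doses = c(3, 10, 30, 100),
                           seed = seed + match(nm, names(drugs)))
    p <- file.path(dir, paste0("screen_", nm, ".csv"))
    utils::write.csv(as.data.frame(tab), p, row.names = FALSE)
    yaml::write_yaml(list(truth = lapply(attr(tab, "truth"), as.data.frame)),
                     file.path(dir, paste0("screen_", nm, "_truth.yml")))
    paths[[paste0("screen_", nm)]] <- p
  }
  invisible(paths)
}
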