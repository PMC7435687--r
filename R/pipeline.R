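#' Default pipeline configuration
#'
#' A flat, namespaced key-value list covering every tunable of the
#' pipeline, each with its unit in the name of the stage it feeds.  A
#' fully-defaulted configuration is valid; unknown keys are rejected by
#' [read_config()].
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    io.fs = 100,                    # Hz, configured sampling rate
    io.accel_unit = "m/s^2",
    io.gyro_unit = "rad/s",
    io.accel_range = 8,             # g
    io.gyro_range = 2000,           # deg/s
    qc.gap_factor = 1.5,            # x nominal dt
    qc.baseline_n = 5000,           # samples
    qc.clip_tol = 0.999,            # fraction of full scale
    zupt.window = 0.1,              # s
    zupt.gyro_threshold = 0.6,      # rad/s
    zupt.accel_threshold = 0.8,     # m/s^2
    zupt.min_duration = 0.05,       # s
    eskf.accel_noise_sd = 0.02,     # m/s^2
    eskf.gyro_noise_sd = 0.2 * pi / 180,  # rad/s
    eskf.zupt_noise_sd = 0.01,      # m/s
    eskf.max_gap = NA,              # s; NA = 3.5 nominal intervals
    eskf.bridge_gaps = FALSE,
    eskf.init_rest_min = 0.5,       # s
    eskf.zupt_enabled = TRUE,
    eskf.check_psd = FALSE,
    events.prominence = 1.5,        # rad/s
    events.min_stride_time = 0.4,   # s
    events.smooth_window = 0.05,    # s
    turns.heading_threshold = 20,   # deg
    turns.drop_adjacent = FALSE,
    match.tol = 0.25,               # s
    cluster.seed = 0,
    foot = "right"
  ), class = "pipeline_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `namespace.key = value`; `#` starts a comment.
#' Values are coerced to numeric or logical where possible.  Keys not
#' present keep their defaults; unknown keys raise an error so that typos
#' never silently fall back to defaults.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    if (val == "NA") {
      val <- NA
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      val <- as.logical(toupper(val))
    } else {
      suppressWarnings(num <- as.numeric(val))
      if (!is.na(num)) val <- num
    }
    cfg[[key]] <- val
  }
  cfg
}

#' Write a configuration (defaults or otherwise) to a file
#' @param cfg a `pipeline_config`.
#' @param path output path, or `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg = default_config(), path = "") {
  fmt <- vapply(cfg, function(v) {
    if (is.character(v)) v else format(v, digits = 12)
  }, character(1))
  writeLines(paste(names(cfg), "=", fmt), if (nzchar(path)) path else stdout())
  invisible(path)
}

config_to_eskf <- function(cfg) {
  eskf_config(
    zupt_window = cfg$zupt.window,
    zupt_gyro_threshold = cfg$zupt.gyro_threshold,
    zupt_accel_threshold = cfg$zupt.accel_threshold,
    zupt_min_duration = cfg$zupt.min_duration,
    accel_noise_sd = cfg$eskf.accel_noise_sd,
    gyro_noise_sd = cfg$eskf.gyro_noise_sd,
    zupt_noise_sd = cfg$eskf.zupt_noise_sd,
    max_gap = if (is.na(cfg$eskf.max_gap)) NULL else cfg$eskf.max_gap,
    bridge_gaps = cfg$eskf.bridge_gaps,
    init_rest_min = cfg$eskf.init_rest_min,
    zupt_enabled = cfg$eskf.zupt_enabled,
    check_psd = cfg$eskf.check_psd)
}

#' Run the full analysis pipeline on one recording
#'
#' Reads a unified CSV, runs quality control, the zero-velocity-aided
#' filter, gait-event detection, stride segmentation and turn exclusion,
#' and -- when a reference stride table is given -- the agreement
#' evaluation.  Artifacts written to `out_dir`: `states.csv` (per-sample
#' navigation states), `strides.csv`, `qc.json`, and `eval.json` (with a
#' reference).  Fails loudly (data-loss abort) when the recording has
#' gaps longer than the configured maximum.
#'
#' @param rec_path unified IMU CSV path.
#' @param ref_path reference stride CSV path, or `NULL`.
#' @param config a `pipeline_config` (or path to a config file).
#' @param out_dir output directory, created if missing.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(rec_path, ref_path = NULL, config = default_config(),
                         out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[read] %s (fs = %g Hz, units %s / %s)", rec_path, cfg$io.fs,
      cfg$io.accel_unit, cfg$io.gyro_unit)
  rec <- read_unified_csv(rec_path, fs_configured = cfg$io.fs,
                          accel_unit = cfg$io.accel_unit,
                          gyro_unit = cfg$io.gyro_unit,
                          accel_range = cfg$io.accel_range,
                          gyro_range = cfg$io.gyro_range)

  gaps <- detect_gaps(rec, cfg$qc.gap_factor)
  clip <- detect_clipping(rec, cfg$qc.clip_tol)
  qc <- list(
    n_samples = n_samples(rec),
    duration_s = diff(range(rec$t)),
    retained_fraction = gaps$retained_fraction,
    n_gaps = gaps$n_gaps,
    gap_intervals = gaps$gap_intervals,
    clipped_fraction_per_axis = clip$clipped_fraction_per_axis,
    clip_limit_mps2 = clip$limit_used)
  if (rec$timestamp_mode != "absent") {
    sr <- empirical_sampling_rates(rec)
    qc$fs_median <- stats::median(sr$fs_values, na.rm = TRUE)
    qc$n_nonpositive_intervals <- sr$n_nonpositive
  }
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  say("[qc] retained %.3f, %d gap(s)", gaps$retained_fraction, gaps$n_gaps)

  say("[eskf] zupt thresholds: gyro %.2f rad/s, accel %.2f m/s^2",
      cfg$zupt.gyro_threshold, cfg$zupt.accel_threshold)
  res <- run_eskf(rec, config_to_eskf(cfg))
  say("[eskf] %d corrections over %d samples",
      res$diagnostics$n_corrections, length(res$t))

  events <- detect_gait_events(rec, cfg$events.prominence,
                               cfg$events.min_stride_time,
                               cfg$events.smooth_window)
  strides <- segment_strides(events, res, foot = cfg$foot)
  strides <- exclude_turns(strides, res, cfg$turns.heading_threshold,
                           cfg$turns.drop_adjacent)
  say("[gait] %d strides (%d after turn exclusion)",
      nrow(attr(strides, "all")), nrow(strides))

  states <- data.frame(t = res$t, vx = res$v[, 1], vy = res$v[, 2],
                       vz = res$v[, 3], sx = res$s[, 1], sy = res$s[, 2],
                       sz = res$s[, 3],
                       stationary = res$mask$stationary)
  utils::write.csv(states, file.path(out_dir, "states.csv"),
                   row.names = FALSE, quote = FALSE)
  write_stride_table(strides, file.path(out_dir, "strides.csv"))

  evaluation <- NULL
  if (!is.null(ref_path)) {
    reference <- read_reference_strides(ref_path)
    evaluation <- list()
    for (metric in c("stride_length", "stride_time")) {
      ev <- evaluate_agreement(strides, reference, metric = metric,
                               tol = cfg$match.tol,
                               cluster_seed = cfg$cluster.seed)
      evaluation[[metric]] <- list(
        n = ev$correlation$n,
        r = ev$correlation$r,
        slope = ev$correlation$slope,
        intercept = ev$correlation$intercept,
        rmse = ev$correlation$rmse,
        bias = ev$bland_altman$bias,
        loa_half_width = ev$bland_altman$loa_half_width,
        n_unmatched_measured = ev$matched$n_unmatched_measured,
        n_unmatched_reference = ev$matched$n_unmatched_reference,
        mean_silhouette = if (!is.null(ev$clusters)) ev$clusters$mean_sc else NA)
      say("[eval] %s: n = %d, r = %.4f, rmse = %.4f", metric,
          ev$correlation$n, ev$correlation$r, ev$correlation$rmse)
    }
    jsonlite::write_json(evaluation, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(rec = rec, qc = qc, eskf = res, events = events,
                 strides = strides, evaluation = evaluation))
}

#' Simulate a walking session to disk
#'
#' Generates a ground-truth walk, converts it to IMU signals, injects
#' artifacts, and writes the unified recording CSV plus the truth
#' reference stride CSV.
#'
#' @param out_dir output directory.
#' @param spec a [gait_spec()].
#' @param art an [artifact_spec()].
#' @return invisibly, list with paths and the in-memory objects.
#' @export
simulate_session <- function(out_dir, spec = gait_spec(),
                             art = artifact_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- synth_walk_trajectory(spec)
  rec <- inject_artifacts(trajectory_to_imu(traj), art)
  rec_path <- file.path(out_dir, "rec.csv")
  ref_path <- file.path(out_dir, "ref.csv")
  write_unified_csv(rec, rec_path)
  write_reference_strides(traj$truth_strides, ref_path)
  invisible(list(rec_path = rec_path, ref_path = ref_path,
                 traj = traj, rec = rec))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `analyze`, `evaluate`, `run`.  Designed
#' to be invoked from an Rscript wrapper:
#' `Rscript -e 'imugait::imugait_cli()' simulate --out dir --seed 7`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return exit status, invisibly (0 on success).
#' @export
imugait_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: imugait <simulate|qc|analyze|evaluate|run|print-config> [options]"
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--in", dest = "input", type = "character"),
    optparse::make_option("--reference", type = "character", default = NULL),
    optparse::make_option("--measured", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-strides", dest = "n_strides", type = "integer",
                          default = 20L),
    optparse::make_option("--stride-length", dest = "stride_length",
                          type = "double", default = 1.2),
    optparse::make_option("--metric", type = "character",
                          default = "stride_length"))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                               args = rest)
  cfg <- read_config(opts$config)
  status <- 0L
  switch(cmd,
    "print-config" = write_config(cfg),
    "simulate" = {
      spec <- gait_spec(n_strides = opts$n_strides,
                        stride_length_mean = opts$stride_length,
                        fs = cfg$io.fs, seed = opts$seed)
      simulate_session(opts$out, spec, artifact_spec(seed = opts$seed + 1))
    },
    "qc" = {
      rec <- read_unified_csv(opts$input, fs_configured = cfg$io.fs,
                              accel_unit = cfg$io.accel_unit,
                              gyro_unit = cfg$io.gyro_unit,
                              accel_range = cfg$io.accel_range)
      gaps <- detect_gaps(rec, cfg$qc.gap_factor)
      clip <- detect_clipping(rec, cfg$qc.clip_tol)
      out <- list(retained_fraction = gaps$retained_fraction,
                  n_gaps = gaps$n_gaps,
                  clipped_fraction_per_axis = clip$clipped_fraction_per_axis)
      jsonlite::write_json(out, file.path(opts$out, "qc.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    "analyze" = ,
    "run" = {
      run_pipeline(opts$input, opts$reference, cfg, opts$out)
    },
    "evaluate" = {
      measured <- read_stride_table(opts$measured)
      reference <- read_reference_strides(opts$reference)
      ev <- evaluate_agreement(measured, reference, metric = opts$metric,
                               tol = cfg$match.tol,
                               cluster_seed = cfg$cluster.seed)
      out <- list(n = ev$correlation$n, r = ev$correlation$r,
                  slope = ev$correlation$slope,
                  intercept = ev$correlation$intercept,
                  rmse = ev$correlation$rmse, bias = ev$bland_altman$bias,
                  loa_half_width = ev$bland_altman$loa_half_width,
                  mean_silhouette = if (!is.null(ev$clusters))
                    ev$clusters$mean_sc else NA)
      jsonlite::write_json(out, file.path(opts$out, "eval.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    {
      message(usage)
      status <- 1L
    })
  invisible(status)
}
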