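# File interfaces: run CSVs, ground-truth/schedule JSON, YAML configs.

#' Write recordings and ground truth to a directory
#'
#' One CSV per run with header
#' `time_ms,xl,yl,xr,yr,pl,pr,blink_l,blink_r`, a `ground_truth.json`
#' sidecar (per-run trial orientations and injected event lists) and a
#' `schedule.json` with the design parameters.
#'
#' @param recordings List of `gaze_recording` objects.
#' @param schedule The `experiment_schedule`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(recordings, schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in recordings) {
    data.table::fwrite(rec$data,
                       file.path(dir, sprintf("run-%02d.csv", rec$run)))
  }
  gt <- lapply(recordings, function(rec) {
    tr <- schedule$trials[schedule$trials$run == rec$run, ]
    list(run = rec$run, orientations = tr$orientation,
         events = rec$ground_truth)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  sj <- schedule[c("sessions", "runs_per_session", "orientations",
                   "trial_duration", "fixation_duration", "flicker_rate",
                   "seed")]
  sj$trials <- schedule$trials
  jsonlite::write_json(sj, file.path(dir, "schedule.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read recordings written by [write_recordings()]
#'
#' @param dir Directory containing `run-*.csv` and `schedule.json`.
#' @param sampling_rate Sampling rate of the stored data (default 1000 Hz).
#' @return List with `recordings` (list of `gaze_recording`) and
#'   `schedule` (an `experiment_schedule`).
#' @export
read_recordings <- function(dir, sampling_rate = 1000) {
  files <- sort(list.files(dir, pattern = "^run-[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0)
    gd_stop(sprintf("no run CSV files found in %s", dir), "gd_missing_data")
  sj <- jsonlite::read_json(file.path(dir, "schedule.json"),
                            simplifyVector = TRUE)
  schedule <- structure(list(
    sessions = sj$sessions, runs_per_session = sj$runs_per_session,
    orientations = sj$orientations, trial_duration = sj$trial_duration,
    fixation_duration = sj$fixation_duration,
    flicker_rate = sj$flicker_rate, seed = sj$seed,
    trials = as.data.frame(sj$trials)
  ), class = "experiment_schedule")
  recordings <- lapply(files, function(f) {
    run <- as.integer(sub("^run-0*([0-9]+)\\.csv$", "\\1", basename(f)))
    d <- as.data.frame(data.table::fread(f))
    structure(list(
      run = run,
      session = schedule$trials$session[match(run, schedule$trials$run)],
      data = d, sampling_rate = sampling_rate,
      ground_truth = NULL), class = "gaze_recording")
  })
  list(recordings = recordings, schedule = schedule)
}

CONFIG_KEYS <- c("schedule", "generator", "confound", "detection",
                 "methods", "train", "stats", "out_dir", "seed")

#' Assemble or validate a pipeline configuration
#'
#' A pipeline configuration bundles all stage parameters plus a single
#' global seed; it round-trips losslessly through YAML, and unknown keys
#' are rejected.
#'
#' @param ... Named entries among `schedule`, `generator`, `confound`,
#'   `detection`, `methods`, `train`, `stats`, `out_dir`, `seed`; each
#'   stage entry is a named list of arguments for the corresponding
#'   constructor.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad))
    gd_stop(paste("unknown config key(s):", paste(bad, collapse = ", ")),
            "gd_invalid_config")
  defaults <- list(schedule = list(), generator = list(), confound = list(),
                   detection = list(), methods = "svm_stats", train = list(),
                   stats = list(), out_dir = ".", seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @param config A `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  config
}

#' Simulate a dataset from a configuration
#'
#' Builds the schedule, simulates all runs and writes run CSVs, ground
#' truth, schedule and the config snapshot into `out_dir`.
#'
#' @param config A `pipeline_config`, a plain list, or a YAML path.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- resolve_config(config)
  out <- out_dir %||% cfg$out_dir
  seeds <- derive_seeds(cfg$seed, 2)
  sched_args <- cfg$schedule
  if (is.null(sched_args$seed)) sched_args$seed <- seeds[1]
  schedule <- do.call(build_schedule, sched_args)
  recs <- simulate_recording(schedule,
                             do.call(generator_params, cfg$generator),
                             do.call(confound_spec, cfg$confound),
                             seed = seeds[2])
  write_recordings(recs, schedule, out)
  write_config(cfg, file.path(out, "config.yaml"))
  message(sprintf("wrote %d runs to %s", length(recs), out))
  invisible(out)
}

#' Analyze a simulated or recorded dataset
#'
#' Reads the run CSVs of `data_dir`, executes
#' preprocess -> detect -> features -> requested decoders, and writes
#' `results.json` (per method: fold accuracies, mean, config snapshot,
#' seed), `features.csv` and `events.tsv` into `out_dir`.
#'
#' @param config A `pipeline_config`, plain list, or YAML path.
#' @param data_dir Directory with `run-*.csv` and `schedule.json`.
#' @param out_dir Output directory (default: `data_dir`).
#' @return Named list of `decoding_result` objects, invisibly.
#' @export
cmd_analyze <- function(config, data_dir, out_dir = data_dir) {
  cfg <- resolve_config(config)
  ds <- read_recordings(data_dir)
  expected <- n_runs(ds$schedule)
  got <- vapply(ds$recordings, function(r) r$run, numeric(1))
  missing <- setdiff(seq_len(expected), got)
  if (length(missing))
    gd_stop(paste("missing run file(s) for run(s):",
                  paste(missing, collapse = ", ")), "gd_missing_data")
  results <- analyze_participant(
    ds$recordings, ds$schedule, methods = cfg$methods,
    detection = do.call(detection_params, cfg$detection),
    config = do.call(train_config, cfg$train))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- lapply(results, function(r) {
    list(method = r$method, fold_accuracies = r$fold_accuracies,
         mean_accuracy = r$mean_accuracy, chance = r$chance, seed = cfg$seed)
  })
  jsonlite::write_json(list(schema_version = 1, config = unclass(cfg),
                            results = summary),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  write_features(attr(results, "features"),
                 file.path(out_dir, "features.csv"))
  write_events(attr(results, "events"), file.path(out_dir, "events.tsv"))
  tp <- results[["svm_time"]]
  if (!is.null(tp))
    data.table::fwrite(data.frame(timepoint = seq_along(tp$accuracy_by_time),
                                  accuracy = tp$accuracy_by_time),
                       file.path(out_dir, "accuracy_by_time.csv"))
  invisible(results)
}

#' Summarize results across participants
#'
#' Reads every `results.json` under `results_dir` (one per participant
#' directory), prints one row per participant and method, and adds the
#' group-level zero-inclusive Wilcoxon p-value per method when two or more
#' participants are present.
#'
#' @param results_dir Directory containing participant subdirectories (or
#'   itself containing a `results.json`).
#' @return Data frame with columns `participant`, `method`, `accuracy`,
#'   plus a `group_p` attribute (named per-method p-values), invisibly.
#' @export
cmd_report <- function(results_dir) {
  files <- list.files(results_dir, pattern = "^results\\.json$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0)
    gd_stop(sprintf("no results.json found under %s", results_dir),
            "gd_missing_data")
  rows <- do.call(rbind, lapply(files, function(f) {
    res <- jsonlite::read_json(f, simplifyVector = TRUE)
    part <- basename(dirname(f))
    data.frame(participant = part,
               method = vapply(res$results, `[[`, "", "method"),
               accuracy = vapply(res$results, `[[`, 0, "mean_accuracy"))
  }))
  rownames(rows) <- NULL
  group_p <- c()
  for (m in unique(rows$method)) {
    acc <- rows$accuracy[rows$method == m]
    if (length(acc) >= 2)
      group_p[m] <- wilcoxon_group(acc)$p
  }
  print(rows)
  if (length(group_p)) {
    cat("\nGroup-level one-sided Wilcoxon (vs chance 0.125):\n")
    for (m in names(group_p))
      cat(sprintf("  %-10s p = %.4g\n", m, group_p[m]))
  }
  attr(rows, "group_p") <- group_p
  invisible(rows)
}
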