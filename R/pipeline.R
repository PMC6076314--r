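#' Simulate one synthetic participant
#'
#' Convenience wrapper: builds the schedule (trial orders seeded from
#' `seed`) and simulates all runs.
#'
#' @param seed Integer seed for schedule and recordings.
#' @param schedule Optional pre-built `experiment_schedule`; by default the
#'   full design (2 sessions x 12 runs x 8 orientations) with trial orders
#'   drawn under `seed`.
#' @param params A `generator_params`.
#' @param confound A `confound_spec`.
#' @return List with `schedule` and `recordings`.
#' @export
simulate_participant <- function(seed, schedule = NULL,
                                 params = generator_params(),
                                 confound = confound_spec()) {
  seeds <- derive_seeds(seed, 2)
  if (is.null(schedule)) schedule <- build_schedule(seed = seeds[1])
  list(schedule = schedule,
       recordings = simulate_recording(schedule, params, confound,
                                       seed = seeds[2]))
}

#' Run the decoding pipeline for one participant
#'
#' Executes preprocess -> microsaccade detection -> summary features ->
#' requested decoders on a participant's raw recordings.
#'
#' @param recordings List of `gaze_recording` objects (one per run).
#' @param schedule The `experiment_schedule`.
#' @param methods Character vector among `"svm_raw"`, `"svm_stats"`,
#'   `"svm_time"`, `"cnn"`, `"rnn"`.
#' @param detection A `detection_params`.
#' @param config A [train_config()] for the neural decoders.
#' @param rnn_stride Temporal subsampling for the LSTM (default 1).
#' @return Named list of `decoding_result` objects, with attributes
#'   `features` (the feature matrix) and `events` (detected events).
#' @export
analyze_participant <- function(recordings, schedule,
                                methods = "svm_stats",
                                detection = detection_params(),
                                config = train_config(),
                                rnn_stride = 1) {
  allowed <- c("svm_raw", "svm_stats", "svm_time", "cnn", "rnn")
  bad <- setdiff(methods, allowed)
  if (length(bad))
    gd_stop(paste("unknown method(s):", paste(bad, collapse = ", ")),
            "gd_invalid_config")
  trials <- preprocess_recordings(recordings, schedule)
  events <- detect_microsaccades(trials, detection)
  feats <- feature_matrix(trials, events)
  folds <- make_folds(trial_runs(trials))
  results <- list()
  for (m in methods) {
    results[[m]] <- switch(m,
      svm_raw = svm_raw(trials, folds),
      svm_stats = svm_stats(feats, folds),
      svm_time = svm_timepoint(trials, folds),
      cnn = cnn_decode(trials, folds, config),
      rnn = rnn_decode(trials, folds, config, stride = rnn_stride))
  }
  attr(results, "features") <- feats
  attr(results, "events") <- events
  results
}

#' Null-calibration experiment: decoding accuracy without any confound
#'
#' Simulates `n_participants` independent participants with zero
#' orientation coupling (so labels are exchangeable by construction), runs
#' the full summary-statistics pipeline with leave-one-run-out
#' cross-validation on each, and returns the per-participant mean
#' accuracies. Their average estimates the pipeline's empirical chance
#' level (1/8 for the default design).
#'
#' @param n_participants Number of simulated participants (default 20).
#' @param seed Master seed; participant seeds are derived from it.
#' @param schedule Optional shared `experiment_schedule` (default: full
#'   design per participant, orders seeded per participant).
#' @param params A `generator_params`.
#' @return Numeric vector of per-participant mean accuracies.
#' @export
null_calibration <- function(n_participants = 20, seed = 1, schedule = NULL,
                             params = generator_params()) {
  seeds <- derive_seeds(seed, n_participants)
  vapply(seeds, function(s) {
    sim <- simulate_participant(s, schedule = schedule, params = params)
    res <- analyze_participant(sim$recordings, sim$schedule, "svm_stats")
    res$svm_stats$mean_accuracy
  }, numeric(1))
}
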