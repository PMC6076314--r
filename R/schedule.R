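#' Build an experiment schedule
#'
#' Constructs the session/run/trial layout of a grating-orientation
#' fixation experiment. Each run starts and ends with a fixation interval
#' and contains every orientation exactly once, in a per-run random order.
#' With the defaults (2 sessions of 12 runs, 8 orientations, 16 s trials and
#' 16 s fixation intervals) a run lasts 160 s and the full design has
#' 192 trials, 24 per orientation.
#'
#' @param sessions Number of sessions.
#' @param runs_per_session Number of runs per session.
#' @param orientations Grating orientations in degrees, distinct, in
#'   \[0, 180). Default: 0 to 157.5 in steps of 22.5.
#' @param trial_duration Trial duration in seconds.
#' @param fixation_duration Duration of the fixation interval at the start
#'   and end of each run, in seconds.
#' @param flicker_rate Stimulus on/off flicker rate in Hz (250 ms on /
#'   250 ms off at the default 2 Hz). Within a trial the stimulus is "on"
#'   during the first half of each flicker cycle.
#' @param seed Integer seed controlling the per-run trial orders.
#' @return An object of class `experiment_schedule`: a list with the design
#'   parameters and a `trials` data frame (columns `session`, `run`,
#'   `trial_in_run`, `trial`, `orientation`).
#' @examples
#' sched <- build_schedule(seed = 1)
#' nrow(sched$trials)        # 192
#' table(sched$trials$orientation)
#' @export
build_schedule <- function(sessions = 2, runs_per_session = 12,
                           orientations = seq(0, 157.5, by = 22.5),
                           trial_duration = 16, fixation_duration = 16,
                           flicker_rate = 2, seed = 1) {
  if (sessions < 1 || runs_per_session < 1)
    gd_stop("sessions and runs_per_session must be >= 1", "gd_invalid_schedule")
  if (anyDuplicated(orientations))
    gd_stop("orientations must be distinct", "gd_invalid_schedule")
  if (any(orientations < 0 | orientations >= 180))
    gd_stop("orientations must lie in [0, 180)", "gd_invalid_schedule")
  if (trial_duration <= 0 || fixation_duration < 0 || flicker_rate <= 0)
    gd_stop("durations and flicker_rate must be positive", "gd_invalid_schedule")

  n_runs <- sessions * runs_per_session
  n_ori <- length(orientations)
  run_seeds <- derive_seeds(seed, n_runs)
  orders <- lapply(seq_len(n_runs), function(r) {
    set.seed(run_seeds[r])
    sample.int(n_ori)
  })
  trials <- data.frame(
    session = rep(seq_len(sessions), each = runs_per_session * n_ori),
    run = rep(seq_len(n_runs), each = n_ori),
    trial_in_run = rep(seq_len(n_ori), times = n_runs),
    trial = seq_len(n_runs * n_ori),
    orientation = unlist(lapply(orders, function(o) orientations[o]))
  )
  structure(list(
    sessions = sessions, runs_per_session = runs_per_session,
    orientations = orientations, trial_duration = trial_duration,
    fixation_duration = fixation_duration, flicker_rate = flicker_rate,
    seed = seed, trials = trials
  ), class = "experiment_schedule")
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf(
    "Experiment schedule: %d session(s) x %d run(s), %d orientations\n",
    x$sessions, x$runs_per_session, length(x$orientations)))
  cat(sprintf("  trials: %d (%d per orientation), run duration %g s\n",
              nrow(x$trials), nrow(x$trials) / length(x$orientations),
              run_duration(x)))
  invisible(x)
}

#' Run duration implied by a schedule
#'
#' Two fixation intervals plus one trial per orientation, in seconds.
#' @param schedule An `experiment_schedule`.
#' @return Duration of one run in seconds.
#' @export
run_duration <- function(schedule) {
  2 * schedule$fixation_duration +
    schedule$trial_duration * length(schedule$orientations)
}

n_runs <- function(schedule) schedule$sessions * schedule$runs_per_session

# Start time (s, relative to run onset) of trial k (1-based) within a run.
trial_start <- function(schedule, k) {
  schedule$fixation_duration + (k - 1) * schedule$trial_duration
}
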