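test_that("identical seed and parameters give bit-identical recordings", {
  sched <- small_schedule()
  a <- simulate_recording(sched, seed = 4)
  b <- simulate_recording(sched, seed = 4)
  expect_identical(a, b)
  c <- simulate_recording(sched, seed = 5)
  expect_false(identical(a[[1]]$data, c[[1]]$data))
})

test_that("silent generator produces exactly zero positions and no events", {
  sched <- small_schedule(runs = 1)
  rec <- simulate_recording(sched, silent_params(), seed = 1)[[1]]
  for (ch in c("xl", "yl", "xr", "yr", "pl", "pr"))
    expect_true(all(rec$data[[ch]] == 0))
  expect_equal(nrow(rec$ground_truth), 0)
  expect_true(all(rec$data$blink_l == 0))
})

test_that("per-trial microsaccade counts follow the configured Poisson rate", {
  sched <- build_schedule(sessions = 1, runs_per_session = 2, seed = 21)
  recs <- simulate_recording(sched, seed = 22)
  gt <- do.call(rbind, lapply(recs, function(r) r$ground_truth))
  n_trials <- 16
  expected <- 1.5 * sched$trial_duration          # 24 events per 16 s trial
  mean_count <- sum(!is.na(gt$trial)) / n_trials
  se <- sqrt(expected / n_trials)                 # Poisson SE of the mean
  expect_lt(abs(mean_count - expected), 3 * se)
})

test_that("full orientation coupling locks directions to the orthogonal axis", {
  sched <- build_schedule(sessions = 1, runs_per_session = 7, seed = 31)
  recs <- simulate_recording(sched, confound = confound_spec(1), seed = 32)
  gt <- do.call(rbind, lapply(recs, function(r)
    cbind(run = r$run, r$ground_truth)))
  gt <- gt[!is.na(gt$trial), ]
  # stimulus-off events keep the baseline distribution; restrict to on-phase
  rel <- gt$onset_ms / 1000 -
    (sched$fixation_duration + (gt$trial - 1) * sched$trial_duration)
  gt <- gt[(rel * sched$flicker_rate) %% 1 < 0.5, ]
  axial <- function(deg) {
    a <- deg * pi / 90
    (atan2(mean(sin(a)), mean(cos(a))) * 90 / pi) %% 180
  }
  circ_diff <- function(a, b) { d <- (a - b) %% 180; pmin(d, 180 - d) }
  # pooled per orientation: tight lock
  for (o in sched$orientations) {
    m <- axial(gt$direction[gt$orientation == o])
    expect_lt(circ_diff(m, (o + 90) %% 180), 11.25)
  }
  # per trial (>= 50 trials): large majority within the same tolerance
  keys <- interaction(gt$run, gt$trial, drop = TRUE)
  per_trial <- tapply(seq_len(nrow(gt)), keys, function(i) {
    circ_diff(axial(gt$direction[i]), (gt$orientation[i[1]] + 90) %% 180)
  })
  expect_gte(length(per_trial), 50)
  expect_gte(mean(per_trial < 11.25), 0.95)
})

test_that("zero coupling reproduces the baseline generator bit for bit", {
  sched <- small_schedule(runs = 2)
  base <- simulate_recording(sched, seed = 9)
  null_c <- simulate_recording(sched, confound = confound_spec(0), seed = 9)
  expect_identical(base, null_c)
})

test_that("blink-flagged fraction matches rate x duration", {
  sched <- build_schedule(sessions = 1, runs_per_session = 2, seed = 41)
  par <- generator_params(blink_rate = 30, blink_duration = 200)
  recs <- simulate_recording(sched, par, seed = 42)
  frac <- mean(c(recs[[1]]$data$blink_l, recs[[2]]$data$blink_l))
  expected <- 30 / 60 * 0.2                       # 10% of samples
  n_expected <- 30 / 60 * 320                     # blinks over both runs
  tol <- 3 * sqrt(n_expected) * 0.2 / 320
  expect_lt(abs(frac - expected), tol)
  # masked samples are missing until imputation
  expect_true(anyNA(recs[[1]]$data$xl[recs[[1]]$data$blink_l == 1]))
})

test_that("drift excursion per second is calibrated to drift_speed", {
  sched <- build_schedule(sessions = 1, runs_per_session = 3,
                          trial_duration = 16, seed = 51)
  par <- generator_params(microsaccade_rate = 0, tremor_amplitude = 0,
                          blink_rate = 0, drift_speed = 0.5)
  recs <- simulate_recording(sched, par, seed = 52)
  exc <- unlist(lapply(recs, function(r) {
    x <- r$data$xl
    abs(x[seq(1001, length(x), by = 1000)] -
          x[seq(1, length(x) - 1000, by = 1000)])
  }))
  expect_lt(abs(mean(exc) - 0.5) / 0.5, 0.15)
})

test_that("binocular sharing follows binocular_correlation", {
  sched <- build_schedule(sessions = 1, runs_per_session = 3, seed = 61)
  recs <- simulate_recording(sched, generator_params(binocular_correlation = 0.9),
                             seed = 62)
  gt <- do.call(rbind, lapply(recs, function(r) r$ground_truth))
  p_both <- mean(gt$eye == "both")
  expect_lt(abs(p_both - 0.9), 3 * sqrt(0.9 * 0.1 / nrow(gt)))
})

test_that("invalid generator and confound parameters are rejected", {
  expect_error(generator_params(microsaccade_rate = -1),
               class = "gd_invalid_params")
  expect_error(generator_params(tremor_band = c(30, 600)),
               class = "gd_invalid_params")
  expect_error(generator_params(binocular_correlation = 1.2),
               class = "gd_invalid_params")
  expect_error(confound_spec(coupling_strength = 1.5),
               class = "gd_invalid_params")
})
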