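test_that("blink imputation replaces flagged samples by the unflagged median", {
  ch <- list(xl = c(1, 2, NA, 4), yl = rep(0, 4), xr = rep(0, 4),
             yr = rep(0, 4), pl = rep(5, 4), pr = rep(5, 4))
  rec <- mk_recording(ch, blink = c(0, 0, 1, 0))
  out <- impute_blinks(rec)
  expect_equal(out$data$xl, c(1, 2, 2, 4))      # median of {1,2,4}
  expect_equal(out$data$pl, rep(5, 4))
  expect_equal(out$data$xl[c(1, 2, 4)], c(1, 2, 4))  # unflagged untouched
})

test_that("imputation is the identity when nothing is flagged", {
  ch <- list(xl = rnorm(50), yl = rnorm(50), xr = rnorm(50), yr = rnorm(50),
             pl = rnorm(50), pr = rnorm(50))
  rec <- mk_recording(ch)
  expect_identical(impute_blinks(rec)$data, rec$data)
})

test_that("a fully flagged channel raises a degenerate-channel error", {
  ch <- list(xl = rep(NA_real_, 10), yl = rnorm(10), xr = rnorm(10),
             yr = rnorm(10), pl = rnorm(10), pr = rnorm(10))
  rec <- mk_recording(ch, blink = rep(1L, 10))
  expect_error(impute_blinks(rec), class = "gd_degenerate_channel")
})

test_that("zero-phase Butterworth gain matches the digital closed form", {
  tt <- (0:15999) / 1000
  # DC / slow passband
  expect_equal(lowpass_filter(rep(3, 1000)), rep(3, 1000), tolerance = 1e-9)
  g10 <- tone_amplitude(lowpass_filter(sin(2 * pi * 10 * tt)))
  expect_lt(abs(g10 - 1), 0.01)
  # 150 Hz stopband edge: zero-phase application squares the magnitude
  g150 <- tone_amplitude(lowpass_filter(sin(2 * pi * 150 * tt)))
  expect_equal(g150, butter_gain(150, 100, 1000, 5)^2, tolerance = 0.02)
  # cutoff: |H| = 1/sqrt(2) single-pass, 1/2 zero-phase
  g100 <- tone_amplitude(lowpass_filter(sin(2 * pi * 100 * tt)))
  expect_equal(g100, 0.5, tolerance = 0.02)
  expect_error(lowpass_filter(rnorm(10), cutoff_hz = 600),
               class = "gd_invalid_params")
})

test_that("downsampling to 256 Hz keeps length, constants and tones", {
  expect_equal(length(downsample(rnorm(16000))), 4096)
  expect_equal(downsample(rep(3, 16000)), rep(3, 4096))
  tt <- (0:15999) / 1000
  d <- downsample(sin(2 * pi * 10 * tt))
  spec <- Mod(stats::fft(d))[1:2048]
  expect_equal((which.max(spec) - 1) * 256 / 4096, 10)
  expect_lt(max(abs(d - sin(2 * pi * 10 * (0:4095) / 256))), 1e-4)
  expect_error(downsample(rnorm(100), fs_in = 100, fs_out = 200),
               class = "gd_invalid_params")
})

test_that("slicing skips the fixation interval and labels trials", {
  sched <- small_schedule(runs = 1, trial_s = 2, fix_s = 1)
  fs <- 256
  n <- run_duration(sched) * fs
  ramp <- (seq_len(n) - 1) / fs          # value = time in s
  ch <- setNames(rep(list(ramp), 6), c("xl", "yl", "xr", "yr", "pl", "pr"))
  trials <- slice_trials(ch, sched, run = 1, fs = fs)
  expect_length(trials, 8)
  expect_equal(unname(trials[[1]]$data["xl", 1]), 1,
               tolerance = 1e-9)                      # 1 s fixation skipped
  expect_equal(unname(trials[[2]]$data["xl", 1]), 3,
               tolerance = 1e-9)                      # abutting trials
  expect_equal(vapply(trials, function(t) t$orientation, numeric(1)),
               sched$trials$orientation[sched$trials$run == 1])
  expect_equal(dim(trials[[1]]$data), c(6, 2 * fs))
  short <- lapply(ch, function(x) x[1:100])
  expect_error(slice_trials(short, sched, run = 1, fs = fs),
               class = "gd_truncated_recording")
})

test_that("run centering zeroes each run-channel median independently", {
  mk <- function(run, offset) {
    lapply(1:3, function(k)
      mk_trial(matrix(rnorm(6 * 64), 6) + offset, trial = k + (run - 1) * 3,
               run = run))
  }
  trials <- c(mk(1, 1.3), mk(2, -2))
  centered <- center_runs(trials)
  for (r in 1:2) {
    stacked <- do.call(cbind, lapply(centered[which(
      vapply(centered, function(t) t$run, numeric(1)) == r)],
      function(t) t$data))
    expect_equal(unname(apply(stacked, 1, median)), rep(0, 6))
  }
  # shape preserved: centering only shifts
  shift <- trials[[1]]$data - centered[[1]]$data
  expect_equal(unname(shift), matrix(shift[, 1], 6, 64), tolerance = 1e-12)
  # idempotent: centering twice equals centering once
  expect_equal(center_runs(centered), centered)
})

test_that("end-to-end preprocessing yields the expected trial inventory", {
  sched <- small_schedule(runs = 3)
  recs <- simulate_recording(sched, seed = 13)
  trials <- preprocess_recordings(recs, sched)
  expect_length(trials, 24)
  expect_true(all(table(vapply(trials, function(t) t$orientation,
                               numeric(1))) == 3))
  expect_true(all(vapply(trials, function(t)
    identical(dim(t$data), as.integer(c(6, 512))), logical(1))))
  expect_false(anyNA(unlist(lapply(trials, function(t) t$data))))
})
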