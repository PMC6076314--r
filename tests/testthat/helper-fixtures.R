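# Shared fixtures, built in code at test time.

# Compact design: full 8 orientations but short trials, for fast end-to-end
# runs where the exact study-scale timing is not the property under test.
small_schedule <- function(runs = 3, trial_s = 2, fix_s = 1, seed = 11) {
  build_schedule(sessions = 1, runs_per_session = runs,
                 trial_duration = trial_s, fixation_duration = fix_s,
                 seed = seed)
}

# Hand-built trial tensor (channels x samples matrix in fixed order).
mk_trial <- function(data, trial = 1, run = 1, orientation = 0, fs = 256) {
  rownames(data) <- c("xl", "yl", "xr", "yr", "pl", "pr")
  structure(list(trial = trial, run = run, orientation = orientation,
                 data = data, sampling_rate = fs),
            class = "trial_tensor")
}

# Hand-built raw recording from a channel list (+ optional blink masks).
mk_recording <- function(channels, blink = NULL, fs = 1000, run = 1) {
  n <- length(channels[[1]])
  if (is.null(blink)) blink <- integer(n)
  structure(list(
    run = run, session = 1,
    data = data.frame(time_ms = (seq_len(n) - 1) / fs * 1000,
                      xl = channels$xl, yl = channels$yl,
                      xr = channels$xr, yr = channels$yr,
                      pl = channels$pl, pr = channels$pr,
                      blink_l = blink, blink_r = blink),
    sampling_rate = fs, ground_truth = NULL), class = "gaze_recording")
}

# Generator configuration with every stochastic component switched off.
silent_params <- function(...) {
  generator_params(microsaccade_rate = 0, drift_speed = 0,
                   tremor_amplitude = 0, blink_rate = 0, pupil_noise = 0,
                   pupil_baseline = 0, ...)
}

# Exact one-sided zero-inclusive signed-rank p by enumeration of all sign
# assignments of the nonzero differences (oracle for wilcoxon_group).
brute_pratt_p <- function(d) {
  ranks <- rank(abs(d))
  rnz <- ranks[d != 0]
  w_obs <- sum(ranks[d > 0])
  m <- length(rnz)
  if (m == 0) return(1)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.numeric(signs %*% rnz)
  mean(w_all >= w_obs)
}

# Single-pass magnitude response of the digital (bilinear) Butterworth
# low-pass at frequency f (closed form with tan prewarping).
butter_gain <- function(f, fc, fs, order) {
  (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))^(-0.5)
}

# Amplitude of a sinusoidal signal from its interior RMS (robust to the
# sample grid missing the exact peaks).
tone_amplitude <- function(x, trim = 0.2) {
  n <- length(x)
  sqrt(2 * mean(x[floor(n * trim):ceiling(n * (1 - trim))]^2))
}
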