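POS_CHANNELS <- c("xl", "yl", "xr", "yr")
ALL_CHANNELS <- c("xl", "yl", "xr", "yr", "pl", "pr")

# Single-pass IIR through C-level stats::filter (FIR numerator as
# convolution, AR denominator as recursion).
iir_filter <- function(x, b, a) df2_filter(b, a, x)

# Zero-phase (forward-backward) filtering with reflective edge padding.
zero_phase_filter <- function(x, b, a) zero_phase_cpp(b, a, x)

#' Low-pass filter a signal with a zero-phase Butterworth filter
#'
#' Digital Butterworth low-pass (designed by bilinear transform), applied
#' forward and backward so the net result has zero phase and the squared
#' magnitude response of the single-pass filter. The single-pass magnitude
#' at frequency f is `(1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 order))^(-1/2)`
#' (the analog prototype's `(1 + (f/fc)^(2 order))^(-1/2)` with the bilinear
#' frequency warping; the two coincide at DC and at the cutoff).
#'
#' @param x Numeric signal.
#' @param order Filter order (single pass); default 5.
#' @param cutoff_hz Cutoff frequency in Hz; default 100.
#' @param fs Sampling rate in Hz; default 1000.
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, order = 5, cutoff_hz = 100, fs = 1000) {
  if (cutoff_hz >= fs / 2)
    gd_stop("cutoff must be below the Nyquist frequency", "gd_invalid_params")
  if (anyNA(x))
    gd_stop("filter input contains missing values; impute blinks first",
            "gd_missing_values")
  bf <- signal::butter(order, cutoff_hz / (fs / 2))
  zero_phase_filter(x, bf$b, bf$a)
}

#' Replace blink-masked samples by the run median
#'
#' Every sample flagged in an eye's blink mask is replaced, in that eye's
#' position and pupil channels, by the channel's median over unflagged
#' samples (i.e. the fixation point for centered gaze). Unflagged samples
#' are returned unchanged.
#'
#' @param recording A `gaze_recording`.
#' @return The recording with missing samples imputed (blink masks kept).
#' @export
impute_blinks <- function(recording) {
  d <- recording$data
  masks <- list(l = d$blink_l > 0, r = d$blink_r > 0)
  for (ch in ALL_CHANNELS) {
    m <- if (grepl("l$", ch)) masks$l else masks$r
    m <- m | is.na(d[[ch]])
    if (!any(m)) next
    if (all(m))
      gd_stop(sprintf("channel %s has no unflagged samples", ch),
              "gd_degenerate_channel")
    d[[ch]][m] <- stats::median(d[[ch]][!m])
  }
  recording$data <- d
  recording
}

#' Resample a signal to a lower rate
#'
#' Interpolates the (already anti-alias-filtered) signal at the sample
#' times of the target rate with a cubic-convolution (Keys) kernel, exact
#' on constants and linear ramps. The caller must have
#' low-pass filtered the signal below the target Nyquist frequency first;
#' `preprocess_recording()` guarantees this ordering.
#'
#' @param x Numeric signal sampled at `fs_in`.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
downsample <- function(x, fs_in = 1000, fs_out = 256) {
  if (fs_out > fs_in)
    gd_stop("fs_out must not exceed fs_in", "gd_invalid_params")
  n_out <- round(length(x) * fs_out / fs_in)
  pos <- (seq_len(n_out) - 1) * fs_in / fs_out  # 0-based input position
  keys_interp(x, pos)
}

#' Slice a preprocessed recording into per-trial tensors
#'
#' Cuts the continuous (already resampled) run into its trials, skipping
#' the initial fixation interval; trials abut with no inter-trial gap.
#'
#' @param channels A list or data frame of the six channel vectors
#'   (`xl, yl, xr, yr, pl, pr`) at `fs` Hz covering one full run.
#' @param schedule The `experiment_schedule`.
#' @param run Run id of this recording.
#' @param fs Sampling rate of `channels` in Hz (default 256).
#' @return List of `trial_tensor` objects: each a list with `trial`, `run`,
#'   `orientation`, a 6 x samples `data` matrix (rows in fixed channel
#'   order) and `sampling_rate`.
#' @export
slice_trials <- function(channels, schedule, run, fs = 256) {
  spt <- round(schedule$trial_duration * fs)
  fix <- round(schedule$fixation_duration * fs)
  tr <- schedule$trials[schedule$trials$run == run, , drop = FALSE]
  n <- length(channels[[ALL_CHANNELS[1]]])
  need <- fix + nrow(tr) * spt
  if (n < need)
    gd_stop(sprintf("recording has %d samples, schedule requires %d", n, need),
            "gd_truncated_recording")
  lapply(seq_len(nrow(tr)), function(k) {
    idx <- fix + (k - 1) * spt + seq_len(spt)
    m <- do.call(rbind, lapply(ALL_CHANNELS, function(ch) channels[[ch]][idx]))
    rownames(m) <- ALL_CHANNELS
    structure(list(trial = tr$trial[k], run = run,
                   orientation = tr$orientation[k],
                   data = m, sampling_rate = fs),
              class = "trial_tensor")
  })
}

#' Center trials on the per-run channel medians
#'
#' For each run and channel, subtracts the median computed over all of that
#' run's trial samples, so gaze is expressed relative to the fixation point
#' and calibration offsets between runs are removed.
#'
#' @param trials List of `trial_tensor` objects carrying run ids.
#' @return The trials, centered.
#' @export
center_runs <- function(trials) {
  runs <- vapply(trials, function(t) t$run, numeric(1))
  for (r in unique(runs)) {
    idx <- which(runs == r)
    stacked <- do.call(cbind, lapply(trials[idx], function(t) t$data))
    med <- apply(stacked, 1, stats::median)
    for (i in idx) trials[[i]]$data <- trials[[i]]$data - med
  }
  trials
}

#' Preprocess one raw recording into centered trial tensors
#'
#' Fixed pipeline: impute blink gaps, zero-phase Butterworth low-pass
#' (order 5, 100 Hz), resample 1000 to 256 Hz, slice into trials. Centering
#' is applied across runs by [preprocess_recordings()]; when called on a
#' single recording the trials are centered against that run alone.
#'
#' @param recording A `gaze_recording`.
#' @param schedule The `experiment_schedule`.
#' @param fs_out Target sampling rate, default 256 Hz.
#' @param filter_order,cutoff_hz Butterworth settings (defaults 5, 100 Hz).
#' @param center If TRUE (default), apply per-run median centering.
#' @return List of `trial_tensor` objects (one per trial of the run).
#' @export
preprocess_recording <- function(recording, schedule, fs_out = 256,
                                 filter_order = 5, cutoff_hz = 100,
                                 center = TRUE) {
  rec <- impute_blinks(recording)
  fs_in <- rec$sampling_rate
  ch <- lapply(ALL_CHANNELS, function(nm)
    downsample(lowpass_filter(rec$data[[nm]], filter_order, cutoff_hz, fs_in),
               fs_in, fs_out))
  names(ch) <- ALL_CHANNELS
  trials <- slice_trials(ch, schedule, rec$run, fs_out)
  if (center) trials <- center_runs(trials)
  trials
}

#' Preprocess all runs of a participant
#'
#' Applies [preprocess_recording()] to every run and centers each run on
#' its own channel medians. With the default schedule, 24 recordings yield
#' 192 trial tensors of 6 channels x 4096 samples, 24 per orientation.
#'
#' @param recordings List of `gaze_recording` objects.
#' @param schedule The `experiment_schedule`.
#' @param ... Passed to [preprocess_recording()].
#' @return Flat list of `trial_tensor` objects across runs.
#' @export
preprocess_recordings <- function(recordings, schedule, ...) {
  unlist(lapply(recordings, preprocess_recording, schedule = schedule, ...),
         recursive = FALSE)
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat(sprintf("Trial %d (run %d, orientation %g deg): %d x %d at %g Hz\n",
              x$trial, x$run, x$orientation, nrow(x$data), ncol(x$data),
              x$sampling_rate))
  invisible(x)
}
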