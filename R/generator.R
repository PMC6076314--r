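#' Generator parameters for synthetic fixational eye movements
#'
#' Bundles the kinematic parameters of the synthetic binocular gaze
#' generator. Defaults reflect the classical fixational-eye-movement
#' literature: microsaccades occur 1--2 times per second with amplitudes
#' up to 30 arcmin (0.5 DVA) and a horizontal direction bias, shared
#' between the eyes; drift is a slow random walk with a mean absolute
#' excursion of about 30 arcmin per second, independent between eyes;
#' tremor is a low-amplitude 30--100 Hz oscillation, independent between
#' eyes; blinks produce short stretches of missing samples in both eyes.
#'
#' @param microsaccade_rate Microsaccade rate in events per second
#'   (a binocular event counts once).
#' @param microsaccade_amplitude_min,microsaccade_amplitude_max Amplitude
#'   range in degrees of visual angle (DVA); amplitudes are drawn uniformly.
#' @param microsaccade_duration_ms Length-2 range (ms) of event durations,
#'   drawn uniformly.
#' @param binocular_correlation Probability in \[0, 1\] that an event is
#'   executed by both eyes (with identical displacement); otherwise it is
#'   monocular, assigned to either eye with equal probability.
#' @param horizontal_bias Concentration (von Mises kappa) of the baseline
#'   microsaccade direction distribution toward the horizontal axis
#'   (an equal mixture of components at 0 and 180 degrees); 0 gives a
#'   uniform direction distribution.
#' @param drift_speed Mean absolute drift excursion per second, DVA/s.
#' @param drift_knot_hz Knot rate (Hz) of the spline-smoothed random walk
#'   that implements drift; sets the drift bandwidth.
#' @param tremor_band Length-2 frequency band (Hz) of tremor; must lie
#'   within (0, Nyquist).
#' @param tremor_amplitude Tremor standard deviation in DVA.
#' @param blink_rate Blink rate in events per minute.
#' @param blink_duration Blink duration in ms.
#' @param pupil_baseline,pupil_noise Pupil dilation baseline and slow-noise
#'   standard deviation, arbitrary units.
#' @param sampling_rate Recording sample rate in Hz.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(microsaccade_rate = 1.5,
                             microsaccade_amplitude_min = 0.1,
                             microsaccade_amplitude_max = 0.5,
                             microsaccade_duration_ms = c(10, 30),
                             binocular_correlation = 0.9,
                             horizontal_bias = 2,
                             drift_speed = 0.5,
                             drift_knot_hz = 2,
                             tremor_band = c(30, 100),
                             tremor_amplitude = 0.01,
                             blink_rate = 6,
                             blink_duration = 200,
                             pupil_baseline = 1000,
                             pupil_noise = 10,
                             sampling_rate = 1000) {
  p <- list(
    microsaccade_rate = microsaccade_rate,
    microsaccade_amplitude_min = microsaccade_amplitude_min,
    microsaccade_amplitude_max = microsaccade_amplitude_max,
    microsaccade_duration_ms = microsaccade_duration_ms,
    binocular_correlation = binocular_correlation,
    horizontal_bias = horizontal_bias,
    drift_speed = drift_speed,
    drift_knot_hz = drift_knot_hz,
    tremor_band = tremor_band,
    tremor_amplitude = tremor_amplitude,
    blink_rate = blink_rate,
    blink_duration = blink_duration,
    pupil_baseline = pupil_baseline,
    pupil_noise = pupil_noise,
    sampling_rate = sampling_rate
  )
  rates <- c(p$microsaccade_rate, p$microsaccade_amplitude_min,
             p$microsaccade_amplitude_max, p$drift_speed, p$tremor_amplitude,
             p$blink_rate, p$pupil_noise)
  if (any(rates < 0))
    gd_stop("rates and amplitudes must be nonnegative", "gd_invalid_params")
  if (p$binocular_correlation < 0 || p$binocular_correlation > 1)
    gd_stop("binocular_correlation must lie in [0, 1]", "gd_invalid_params")
  if (length(p$tremor_band) != 2 || p$tremor_band[1] <= 0 ||
      p$tremor_band[2] >= p$sampling_rate / 2 ||
      p$tremor_band[1] >= p$tremor_band[2])
    gd_stop("tremor_band must lie within (0, Nyquist)", "gd_invalid_params")
  if (p$microsaccade_amplitude_min > p$microsaccade_amplitude_max)
    gd_stop("amplitude min must not exceed max", "gd_invalid_params")
  structure(p, class = "generator_params")
}

#' Orientation-coupled microsaccade confound specification
#'
#' Describes an injected dependency between the presented grating
#' orientation and microsaccade behaviour, used as positive control for the
#' decoding pipeline. With `coupling_strength > 0`, microsaccades occurring
#' while the stimulus is on draw their direction, with probability
#' `coupling_strength`, from an axial von Mises distribution locked to an
#' orientation-dependent axis (by default orthogonal to the grating).
#' `coupling_strength = 0` reproduces the baseline generator exactly
#' (identical output for identical seed).
#'
#' @param coupling_strength Mixing weight in \[0, 1\] between the baseline
#'   direction distribution and the orientation-locked one.
#' @param direction_rule Function mapping an orientation (degrees) to a
#'   preferred movement axis in \[0, 180); default orthogonal.
#' @param rate_modulation Optional named numeric vector of per-orientation
#'   rate multipliers (names are orientations in degrees), or NULL.
#' @param concentration von Mises kappa of the orientation-locked axial
#'   direction distribution. The default (20, circular SD about 13 degrees)
#'   keeps per-trial mean directions within half a 22.5-degree histogram
#'   bin of the target axis.
#' @return An object of class `confound_spec`.
#' @export
confound_spec <- function(coupling_strength = 0,
                          direction_rule = function(ori) (ori + 90) %% 180,
                          rate_modulation = NULL,
                          concentration = 20) {
  if (coupling_strength < 0 || coupling_strength > 1)
    gd_stop("coupling_strength must lie in [0, 1]", "gd_invalid_params")
  structure(list(coupling_strength = coupling_strength,
                 direction_rule = direction_rule,
                 rate_modulation = rate_modulation,
                 concentration = concentration),
            class = "confound_spec")
}

# Raised-cosine-velocity saccade displacement profile at samples 0..k
# (fraction of total amplitude).
saccade_profile <- function(k) {
  p <- seq(0, 1, length.out = k + 1)
  p - sin(2 * pi * p) / (2 * pi)
}

# Sample one microsaccade direction. `axis` is NA for baseline events.
draw_direction <- function(axis, kappa_axis, horizontal_bias) {
  if (!is.na(axis)) {
    mode <- axis + 180 * (runif(1) < 0.5)
    return(rvonmises(1, mode, kappa_axis))
  }
  if (horizontal_bias <= 0) return(runif(1, 0, 360))
  mode <- 180 * (runif(1) < 0.5)
  rvonmises(1, mode, horizontal_bias)
}

# Two-sided frequency mask for band-limited noise synthesis; memoised on
# (n, fs, band) since every run of a dataset shares it.
tremor_band_mask <- local({
  cache_key <- NULL; cache_val <- NULL
  function(n, fs, band) {
    key <- c(n, fs, band)
    if (!identical(key, cache_key)) {
      freq <- (seq_len(n) - 1) * fs / n
      freq <- pmin(freq, fs - freq)
      cache_val <<- freq >= band[1] & freq <= band[2]
      cache_key <<- key
    }
    cache_val
  }
})

# Smooth band-limited random walk: cubic spline through Gaussian knots.
# step_sd is the per-knot increment SD.
spline_walk <- function(t, knot_hz, step_sd) {
  if (step_sd == 0) return(numeric(length(t)))
  dur <- max(t)
  kt <- seq(0, dur + 1 / knot_hz, by = 1 / knot_hz)
  kv <- cumsum(rnorm(length(kt), sd = step_sd))
  stats::spline(kt, kv, xout = t, method = "fmm")$y
}

# One run of synthetic binocular gaze. Returns a gaze_recording.
sim_run <- function(run_idx, schedule, params, confound, run_seed) {
  set.seed(run_seed)
  fs <- params$sampling_rate
  dur <- run_duration(schedule)
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  oris <- schedule$trials$orientation[schedule$trials$run == run_idx]
  n_tr <- length(oris)
  dmax_s <- max(params$microsaccade_duration_ms) / 1000

  # --- microsaccade events, segment-wise so per-trial counts are Poisson
  seg_start <- c(0, trial_start(schedule, seq_len(n_tr)),
                 schedule$fixation_duration + n_tr * schedule$trial_duration)
  seg_end <- c(seg_start[-1], dur)
  seg_trial <- c(NA, seq_len(n_tr), NA)
  ev <- list()
  for (s in seq_along(seg_start)) {
    rate <- params$microsaccade_rate
    tr <- seg_trial[s]
    if (!is.na(tr) && !is.null(confound$rate_modulation)) {
      m <- confound$rate_modulation[as.character(oris[tr])]
      if (!is.na(m)) rate <- rate * m
    }
    span <- seg_end[s] - seg_start[s]
    if (rate <= 0 || span <= dmax_s) next
    k <- stats::rpois(1, rate * span)
    if (k == 0) next
    onset <- sort(runif(k, seg_start[s], seg_end[s] - dmax_s))
    dms <- runif(k, params$microsaccade_duration_ms[1],
                 params$microsaccade_duration_ms[2])
    amp <- runif(k, params$microsaccade_amplitude_min,
                 params$microsaccade_amplitude_max)
    both <- runif(k) < params$binocular_correlation
    mono_right <- runif(k) < 0.5
    eye <- ifelse(both, "both", ifelse(mono_right, "right", "left"))
    dir <- numeric(k)
    for (j in seq_len(k)) {
      axis <- NA_real_
      if (!is.na(tr) && confound$coupling_strength > 0) {
        # stimulus on during first half of each flicker cycle
        rel <- onset[j] - seg_start[s]
        on_phase <- (rel * schedule$flicker_rate) %% 1 < 0.5
        if (on_phase && runif(1) < confound$coupling_strength)
          axis <- confound$direction_rule(oris[tr]) %% 180
      }
      dir[j] <- draw_direction(axis, confound$concentration,
                               params$horizontal_bias)
    }
    ev[[length(ev) + 1L]] <- data.frame(
      onset_ms = onset * 1000, duration_ms = dms, amplitude = amp,
      direction = dir, eye = eye, trial = rep(tr, k),
      orientation = if (is.na(tr)) rep(NA_real_, k) else rep(oris[tr], k))
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset_ms = numeric(), duration_ms = numeric(),
               amplitude = numeric(), direction = numeric(),
               eye = character(), trial = numeric(), orientation = numeric())

  # saccadic displacement built from per-sample increments, then integrated
  sacc <- function(which_eye) {
    dx <- numeric(n); dy <- numeric(n)
    sel <- which(events$eye %in% c("both", which_eye))
    for (j in sel) {
      i0 <- round(events$onset_ms[j] / 1000 * fs) + 1L
      k <- max(2L, round(events$duration_ms[j] / 1000 * fs))
      if (i0 + k > n) next
      prof <- events$amplitude[j] * diff(saccade_profile(k))
      th <- deg2rad(events$direction[j])
      idx <- i0 + seq_len(k) - 1L
      dx[idx] <- dx[idx] + prof * cos(th)
      dy[idx] <- dy[idx] + prof * sin(th)
    }
    list(x = cumsum(dx), y = cumsum(dy))
  }
  sl <- sacc("left"); sr <- sacc("right")

  # drift: knot step SD calibrated so E|x(t+1s) - x(t)| = drift_speed
  step_sd <- params$drift_speed /
    (sqrt(params$drift_knot_hz) * sqrt(2 / pi))
  drl_x <- spline_walk(tt, params$drift_knot_hz, step_sd)
  drl_y <- spline_walk(tt, params$drift_knot_hz, step_sd)
  drr_x <- spline_walk(tt, params$drift_knot_hz, step_sd)
  drr_y <- spline_walk(tt, params$drift_knot_hz, step_sd)

  # Band-limited Gaussian noise, synthesized in the frequency domain:
  # iid complex-Gaussian spectrum on the tremor band, inverse FFT. The
  # real and imaginary parts of one transform give two independent
  # channels. Each channel is scaled to the configured SD.
  tremor_pair <- function() {
    if (params$tremor_amplitude == 0) return(list(numeric(n), numeric(n)))
    band <- tremor_band_mask(n, fs, params$tremor_band)
    W <- complex(real = numeric(n), imaginary = numeric(n))
    m <- sum(band)
    W[band] <- complex(real = rnorm(m), imaginary = rnorm(m))
    z <- stats::fft(W, inverse = TRUE) / sqrt(n)
    lapply(list(Re(z), Im(z)), function(u)
      u * (params$tremor_amplitude / stats::sd(u)))
  }
  tl <- tremor_pair(); tr_ <- tremor_pair()
  xl <- drl_x + tl[[1]] + sl$x
  yl <- drl_y + tl[[2]] + sl$y
  xr <- drr_x + tr_[[1]] + sr$x
  yr <- drr_y + tr_[[2]] + sr$y

  pupil <- function() {
    params$pupil_baseline + spline_walk(tt, 1, params$pupil_noise)
  }
  pl <- pupil(); pr <- pupil()

  # blinks: binocular gaps flagged in the mask, samples set missing
  blink <- logical(n)
  nb <- stats::rpois(1, params$blink_rate / 60 * dur)
  if (nb > 0 && params$blink_duration > 0) {
    bd <- round(params$blink_duration / 1000 * fs)
    b0 <- round(runif(nb, 0, n - bd - 1))
    for (j in seq_len(nb)) blink[b0[j] + seq_len(bd)] <- TRUE
  }
  xl[blink] <- NA; yl[blink] <- NA; pl[blink] <- NA
  xr[blink] <- NA; yr[blink] <- NA; pr[blink] <- NA

  structure(list(
    run = run_idx,
    session = schedule$trials$session[match(run_idx, schedule$trials$run)],
    data = data.frame(time_ms = tt * 1000, xl = xl, yl = yl, xr = xr,
                      yr = yr, pl = pl, pr = pr,
                      blink_l = as.integer(blink),
                      blink_r = as.integer(blink)),
    sampling_rate = fs,
    ground_truth = events
  ), class = "gaze_recording")
}

#' Simulate binocular gaze recordings for an experiment schedule
#'
#' Generates one 1000 Hz recording per run: drift (smooth random walk,
#' independent between eyes), tremor (band-passed noise, independent
#' between eyes), microsaccades (ballistic raised-cosine-velocity
#' displacements with Poisson timing, shared between eyes with probability
#' `binocular_correlation`), slow pupil fluctuations and binocular blinks.
#' With a nonzero confound coupling, microsaccade directions during
#' stimulus-on epochs become locked to an orientation-dependent axis.
#'
#' @param schedule An `experiment_schedule`.
#' @param params A `generator_params` object.
#' @param confound A `confound_spec` object; the default injects nothing,
#'   so generated data carry no orientation information.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return List of `gaze_recording` objects, one per run. Each carries the
#'   sample table (columns `time_ms, xl, yl, xr, yr, pl, pr, blink_l,
#'   blink_r`; positions in DVA, pupil in arbitrary units, blink-masked
#'   samples are `NA`) and the ground-truth event list.
#' @examples
#' sched <- build_schedule(sessions = 1, runs_per_session = 1,
#'                         trial_duration = 2, fixation_duration = 1)
#' rec <- simulate_recording(sched, seed = 7)
#' head(rec[[1]]$data)
#' @export
simulate_recording <- function(schedule, params = generator_params(),
                               confound = confound_spec(), seed = 1) {
  stopifnot(inherits(schedule, "experiment_schedule"))
  if (!inherits(params, "generator_params"))
    params <- do.call(generator_params, params)
  if (!inherits(confound, "confound_spec"))
    confound <- do.call(confound_spec, confound)
  nr <- n_runs(schedule)
  run_seeds <- derive_seeds(seed, nr)
  lapply(seq_len(nr), function(r)
    sim_run(r, schedule, params, confound, run_seeds[r]))
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("Gaze recording, run %d: %d samples at %g Hz, %d ground-truth events\n",
              x$run, nrow(x$data), x$sampling_rate, nrow(x$ground_truth)))
  invisible(x)
}
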