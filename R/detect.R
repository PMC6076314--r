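#' Microsaccade detection parameters
#'
#' @param lambda Threshold multiplier applied to the median-based velocity
#'   scale estimate; the classical velocity-threshold setting is 6.
#' @param min_duration_ms Minimum event duration in ms; events must
#'   strictly exceed this (6 ms means at least 2 samples at 256 Hz).
#' @param binocular_required If TRUE, only events that overlap in time
#'   between the two eyes are kept.
#' @return A `detection_params` list.
#' @export
detection_params <- function(lambda = 6, min_duration_ms = 6,
                             binocular_required = FALSE) {
  if (lambda <= 0 || min_duration_ms <= 0)
    gd_stop("lambda and min_duration_ms must be positive", "gd_invalid_params")
  structure(list(lambda = lambda, min_duration_ms = min_duration_ms,
                 binocular_required = binocular_required),
            class = "detection_params")
}

#' Moving-average velocity estimate
#'
#' Converts a position trace to velocity with the 5-point moving-average
#' derivative whose denominator spans six sample intervals:
#' `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`.
#' It is exact for linear signals and suppresses high-frequency noise.
#' The two boundary samples on each side are set to 0.
#'
#' @param xy n x 2 matrix of (x, y) positions.
#' @param fs Sampling rate in Hz.
#' @return n x 2 matrix of velocities (units of `xy` per second).
#' @export
compute_velocity <- function(xy, fs) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 5) gd_stop("need at least 5 samples", "gd_invalid_input")
  v <- matrix(0, n, ncol(xy))
  i <- 3:(n - 2)
  v[i, ] <- (xy[i + 2, ] + xy[i + 1, ] - xy[i - 1, ] - xy[i - 2, ]) * fs / 6
  v
}

#' Median-based velocity thresholds
#'
#' Per axis, the scale is `sigma = sqrt(median(v^2) - median(v)^2)` (a
#' median-based analogue of the standard deviation, robust to the saccadic
#' outliers being detected) and the threshold is `eta = lambda * sigma`.
#'
#' @param v n x 2 velocity matrix.
#' @param lambda Threshold multiplier.
#' @return Length-2 vector `(eta_x, eta_y)`.
#' @export
estimate_thresholds <- function(v, lambda = 6) {
  eta <- apply(as.matrix(v), 2, function(col) {
    s2 <- stats::median(col^2) - stats::median(col)^2
    if (s2 <= 0)
      gd_stop("degenerate velocity distribution (zero scale)",
              "gd_degenerate_velocity")
    lambda * sqrt(s2)
  })
  unname(eta)
}

#' Detect microsaccades as suprathreshold velocity excursions
#'
#' An event is a maximal run of consecutive samples whose velocity lies
#' outside the ellipse `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` and whose duration
#' strictly exceeds `min_duration_ms`. Onset/offset are 0-based half-open
#' sample indices; amplitude and direction are taken from the displacement
#' between the first and last suprathreshold sample.
#'
#' @param v n x 2 velocity matrix.
#' @param eta Length-2 thresholds from [estimate_thresholds()].
#' @param xy n x 2 position matrix (for amplitude/direction).
#' @param fs Sampling rate in Hz.
#' @param min_duration_ms Minimum duration (strict) in ms.
#' @return Data frame with columns `onset`, `offset`, `amplitude`,
#'   `direction`, `peak_velocity`, `duration_ms` (possibly 0 rows).
#' @export
detect_events <- function(v, eta, xy, fs, min_duration_ms = 6) {
  v <- as.matrix(v); xy <- as.matrix(xy)
  supra <- (v[, 1] / eta[1])^2 + (v[, 2] / eta[2])^2 > 1
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fs * 1000 > min_duration_ms)
  if (!any(keep)) {
    return(data.frame(onset = integer(), offset = integer(),
                      amplitude = numeric(), direction = numeric(),
                      peak_velocity = numeric(), duration_ms = numeric()))
  }
  i0 <- starts[keep]; i1 <- ends[keep]
  dx <- xy[i1, 1] - xy[i0, 1]
  dy <- xy[i1, 2] - xy[i0, 2]
  pk <- mapply(function(a, b) max(sqrt(v[a:b, 1]^2 + v[a:b, 2]^2)), i0, i1)
  data.frame(
    onset = i0 - 1L, offset = i1,   # 0-based half-open
    amplitude = sqrt(dx^2 + dy^2),
    direction = wrap360(rad2deg(atan2(dy, dx))),
    peak_velocity = pk,
    duration_ms = (i1 - i0 + 1L) / fs * 1000
  )
}

#' Discretize an angle into equal circular bins
#'
#' Half-open bins `[lo, hi)` of width `360 / n_bins`, 0-based: with 16 bins,
#' 0 deg falls in bin 0, 22.5 deg in bin 1, 359.9 deg in bin 15.
#'
#' @param angle_deg Angle(s) in degrees (any real value; reduced mod 360).
#' @param n_bins Number of bins (default 16).
#' @return Integer bin index/indices in `0 .. n_bins - 1`.
#' @export
bin_direction <- function(angle_deg, n_bins = 16) {
  stopifnot(n_bins >= 1)
  as.integer(floor((angle_deg %% 360) / (360 / n_bins)))
}

#' Detect microsaccades in preprocessed trials
#'
#' Runs velocity-threshold detection per eye on each (centered, 256 Hz)
#' trial tensor. Thresholds are estimated per trial and eye from the
#' trial's own velocity distribution.
#'
#' @param trials List of `trial_tensor` objects.
#' @param params A `detection_params` object.
#' @return Data frame of events with columns `trial`, `run`, `orientation`,
#'   `eye`, `onset`, `offset`, `amplitude`, `direction`, `peak_velocity`,
#'   `duration_ms`.
#' @export
detect_microsaccades <- function(trials, params = detection_params()) {
  eyes <- list(left = c("xl", "yl"), right = c("xr", "yr"))
  out <- lapply(trials, function(tr) {
    per_eye <- lapply(names(eyes), function(e) {
      xy <- t(tr$data[eyes[[e]], , drop = FALSE])
      v <- compute_velocity(xy, tr$sampling_rate)
      eta <- estimate_thresholds(v, params$lambda)
      ev <- detect_events(v, eta, xy, tr$sampling_rate,
                          params$min_duration_ms)
      if (nrow(ev) == 0) return(NULL)
      cbind(data.frame(trial = tr$trial, run = tr$run,
                       orientation = tr$orientation, eye = e), ev)
    })
    per_eye <- per_eye[!vapply(per_eye, is.null, logical(1))]
    if (length(per_eye) == 0) return(NULL)
    ev <- do.call(rbind, per_eye)
    if (isTRUE(params$binocular_required)) ev <- binocular_filter(ev)
    ev
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(trial = integer(), run = integer(),
                      orientation = numeric(), eye = character(),
                      onset = integer(), offset = integer(),
                      amplitude = numeric(), direction = numeric(),
                      peak_velocity = numeric(), duration_ms = numeric()))
  }
  rownames2 <- do.call(rbind, out)
  rownames(rownames2) <- NULL
  rownames2
}

# Keep only events overlapping in time between the two eyes (within trial).
binocular_filter <- function(ev) {
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    other <- ev$eye != ev$eye[i]
    keep[i] <- any(other & ev$onset < ev$offset[i] & ev$offset > ev$onset[i])
  }
  ev[keep, , drop = FALSE]
}

#' Write a detected-event table to a tab-separated file
#'
#' Columns: `run, trial, eye, onset_sample, offset_sample, amplitude_dva,
#' direction_deg, peak_vel` with half-open 0-based sample coordinates.
#'
#' @param events Event table from [detect_microsaccades()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(run = events$run, trial = events$trial, eye = events$eye,
                    onset_sample = events$onset, offset_sample = events$offset,
                    amplitude_dva = events$amplitude,
                    direction_deg = events$direction,
                    peak_vel = events$peak_velocity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
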