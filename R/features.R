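#' Eye-angle occupancy histogram
#'
#' Percentage of trial time the eye spent at each angle relative to the
#' fixation point (the origin of centered position data). Angles are
#' `atan2(y, x)` binned into `n_bins` half-open sectors. Samples exactly at
#' the origin have no defined angle and are excluded from the denominator;
#' for median-centered continuous data these form a measure-zero set.
#'
#' @param xy n x 2 matrix of centered (x, y) positions.
#' @param n_bins Number of angular bins (default 16).
#' @return Numeric vector of length `n_bins` summing to 100 (all zeros for
#'   the degenerate all-origin input).
#' @export
angle_occupancy <- function(xy, n_bins = 16) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 0) gd_stop("empty trial", "gd_invalid_input")
  r2 <- xy[, 1]^2 + xy[, 2]^2
  ok <- r2 > 0
  h <- numeric(n_bins)
  if (!any(ok)) return(h)
  ang <- wrap360(rad2deg(atan2(xy[ok, 2], xy[ok, 1])))
  b <- bin_direction(ang, n_bins)
  tab <- tabulate(b + 1L, nbins = n_bins)
  100 * tab / sum(tab)
}

# population SD (divide by n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summary-statistic feature vector for one trial
#'
#' The 76-dimensional per-trial feature vector: per eye, the mean and
#' standard deviation of x position, y position and pupil dilation
#' (12 values), the 16-bin eye-angle occupancy histogram (percent of trial
#' time) and the 16-bin microsaccade-direction histogram (event counts).
#' Concatenation order:
#' `[mu_xl, mu_yl, mu_pl, mu_xr, mu_yr, mu_pr,
#'   sd_xl, sd_yl, sd_pl, sd_xr, sd_yr, sd_pr,
#'   theta_el (16), theta_er (16), theta_ml (16), theta_mr (16)]`.
#' Standard deviations use the population convention (divide by n).
#'
#' @param trial A `trial_tensor`.
#' @param events Detected-event table restricted to any set containing this
#'   trial's events (filtered internally by trial id).
#' @param n_bins Number of angular bins (default 16).
#' @return Named numeric vector of length `12 + 4 * n_bins` (76 by default).
#' @export
summarize_trial <- function(trial, events, n_bins = 16) {
  d <- trial$data
  mu <- c(mean(d["xl", ]), mean(d["yl", ]), mean(d["pl", ]),
          mean(d["xr", ]), mean(d["yr", ]), mean(d["pr", ]))
  sds <- c(sd_pop(d["xl", ]), sd_pop(d["yl", ]), sd_pop(d["pl", ]),
           sd_pop(d["xr", ]), sd_pop(d["yr", ]), sd_pop(d["pr", ]))
  occ_l <- angle_occupancy(cbind(d["xl", ], d["yl", ]), n_bins)
  occ_r <- angle_occupancy(cbind(d["xr", ], d["yr", ]), n_bins)
  ev <- events[events$trial == trial$trial, , drop = FALSE]
  dir_hist <- function(eye) {
    ang <- ev$direction[ev$eye == eye]
    tabulate(bin_direction(ang, n_bins) + 1L, nbins = n_bins)
  }
  out <- c(mu, sds, occ_l, occ_r, dir_hist("left"), dir_hist("right"))
  names(out) <- c(
    "mu_xl", "mu_yl", "mu_pl", "mu_xr", "mu_yr", "mu_pr",
    "sd_xl", "sd_yl", "sd_pl", "sd_xr", "sd_yr", "sd_pr",
    paste0("theta_el_", seq_len(n_bins) - 1L),
    paste0("theta_er_", seq_len(n_bins) - 1L),
    paste0("theta_ml_", seq_len(n_bins) - 1L),
    paste0("theta_mr_", seq_len(n_bins) - 1L))
  out
}

#' Feature matrix for a set of trials
#'
#' @param trials List of `trial_tensor` objects.
#' @param events Detected-event table (from [detect_microsaccades()]).
#' @param n_bins Number of angular bins (default 16).
#' @return Data frame with metadata columns `trial`, `run`, `orientation`
#'   followed by the named feature columns (76 with default bins).
#' @export
feature_matrix <- function(trials, events, n_bins = 16) {
  feats <- t(vapply(trials, summarize_trial, events = events, n_bins = n_bins,
                    FUN.VALUE = numeric(12 + 4 * n_bins)))
  meta <- data.frame(
    trial = vapply(trials, function(t) t$trial, numeric(1)),
    run = vapply(trials, function(t) t$run, numeric(1)),
    orientation = vapply(trials, function(t) t$orientation, numeric(1)))
  cbind(meta, as.data.frame(feats))
}

#' Write a feature matrix to CSV
#'
#' @param features Data frame from [feature_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}
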