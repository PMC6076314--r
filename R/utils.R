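# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gazedecode_error")))
}

#' Derive independent sub-seeds from one master seed
#'
#' A single user-facing seed is fanned out into per-stage (or per-run,
#' per-participant) seeds so that stages draw from independent, reproducible
#' streams. Seeds stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

wrap360 <- function(deg) deg %% 360
wrap180 <- function(deg) deg %% 180

# von Mises sampler (Best & Fisher 1979 rejection); kappa = 0 is uniform.
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap360(rad2deg(out))
}

# Axial (mod 180) circular mean of directions in degrees, via doubled angles.
axial_mean <- function(deg) {
  a <- deg2rad(deg) * 2
  wrap180(rad2deg(atan2(mean(sin(a)), mean(cos(a))) / 2))
}

# Smallest absolute angular difference on a cycle of `period` degrees.
ang_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}
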