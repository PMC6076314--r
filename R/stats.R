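new_test_report <- function(statistic, p, alpha = 0.05, n_null = NA,
                            correction = "none", p_values = NULL,
                            threshold = alpha, extra = list()) {
  structure(c(list(statistic = statistic, p = p, alpha = alpha,
                   n_null = n_null, correction = correction,
                   decision = p < threshold, threshold = threshold,
                   p_values = p_values), extra),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("Test report: statistic %.4g, p = %.4g (alpha %.3g%s) -> %s\n",
              x$statistic, x$p, x$alpha,
              if (x$correction != "none")
                paste0(", ", x$correction, "-corrected") else "",
              if (isTRUE(x$decision)) "reject" else "retain"))
  invisible(x)
}

#' Label-permutation test for decoding accuracy
#'
#' Re-runs the complete cross-validated decoding pipeline with labels
#' permuted across the whole session (once per permutation, before the
#' fold loop) and compares the observed mean accuracy against the
#' permutation null. The p-value uses the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`, which is never
#' exactly zero and yields a valid test.
#'
#' @param decode_fn Function taking a label vector and returning the
#'   cross-validated mean accuracy (the full CV pipeline).
#' @param labels Observed label vector.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return A `test_report` with the observed accuracy, the p-value and the
#'   permutation distribution (`null_accuracies`).
#' @export
permutation_test <- function(decode_fn, labels, n_perm = 1000, alpha = 0.05,
                             seed = 1) {
  if (n_perm < 1) gd_stop("n_perm must be >= 1", "gd_invalid_params")
  observed <- decode_fn(labels)
  set.seed(seed)
  null_acc <- vapply(seq_len(n_perm),
                     function(i) decode_fn(sample(labels)), numeric(1))
  p <- (1 + sum(null_acc >= observed)) / (n_perm + 1)
  new_test_report(observed, p, alpha, n_null = n_perm,
                  extra = list(null_accuracies = null_acc))
}

# Exact one-sided (greater) zero-inclusive signed-rank p-value by
# convolution of the rank generating function; ranks may be tied
# half-integers, so they are doubled to integers.
pratt_exact_p <- function(w_obs, ranks_nonzero) {
  r2 <- round(2 * ranks_nonzero)
  dist <- numeric(sum(r2) + 1)  # index s+1 holds count of doubled-sum s
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  total <- 2^length(r2)
  s_obs <- round(2 * w_obs)
  sum(dist[(s_obs + 1):length(dist)]) / total
}

#' Group-level zero-inclusive Wilcoxon signed-rank test against chance
#'
#' One-sample, one-sided (greater) signed-rank test of per-participant
#' accuracies against chance level, with zero differences retained in the
#' ranking (the Pratt convention): all `|difference|` values, zeros
#' included, are ranked together; zeros then contribute to neither sign,
#' but inflate the ranks of the nonzero differences. The null distribution
#' is computed exactly (enumeration over sign assignments of the nonzero
#' differences) for `n <= exact_max`, and by a normal approximation with
#' continuity correction above.
#'
#' @param accuracies Per-participant accuracies in \[0, 1\].
#' @param chance Chance level (default 1/8 = 0.125).
#' @param alpha Significance level (default 0.05).
#' @param exact_max Largest sample size for exact enumeration (default 25).
#' @return A `test_report`; statistic is W+ (sum of positive-difference
#'   ranks). All differences zero gives p = 1 by convention.
#' @export
wilcoxon_group <- function(accuracies, chance = 0.125, alpha = 0.05,
                           exact_max = 25) {
  if (length(accuracies) < 2)
    gd_stop("need at least 2 participants", "gd_invalid_input")
  # rounding keeps ties tied in the presence of floating-point dust
  d <- signif(accuracies - chance, 10)
  ranks <- rank(abs(d))          # zeros included in the ranking
  nz <- d != 0
  w <- sum(ranks[d > 0])
  if (!any(nz))
    return(new_test_report(w, 1, alpha, extra = list(method = "pratt-exact")))
  if (length(d) <= exact_max) {
    p <- pratt_exact_p(w, ranks[nz])
    method <- "pratt-exact"
  } else {
    mu <- sum(ranks[nz]) / 2
    sigma <- sqrt(sum(ranks[nz]^2) / 4)
    p <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    method <- "pratt-normal"
  }
  new_test_report(w, p, alpha, extra = list(method = method))
}

#' Bonferroni correction over per-time-point p-values
#'
#' Declares a time point significant iff its raw p-value is below
#' `alpha / n_tests`; also reports Bonferroni-adjusted p-values
#' (`min(1, p * n)`).
#'
#' @param p_values Vector of raw p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `test_report`: `statistic` is the smallest raw p, `p` its
#'   adjusted value, plus `p_adjusted`, `significant` (logical vector) and
#'   the adjusted `threshold`.
#' @export
bonferroni_timepoints <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1)
  n <- length(p_values)
  thr <- alpha / n
  p_adj <- pmin(1, p_values * n)
  new_test_report(min(p_values), min(p_adj), alpha,
                  correction = "bonferroni", p_values = p_values,
                  threshold = alpha,
                  extra = list(p_adjusted = p_adj,
                               significant = p_values < thr,
                               raw_threshold = thr))
}
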