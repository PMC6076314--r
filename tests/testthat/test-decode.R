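test_that("leave-one-run-out folds partition trials by run", {
  sched <- build_schedule(seed = 1)
  folds <- make_folds(sched)
  expect_length(folds, 24)
  for (f in folds) {
    expect_length(f$train, 184)
    expect_length(f$test, 8)
    expect_length(intersect(f$train, f$test), 0)
  }
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, seq_len(192))          # each trial tested once
  expect_length(make_folds(c(1, 1, 2, 2)), 2)
  expect_error(make_folds(rep(1, 8)), class = "gd_invalid_input")
})

test_that("standardization uses training statistics for both splits", {
  set.seed(2)
  train <- cbind(rnorm(50, 5, 2), rnorm(50, -1, 0.5), rep(7, 50))
  test <- cbind(rnorm(10, 9, 2), rnorm(10, 0, 0.5), rep(9, 10))
  s <- standardize(train, test)
  expect_equal(unname(colMeans(s$train)[1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s$train, 2, sd)[1:2]), c(1, 1),
               tolerance = 1e-12)
  # constant training column: divided by 1, so train -> 0, test -> x - c
  expect_equal(s$train[, 3], rep(0, 50))
  expect_equal(s$test[, 3], rep(2, 10))
  # test transformed with train stats, not its own
  expect_equal(s$test[, 1], (test[, 1] - mean(train[, 1])) / sd(train[, 1]))
  expect_gt(abs(mean(s$test[, 1])), 0.5)          # not re-centered
  expect_error(standardize(train[1, , drop = FALSE], test),
               class = "gd_invalid_input")
})

# trials whose channels all carry an orientation-indexed offset (so the
# class signal survives per-feature standardization)
separable_trials <- function(n_runs = 2, len = 32, noise = 0.05, seed = 3) {
  set.seed(seed)
  oris <- seq(0, 157.5, by = 22.5)
  out <- list()
  for (r in seq_len(n_runs)) {
    for (k in seq_along(oris)) {
      d <- matrix(rnorm(6 * len, sd = noise), 6) + k
      out[[length(out) + 1]] <- mk_trial(
        d, trial = (r - 1) * 8 + k, run = r, orientation = oris[k])
    }
  }
  out
}

test_that("linearly separable raw data are decoded perfectly", {
  trials <- separable_trials(n_runs = 3)
  res <- svm_raw(trials)
  expect_s3_class(res, "decoding_result")
  expect_equal(res$mean_accuracy, 1)
  expect_length(res$fold_accuracies, 3)
})

test_that("permuting labels of separable data destroys raw decoding", {
  trials <- separable_trials(n_runs = 3)
  set.seed(4)
  res <- svm_raw(trials, labels = sample(trial_labels(trials)))
  expect_lt(res$mean_accuracy, 0.4)
})

# trials with flat gaze but microsaccade directions locked to the label:
# the summary features carry the class purely in the direction histograms,
# mimicking the injected confound
direction_coded_fixture <- function(n_runs = 3, seed = 5) {
  set.seed(seed)
  oris <- seq(0, 157.5, by = 22.5)
  trials <- list(); events <- list()
  for (r in seq_len(n_runs)) for (k in 1:8) {
    id <- (r - 1) * 8 + k
    trials[[id]] <- mk_trial(matrix(rnorm(6 * 32, sd = 0.1), 6), trial = id,
                             run = r, orientation = oris[k])
    # +11.25 centers the direction in a histogram bin, so adjacent
    # orientations occupy disjoint bins
    events[[id]] <- data.frame(
      trial = id, eye = rep(c("left", "right"), each = 4),
      direction = (oris[k] + 90 + 11.25 + rnorm(8, sd = 3)) %% 360)
  }
  list(trials = trials, events = do.call(rbind, events))
}

test_that("summary-statistics SVM decodes direction-locked microsaccades", {
  fx <- direction_coded_fixture()
  fm <- feature_matrix(fx$trials, fx$events)
  res <- svm_stats(fm)
  expect_gt(res$mean_accuracy, 0.9)
  # permuted labels: decoding collapses
  set.seed(6)
  resp <- svm_stats(fm, labels = sample(fm$orientation))
  expect_lt(resp$mean_accuracy, 0.4)
})

test_that("per-timepoint SVM localizes a temporally confined signal", {
  set.seed(6)
  oris <- seq(0, 157.5, by = 22.5)
  trials <- list()
  for (r in 1:3) for (k in 1:8) {
    d <- matrix(rnorm(6 * 24, sd = 0.05), 6)
    d[, 1:6] <- d[, 1:6] + k                # signal only in early samples
    trials[[length(trials) + 1]] <- mk_trial(
      d, trial = (r - 1) * 8 + k, run = r, orientation = oris[k])
  }
  res <- svm_timepoint(trials)
  expect_length(res$accuracy_by_time, 24)
  expect_gt(mean(res$accuracy_by_time[1:6]), 0.9)
  expect_lt(mean(res$accuracy_by_time[13:24]), 0.45)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies))
})

test_that("cached CV closure agrees with the direct implementation", {
  fx <- direction_coded_fixture(n_runs = 2)
  fm <- feature_matrix(fx$trials, fx$events)
  X <- as.matrix(fm[, -(1:3)])
  folds <- make_folds(fm$run)
  fn <- svm_cv_fn(X, folds)
  expect_equal(fn(fm$orientation), svm_stats(fm)$mean_accuracy)
})
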