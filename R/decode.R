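#' Leave-one-run-out fold splits
#'
#' One fold per run: that run's trials are the test set, all other runs'
#' trials the training set. With the default design each fold trains on
#' 23 runs (184 trials) and tests on 8.
#'
#' @param run_ids Run id per trial (vector), or an `experiment_schedule`.
#' @return List of folds, each a list with `run` (held-out run id),
#'   `train` and `test` (trial indices into the input order).
#' @export
make_folds <- function(run_ids) {
  if (inherits(run_ids, "experiment_schedule")) run_ids <- run_ids$trials$run
  runs <- unique(run_ids)
  if (length(runs) < 2)
    gd_stop("need at least 2 runs for leave-one-run-out CV",
            "gd_invalid_input")
  lapply(runs, function(r) {
    list(run = r, train = which(run_ids != r), test = which(run_ids == r))
  })
}

#' Standardize features using training-split statistics
#'
#' Per feature: subtract the training mean and divide by the training
#' standard deviation; the test split is transformed with the training
#' statistics. Zero-variance features are divided by 1.
#'
#' @param train,test Numeric matrices (rows = trials).
#' @return List with standardized `train` and `test`.
#' @export
standardize <- function(train, test) {
  if (nrow(train) < 2)
    gd_stop("training split needs at least 2 rows", "gd_invalid_input")
  mu <- colMeans(train)
  sdev <- apply(train, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdev, "/"))
}

new_decoding_result <- function(method, fold_acc, seed = NA,
                                accuracy_by_time = NULL, losses = NULL,
                                config = NULL) {
  structure(list(method = method, fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc), chance = 0.125,
                 accuracy_by_time = accuracy_by_time, losses = losses,
                 config = config, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result [%s]: mean accuracy %.3f over %d folds (chance %.3f)\n",
              x$method, x$mean_accuracy, length(x$fold_accuracies), x$chance))
  invisible(x)
}

# Linear one-vs-one SVM cross-validation on a trials x features matrix.
cv_svm <- function(X, labels, folds, cost = 1) {
  y <- factor(labels)
  vapply(folds, function(f) {
    s <- standardize(X[f$train, , drop = FALSE], X[f$test, , drop = FALSE])
    fit <- e1071::svm(s$train, y[f$train], kernel = "linear", cost = cost,
                      scale = FALSE, type = "C-classification")
    mean(stats::predict(fit, s$test) == y[f$test])
  }, numeric(1))
}

#' Build a label-to-accuracy cross-validation closure
#'
#' Precomputes the per-fold standardized train/test matrices (which do not
#' depend on the labels) and returns a function mapping a label vector to
#' the cross-validated mean accuracy. This is the natural `decode_fn` for
#' [permutation_test()], where only the labels change between calls.
#'
#' @param X Trials x features numeric matrix.
#' @param folds Folds from [make_folds()].
#' @param cost SVM regularization constant (default 1).
#' @return `function(labels) -> mean accuracy`.
#' @export
svm_cv_fn <- function(X, folds, cost = 1) {
  X <- as.matrix(X)
  cached <- lapply(folds, function(f) {
    s <- standardize(X[f$train, , drop = FALSE], X[f$test, , drop = FALSE])
    list(train_idx = f$train, test_idx = f$test,
         train = s$train, test = s$test)
  })
  function(labels) {
    y <- factor(labels)
    acc <- vapply(cached, function(f) {
      fit <- e1071::svm(f$train, y[f$train_idx], kernel = "linear",
                        cost = cost, scale = FALSE, type = "C-classification")
      mean(stats::predict(fit, f$test) == y[f$test_idx])
    }, numeric(1))
    mean(acc)
  }
}

trial_labels <- function(trials)
  vapply(trials, function(t) t$orientation, numeric(1))

trial_runs <- function(trials)
  vapply(trials, function(t) t$run, numeric(1))

flatten_trials <- function(trials) {
  t(vapply(trials, function(tr) as.numeric(t(tr$data)),
           numeric(nrow(trials[[1]]$data) * ncol(trials[[1]]$data))))
}

#' Decode orientation from raw trial time series with a linear SVM
#'
#' Flattens each trial's 6 x T channel matrix into one feature vector
#' (24576 values for 16 s trials at 256 Hz) and classifies it with a linear
#' one-vs-one SVM under the given folds, standardizing with training-split
#' statistics.
#'
#' @param trials List of `trial_tensor` objects.
#' @param folds Folds from [make_folds()] (defaults to leave-one-run-out
#'   over the trials' run ids).
#' @param cost SVM regularization constant (default 1).
#' @param labels Optional label vector overriding the trials' orientations
#'   (used by permutation testing).
#' @return A `decoding_result`.
#' @export
svm_raw <- function(trials, folds = make_folds(trial_runs(trials)), cost = 1,
                    labels = trial_labels(trials)) {
  X <- flatten_trials(trials)
  new_decoding_result("svm_raw", cv_svm(X, labels, folds, cost))
}

#' Decode orientation from summary statistics with a linear SVM
#'
#' Classifies the 76-dimensional per-trial summary-feature vectors
#' (means, standard deviations, eye-angle occupancy, microsaccade-direction
#' histograms) with a linear one-vs-one SVM under the given folds.
#'
#' @param features Feature data frame from [feature_matrix()], or a plain
#'   numeric matrix accompanied by `labels` and `folds`.
#' @param folds Folds from [make_folds()]; default leave-one-run-out using
#'   the feature table's `run` column.
#' @param cost SVM regularization constant (default 1).
#' @param labels Optional label vector (defaults to the `orientation`
#'   column).
#' @return A `decoding_result`.
#' @export
svm_stats <- function(features, folds = NULL, cost = 1, labels = NULL) {
  if (is.data.frame(features)) {
    meta <- intersect(c("trial", "run", "orientation"), names(features))
    X <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
    if (is.null(labels)) labels <- features$orientation
    if (is.null(folds)) folds <- make_folds(features$run)
  } else {
    X <- as.matrix(features)
    if (is.null(labels) || is.null(folds))
      gd_stop("matrix input requires explicit labels and folds",
              "gd_invalid_input")
  }
  new_decoding_result("svm_stats", cv_svm(X, labels, folds, cost))
}

#' Decode orientation at each time point with a linear SVM
#'
#' For every sample index, the six instantaneous channel values are
#' classified with a linear one-vs-one SVM under the given folds, yielding
#' an accuracy trace over time. Fold accuracies are averaged over time
#' points; `accuracy_by_time` holds the per-time-point fold means.
#'
#' @inheritParams svm_raw
#' @return A `decoding_result` with `accuracy_by_time` of length T.
#' @export
svm_timepoint <- function(trials, folds = make_folds(trial_runs(trials)),
                          cost = 1, labels = trial_labels(trials)) {
  T_len <- ncol(trials[[1]]$data)
  acc <- matrix(NA_real_, length(folds), T_len)
  for (tp in seq_len(T_len)) {
    X <- t(vapply(trials, function(tr) tr$data[, tp], numeric(6)))
    acc[, tp] <- cv_svm(X, labels, folds, cost)
  }
  new_decoding_result("svm_time", rowMeans(acc),
                      accuracy_by_time = colMeans(acc))
}
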