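test_that("uniform-probability classifier scores the ln(8) chance loss", {
  p <- matrix(1 / 8, nrow = 24, ncol = 8)
  expect_equal(cross_entropy(p, rep(1:8, 3)), log(8))
  expect_equal(round(cross_entropy(p, rep(1:8, 3)), 3), 2.079)
})

numeric_grad <- function(fn, par, nm, idx, eps = 1e-5) {
  up <- par; up[[nm]][idx] <- up[[nm]][idx] + eps
  dn <- par; dn[[nm]][idx] <- dn[[nm]][idx] - eps
  (fn(up) - fn(dn)) / (2 * eps)
}

test_that("CNN backpropagation matches numerical gradients", {
  set.seed(11)
  L <- 100
  X <- matrix(rnorm(6 * L), 6)
  y <- 3L
  par <- gazedecode:::cnn_init(L, 6, 8)
  loss_fn <- function(p) {
    fw <- gazedecode:::cnn_forward(X, p)
    pr <- gazedecode:::softmax_rows(matrix(fw$logits, 1))[1, ]
    -log(pr[y])
  }
  fw <- gazedecode:::cnn_forward(X, par, keep_cache = TRUE)
  pr <- gazedecode:::softmax_rows(matrix(fw$logits, 1))[1, ]
  dl <- pr; dl[y] <- dl[y] - 1
  g <- gazedecode:::cnn_backward(dl, par, fw$cache)
  for (nm in c("W1", "b2", "W3", "W4", "b4", "W5", "b5")) {
    for (idx in c(1L, length(par[[nm]]))) {
      expect_equal(g[[nm]][idx], numeric_grad(loss_fn, par, nm, idx),
                   tolerance = 1e-4)
    }
  }
})

test_that("LSTM backpropagation matches numerical gradients", {
  set.seed(12)
  B <- 3; Tt <- 6
  X <- array(rnorm(B * 6 * Tt), c(B, 6, Tt))
  y <- c(1L, 4L, 8L)
  par <- gazedecode:::lstm_init(6, 5, 8)
  loss_fn <- function(p) {
    h <- gazedecode:::lstm_forward(X, p)$h
    pr <- gazedecode:::softmax_rows(h %*% p$Wo +
      matrix(p$bo, B, 8, byrow = TRUE))
    gazedecode::cross_entropy(pr, y)
  }
  fw <- gazedecode:::lstm_forward(X, par, keep_cache = TRUE)
  pr <- gazedecode:::softmax_rows(fw$h %*% par$Wo +
    matrix(par$bo, B, 8, byrow = TRUE))
  dlog <- pr; dlog[cbind(1:B, y)] <- dlog[cbind(1:B, y)] - 1
  dlog <- dlog / B
  g <- list(Wo = t(fw$h) %*% dlog, bo = colSums(dlog))
  g <- c(g, gazedecode:::lstm_backward(dlog %*% t(par$Wo), par, fw$cache))
  for (nm in c("Wx", "Wh", "b", "Wo", "bo")) {
    for (idx in c(1L, length(par[[nm]]))) {
      expect_equal(g[[nm]][idx], numeric_grad(loss_fn, par, nm, idx),
                   tolerance = 1e-4)
    }
  }
})

# short trials whose channel means encode the orientation
coded_trials <- function(n_runs, len, scale = 1, seed = 13) {
  set.seed(seed)
  oris <- seq(0, 157.5, by = 22.5)
  out <- list()
  for (r in seq_len(n_runs)) for (k in 1:8) {
    d <- matrix(rnorm(6 * len, sd = 0.3), 6) + scale * k
    out[[length(out) + 1]] <- mk_trial(
      d, trial = (r - 1) * 8 + k, run = r, orientation = oris[k])
  }
  out
}

test_that("CNN learns a strongly coded signal and records loss curves", {
  trials <- coded_trials(4, len = 100, scale = 2)
  res <- cnn_decode(trials, config = train_config(epochs = 30, seed = 1,
                                                  batch_size = 8))
  expect_s3_class(res, "decoding_result")
  expect_length(res$fold_accuracies, 4)
  expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 1))
  h <- res$losses[[1]]
  expect_equal(nrow(h), 30)
  # training loss falls well below the chance plateau on separable data
  expect_lt(tail(h$train_loss, 1), 0.6 * log(8))
  expect_gt(res$mean_accuracy, 0.4)
})

test_that("CNN rejects inputs shorter than the convolutional stack", {
  trials <- coded_trials(2, len = 40)
  expect_error(cnn_decode(trials, config = train_config(epochs = 1)),
               class = "gd_invalid_config")
})

test_that("LSTM learns an integrable signal", {
  trials <- coded_trials(4, len = 40, scale = 2)
  res <- rnn_decode(trials, config = train_config(epochs = 40, seed = 2,
                                                  batch_size = 8))
  expect_length(res$fold_accuracies, 4)
  expect_gt(res$mean_accuracy, 0.4)
  expect_lt(tail(res$losses[[1]]$train_loss, 1), log(8))
})

test_that("neural decoders are seed-reproducible", {
  trials <- coded_trials(2, len = 100)
  cfg <- train_config(epochs = 3, seed = 7, batch_size = 8)
  a <- cnn_decode(trials, config = cfg)
  b <- cnn_decode(trials, config = cfg)
  expect_identical(a$fold_accuracies, b$fold_accuracies)
  expect_identical(a$losses, b$losses)
})
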