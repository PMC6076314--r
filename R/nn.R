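# Minimal neural-network layer kit: 1-D convolution (im2col), max pooling,
# dense layers, LSTM, softmax cross-entropy, Adam. Written for clarity and
# small-data decoding experiments, not for GPU-scale throughput.

#' Training configuration for the neural decoders
#'
#' @param epochs Training epochs (default 100).
#' @param alpha Adam learning rate (default 0.001).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, alpha = 0.001, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 32, seed = 1) {
  if (epochs < 1) gd_stop("epochs must be >= 1", "gd_invalid_params")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    gd_stop("Adam betas must lie in (0, 1)", "gd_invalid_params")
  structure(list(epochs = epochs, alpha = alpha, beta1 = beta1,
                 beta2 = beta2, batch_size = batch_size, seed = seed),
            class = "train_config")
}

#' Multiclass cross-entropy loss
#'
#' Mean negative log predicted probability of the true class. A classifier
#' emitting the uniform distribution over `k` classes scores `log(k)`
#' (2.079 for 8 classes), the best attainable loss when no feature is
#' predictive and classes are balanced.
#'
#' @param prob n x k matrix of predicted class probabilities.
#' @param labels Integer class indices in `1..k` (or a factor).
#' @return Mean cross-entropy (nats).
#' @export
cross_entropy <- function(prob, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  p <- prob[cbind(seq_len(nrow(prob)), labels)]
  mean(-log(pmax(p, 1e-12)))
}

# ---- layer primitives (single sample: X is channels x length) -------------

im2col <- function(X, k) {
  C <- nrow(X); Lout <- ncol(X) - k + 1
  cols <- matrix(0, C * k, Lout)
  for (j in seq_len(k))
    cols[(j - 1) * C + seq_len(C), ] <- X[, j:(j + Lout - 1), drop = FALSE]
  cols
}

col2im <- function(dcols, C, k, L) {
  dX <- matrix(0, C, L)
  Lout <- L - k + 1
  for (j in seq_len(k)) {
    idx <- j:(j + Lout - 1)
    dX[, idx] <- dX[, idx] + dcols[(j - 1) * C + seq_len(C), , drop = FALSE]
  }
  dX
}

conv_fwd <- function(X, W, b, k) {
  cols <- im2col(X, k)
  list(out = W %*% cols + b, cols = cols)
}

conv_bwd <- function(dY, cache_cols, W, C, k, L) {
  list(dW = dY %*% t(cache_cols), db = rowSums(dY),
       dX = col2im(t(W) %*% dY, C, k, L))
}

pool_fwd <- function(X) {
  Lp <- floor(ncol(X) / 2)
  a <- X[, 2 * seq_len(Lp) - 1, drop = FALSE]
  b <- X[, 2 * seq_len(Lp), drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a, L = ncol(X))
}

pool_bwd <- function(dY, cache) {
  dX <- matrix(0, nrow(dY), cache$L)
  Lp <- ncol(dY)
  dX[, 2 * seq_len(Lp) - 1] <- dY * cache$take_a
  dX[, 2 * seq_len(Lp)] <- dY * !cache$take_a
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1
  a <- cfg$alpha * sqrt(1 - cfg$beta2^state$t) / (1 - cfg$beta1^state$t)
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] +
      (1 - cfg$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      a * state$m[[nm]] / (sqrt(state$v[[nm]]) + 1e-8)
  }
  list(params = params, state = state)
}

# ---- CNN ------------------------------------------------------------------

# conv(6, k=32) -> ReLU -> pool2 -> conv(16, k=16) -> ReLU -> pool2
#   -> conv(120, k=8) -> ReLU -> flatten -> dense 84 (ReLU) -> dense 8
CNN_SHAPE <- list(f1 = 6, k1 = 32, f2 = 16, k2 = 16, f3 = 120, k3 = 8,
                  fc = 84)

cnn_dims <- function(L, n_channels = 6) {
  s <- CNN_SHAPE
  L1 <- L - s$k1 + 1; P1 <- floor(L1 / 2)
  L2 <- P1 - s$k2 + 1; P2 <- floor(L2 / 2)
  L3 <- P2 - s$k3 + 1
  if (L1 < 1 || L2 < 1 || L3 < 1)
    gd_stop(sprintf("input length %d too short for the convolutional stack", L),
            "gd_invalid_config")
  list(L1 = L1, P1 = P1, L2 = L2, P2 = P2, L3 = L3,
       flat = s$f3 * L3)
}

cnn_init <- function(L, n_channels = 6, n_classes = 8) {
  s <- CNN_SHAPE
  d <- cnn_dims(L, n_channels)
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  list(
    W1 = he(s$f1, n_channels * s$k1), b1 = numeric(s$f1),
    W2 = he(s$f2, s$f1 * s$k2), b2 = numeric(s$f2),
    W3 = he(s$f3, s$f2 * s$k3), b3 = numeric(s$f3),
    W4 = he(s$fc, d$flat), b4 = numeric(s$fc),
    W5 = matrix(rnorm(n_classes * s$fc, sd = sqrt(1 / s$fc)), n_classes,
                s$fc), b5 = numeric(n_classes)
  )
}

cnn_forward <- function(X, par, keep_cache = FALSE) {
  s <- CNN_SHAPE
  c1 <- conv_fwd(X, par$W1, par$b1, s$k1); a1 <- pmax(c1$out, 0)
  p1 <- pool_fwd(a1)
  c2 <- conv_fwd(p1$out, par$W2, par$b2, s$k2); a2 <- pmax(c2$out, 0)
  p2 <- pool_fwd(a2)
  c3 <- conv_fwd(p2$out, par$W3, par$b3, s$k3); a3 <- pmax(c3$out, 0)
  flat <- as.numeric(a3)
  z4 <- as.numeric(par$W4 %*% flat + par$b4); a4 <- pmax(z4, 0)
  z5 <- as.numeric(par$W5 %*% a4 + par$b5)
  out <- list(logits = z5)
  if (keep_cache)
    out$cache <- list(X = X, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                      p2 = p2, c3 = c3, a3 = a3, flat = flat, a4 = a4)
  out
}

cnn_backward <- function(dlogits, par, cache) {
  s <- CNN_SHAPE
  g <- list()
  g$W5 <- outer(dlogits, cache$a4); g$b5 <- dlogits
  da4 <- as.numeric(t(par$W5) %*% dlogits) * (cache$a4 > 0)
  g$W4 <- outer(da4, cache$flat); g$b4 <- da4
  dflat <- as.numeric(t(par$W4) %*% da4)
  da3 <- matrix(dflat, nrow(cache$a3), ncol(cache$a3)) * (cache$a3 > 0)
  bw3 <- conv_bwd(da3, cache$c3$cols, par$W3, nrow(cache$p2$out), s$k3,
                  ncol(cache$p2$out))
  g$W3 <- bw3$dW; g$b3 <- bw3$db
  da2 <- pool_bwd(bw3$dX, cache$p2) * (cache$a2 > 0)
  bw2 <- conv_bwd(da2, cache$c2$cols, par$W2, nrow(cache$p1$out), s$k2,
                  ncol(cache$p1$out))
  g$W2 <- bw2$dW; g$b2 <- bw2$db
  da1 <- pool_bwd(bw2$dX, cache$p1) * (cache$a1 > 0)
  bw1 <- conv_bwd(da1, cache$c1$cols, par$W1, nrow(cache$X), s$k1,
                  ncol(cache$X))
  g$W1 <- bw1$dW; g$b1 <- bw1$db
  g
}

cnn_predict_prob <- function(Xlist, par) {
  logits <- t(vapply(Xlist, function(X) cnn_forward(X, par)$logits,
                     numeric(length(par$b5))))
  softmax_rows(logits)
}

# Train the CNN on a list of channels x length matrices.
cnn_train <- function(Xtrain, ytrain, cfg, Xval = NULL, yval = NULL) {
  set.seed(cfg$seed)
  n <- length(Xtrain)
  par <- cnn_init(ncol(Xtrain[[1]]), nrow(Xtrain[[1]]),
                  n_classes = length(unique(ytrain)))
  st <- adam_init(par)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_, val_acc = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      grads <- NULL
      bl <- 0
      for (i in idx) {
        fw <- cnn_forward(Xtrain[[i]], par, keep_cache = TRUE)
        p <- softmax_rows(matrix(fw$logits, 1))[1, ]
        bl <- bl - log(max(p[ytrain[i]], 1e-12))
        dl <- p; dl[ytrain[i]] <- dl[ytrain[i]] - 1
        g <- cnn_backward(dl / length(idx), par, fw$cache)
        grads <- if (is.null(grads)) g else
          Map(`+`, grads, g)
      }
      upd <- adam_step(par, grads, st, cfg)
      par <- upd$params; st <- upd$state
      losses <- c(losses, bl / length(idx))
    }
    hist$train_loss[ep] <- mean(losses)
    if (!is.null(Xval)) {
      pv <- cnn_predict_prob(Xval, par)
      hist$val_loss[ep] <- cross_entropy(pv, yval)
      hist$val_acc[ep] <- mean(max.col(pv) == yval)
    }
  }
  list(params = par, history = hist)
}

# ---- LSTM -----------------------------------------------------------------

lstm_init <- function(n_in = 6, n_units = 20, n_classes = 8) {
  gl <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  b0 <- numeric(4 * n_units)
  b0[n_units + seq_len(n_units)] <- 1  # forget-gate bias
  list(Wx = gl(n_in, 4 * n_units), Wh = gl(n_units, 4 * n_units), b = b0,
       Wo = gl(n_units, n_classes), bo = numeric(n_classes))
}

sigm <- function(x) 1 / (1 + exp(-x))

# X: batch x channels x time array. Returns final hidden state and caches.
lstm_forward <- function(X, par, keep_cache = FALSE) {
  B <- dim(X)[1]; Tt <- dim(X)[3]; H <- ncol(par$Wh)
  nu <- H / 4
  h <- matrix(0, B, nu); cc <- matrix(0, B, nu)
  cache <- if (keep_cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    xt <- X[, , t, drop = FALSE]; dim(xt) <- dim(X)[1:2]
    z <- xt %*% par$Wx + h %*% par$Wh +
      matrix(par$b, B, H, byrow = TRUE)
    i <- sigm(z[, seq_len(nu), drop = FALSE])
    f <- sigm(z[, nu + seq_len(nu), drop = FALSE])
    o <- sigm(z[, 2 * nu + seq_len(nu), drop = FALSE])
    g <- tanh(z[, 3 * nu + seq_len(nu), drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    if (keep_cache)
      cache[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f,
                         o = o, g = g, c = c_new)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(dh_last, par, cache) {
  Tt <- length(cache)
  nu <- ncol(dh_last)
  g <- list(Wx = par$Wx * 0, Wh = par$Wh * 0, b = par$b * 0)
  dh <- dh_last
  dc <- matrix(0, nrow(dh), nu)
  for (t in rev(seq_len(Tt))) {
    ca <- cache[[t]]
    tc <- tanh(ca$c)
    do_ <- dh * tc * ca$o * (1 - ca$o)
    dc <- dc + dh * ca$o * (1 - tc^2)
    di <- dc * ca$g * ca$i * (1 - ca$i)
    df <- dc * ca$c_prev * ca$f * (1 - ca$f)
    dg <- dc * ca$i * (1 - ca$g^2)
    dz <- cbind(di, df, do_, dg)
    g$Wx <- g$Wx + t(ca$xt) %*% dz
    g$Wh <- g$Wh + t(ca$h_prev) %*% dz
    g$b <- g$b + colSums(dz)
    dh <- dz %*% t(par$Wh)
    dc <- dc * ca$f
  }
  g
}

lstm_predict_prob <- function(X, par) {
  h <- lstm_forward(X, par)$h
  softmax_rows(h %*% par$Wo + matrix(par$bo, nrow(h), length(par$bo),
                                     byrow = TRUE))
}

lstm_train <- function(Xtrain, ytrain, cfg, Xval = NULL, yval = NULL,
                       n_units = 20) {
  set.seed(cfg$seed)
  n <- dim(Xtrain)[1]
  par <- lstm_init(dim(Xtrain)[2], n_units, length(unique(ytrain)))
  st <- adam_init(par)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_, val_acc = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- Xtrain[idx, , , drop = FALSE]
      fw <- lstm_forward(Xb, par, keep_cache = TRUE)
      logits <- fw$h %*% par$Wo +
        matrix(par$bo, length(idx), length(par$bo), byrow = TRUE)
      p <- softmax_rows(logits)
      yb <- ytrain[idx]
      losses <- c(losses, cross_entropy(p, yb))
      dlog <- p
      dlog[cbind(seq_along(idx), yb)] <- dlog[cbind(seq_along(idx), yb)] - 1
      dlog <- dlog / length(idx)
      g <- list(Wo = t(fw$h) %*% dlog, bo = colSums(dlog))
      dh <- dlog %*% t(par$Wo)
      g <- c(g, lstm_backward(dh, par, fw$cache))
      upd <- adam_step(par, g[names(par)], st, cfg)
      par <- upd$params; st <- upd$state
    }
    hist$train_loss[ep] <- mean(losses)
    if (!is.null(Xval)) {
      pv <- lstm_predict_prob(Xval, par)
      hist$val_loss[ep] <- cross_entropy(pv, yval)
      hist$val_acc[ep] <- mean(max.col(pv) == yval)
    }
  }
  list(params = par, history = hist)
}

# ---- decoders -------------------------------------------------------------

# Standardize trials per channel-timepoint feature using training statistics,
# returning a list of channels x length matrices (and optionally an array).
standardize_trials <- function(trials, train_idx, test_idx) {
  X <- flatten_trials(trials)
  s <- standardize(X[train_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
  C <- nrow(trials[[1]]$data); L <- ncol(trials[[1]]$data)
  tolist <- function(M) lapply(seq_len(nrow(M)), function(i)
    matrix(M[i, ], C, L, byrow = TRUE))
  list(train = tolist(s$train), test = tolist(s$test))
}

#' Decode orientation with a 1-D convolutional network
#'
#' A LeNet-style 1-D CNN: three convolutional layers (6 kernels of 32
#' samples, 16 of 16, 120 of 8; stride 1, no padding), ReLU activations,
#' max pooling (window 2, stride 2) after the first two convolutions, then
#' fully connected layers of 84 and `n_classes` units with a softmax
#' output. Trained per fold with Adam and a cross-entropy loss; the
#' held-out fold serves as validation set, whose per-epoch loss and
#' accuracy are recorded alongside the training loss.
#'
#' @inheritParams svm_raw
#' @param config A [train_config()].
#' @return A `decoding_result` with per-fold `losses` histories.
#' @export
cnn_decode <- function(trials, folds = make_folds(trial_runs(trials)),
                       config = train_config(),
                       labels = trial_labels(trials)) {
  y <- as.integer(factor(labels))
  fold_seeds <- derive_seeds(config$seed, length(folds))
  acc <- numeric(length(folds))
  hists <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    s <- standardize_trials(trials, f$train, f$test)
    cfg <- config; cfg$seed <- fold_seeds[k]
    fit <- cnn_train(s$train, y[f$train], cfg, s$test, y[f$test])
    pv <- cnn_predict_prob(s$test, fit$params)
    acc[k] <- mean(max.col(pv) == y[f$test])
    hists[[k]] <- fit$history
  }
  new_decoding_result("cnn", acc, seed = config$seed, losses = hists,
                      config = config)
}

#' Decode orientation with an LSTM recurrent network
#'
#' A 20-unit LSTM consumes the 6-channel sequence one time point at a
#' time; its final hidden state feeds a fully connected softmax layer with
#' one output per orientation. Trained per fold with Adam and a
#' cross-entropy loss, validation on the held-out fold.
#'
#' @inheritParams cnn_decode
#' @param n_units Number of LSTM units (default 20).
#' @param stride Optional temporal subsampling factor applied to the input
#'   sequence before training (default 1 = no subsampling).
#' @return A `decoding_result` with per-fold `losses` histories.
#' @export
rnn_decode <- function(trials, folds = make_folds(trial_runs(trials)),
                       config = train_config(),
                       labels = trial_labels(trials), n_units = 20,
                       stride = 1) {
  y <- as.integer(factor(labels))
  C <- nrow(trials[[1]]$data); L <- ncol(trials[[1]]$data)
  keep <- seq(1, L, by = stride)
  fold_seeds <- derive_seeds(config$seed, length(folds))
  acc <- numeric(length(folds))
  hists <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    s <- standardize_trials(trials, f$train, f$test)
    toarr <- function(lst) {
      A <- array(0, c(length(lst), C, length(keep)))
      for (i in seq_along(lst)) A[i, , ] <- lst[[i]][, keep, drop = FALSE]
      A
    }
    cfg <- config; cfg$seed <- fold_seeds[k]
    fit <- lstm_train(toarr(s$train), y[f$train], cfg, toarr(s$test),
                      y[f$test], n_units)
    pv <- lstm_predict_prob(toarr(s$test), fit$params)
    acc[k] <- mean(max.col(pv) == y[f$test])
    hists[[k]] <- fit$history
  }
  new_decoding_result("rnn", acc, seed = config$seed, losses = hists,
                      config = config)
}
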