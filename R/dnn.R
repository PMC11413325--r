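# Sequence-to-sequence LSTM forecaster, implemented in-package with
# vectorised matrix algebra: one LSTM layer, one ReLU dense layer and a
# linear output layer emitting all horizon steps at once. He-uniform
# initialisation, Adam optimiser, mean-square-error loss, and a
# reduce-on-plateau learning-rate schedule. Training is fully seeded.

#' LSTM training specification
#'
#' @param history_length input window length L in steps.
#' @param horizon_steps output dimension: prediction horizon in 5-min steps
#'   (6 for 30 min, 12 for 60 min).
#' @param hidden_units LSTM state width.
#' @param dense_units width of the ReLU dense layer between the LSTM and
#'   the linear output.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param initial_lr initial Adam learning rate.
#' @param lr_factor multiplier applied to the learning rate when the
#'   validation loss stops improving.
#' @param lr_patience epochs without validation-loss improvement before the
#'   learning rate is reduced.
#' @param validation_fraction final fraction of training windows held out,
#'   time-ordered, to drive the schedule.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return an object of class `lstm_spec`.
#' @export
lstm_spec <- function(history_length = 12, horizon_steps = 6,
                      hidden_units = 128, dense_units = 64,
                      epochs = 200, batch_size = 32,
                      initial_lr = 0.01, lr_factor = 0.1, lr_patience = 20,
                      validation_fraction = 0.2, seed = 1L) {
  if (epochs <= 0 || batch_size <= 0) stopf("epochs and batch_size must be positive")
  structure(list(history_length = history_length,
                 horizon_steps = horizon_steps,
                 hidden_units = hidden_units, dense_units = dense_units,
                 epochs = epochs, batch_size = batch_size,
                 initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_patience = lr_patience,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "lstm_spec")
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

lstm_init <- function(C, Hd, Dd, Hout) {
  list(Wx = he_uniform(C, 4 * Hd, C),
       Wh = he_uniform(Hd, 4 * Hd, Hd),
       b = matrix(0, 1, 4 * Hd),
       Wd = he_uniform(Hd, Dd, Hd),
       bd = matrix(0, 1, Dd),
       Wo = he_uniform(Dd, Hout, Dd),
       bo = matrix(0, 1, Hout))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass over a batch; X is B x L x C, returns prediction and cache
lstm_forward <- function(X, W, keep_cache = TRUE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  Hd <- nrow(W$Wh)
  h <- matrix(0, B, Hd); cs <- matrix(0, B, Hd)
  cache <- if (keep_cache) vector("list", L) else NULL
  ones <- rep(1, B)
  for (t in seq_len(L)) {
    Xt <- X[, t, , drop = FALSE]; dim(Xt) <- c(B, dim(X)[3])
    Z <- Xt %*% W$Wx + h %*% W$Wh + ones %*% W$b
    i <- sigmoid(Z[, 1:Hd, drop = FALSE])
    f <- sigmoid(Z[, (Hd + 1):(2 * Hd), drop = FALSE])
    o <- sigmoid(Z[, (2 * Hd + 1):(3 * Hd), drop = FALSE])
    g <- tanh(Z[, (3 * Hd + 1):(4 * Hd), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(Xt = Xt, h_prev = h, c_prev = c_prev,
                         i = i, f = f, o = o, g = g, tc = tc)
    h <- h_new
  }
  Dpre <- h %*% W$Wd + ones %*% W$bd
  D <- pmax(Dpre, 0)
  Y <- D %*% W$Wo + ones %*% W$bo
  list(Y = Y, h = h, D = D, Dpre = Dpre, cache = cache)
}

# gradients of the mean-square-error loss w.r.t. all weights
lstm_backward <- function(X, T_mat, W, fw) {
  B <- dim(X)[1]; L <- dim(X)[2]
  Hd <- nrow(W$Wh)
  dY <- 2 * (fw$Y - T_mat) / length(T_mat)
  gWo <- t(fw$D) %*% dY
  gbo <- matrix(colSums(dY), 1)
  dD <- dY %*% t(W$Wo)
  dD[fw$Dpre <= 0] <- 0
  gWd <- t(fw$h) %*% dD
  gbd <- matrix(colSums(dD), 1)
  dh <- dD %*% t(W$Wd)
  dc <- matrix(0, B, Hd)
  gWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
  gWh <- matrix(0, Hd, 4 * Hd)
  gb <- matrix(0, 1, 4 * Hd)
  for (t in rev(seq_len(L))) {
    ca <- fw$cache[[t]]
    do_ <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dZ <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o),
                dg * (1 - ca$g^2))
    gWx <- gWx + t(ca$Xt) %*% dZ
    gWh <- gWh + t(ca$h_prev) %*% dZ
    gb <- gb + colSums(dZ)
    dh <- dZ %*% t(W$Wh)
    dc <- dc * ca$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

adam_step <- function(W, G, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(G)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * G[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * G[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(W = W, state = state)
}

# frame -> scaled arrays: X (n x L x C) and T (n x H)
frame_tensors <- function(frame, scalers = NULL) {
  n <- length(frame$inputs)
  L <- frame$history_length; C <- length(frame$channels)
  H <- frame$horizon
  X <- array(0, c(n, L, C))
  for (i in seq_len(n)) X[i, , ] <- frame$inputs[[i]]
  T_mat <- t(vapply(frame$targets, as.numeric, numeric(H)))
  if (is.null(scalers)) {
    scalers <- list(
      x = lapply(seq_len(C), function(j) fit_minmax(as.numeric(X[, , j]))),
      y = fit_minmax(as.numeric(T_mat)))
  }
  for (j in seq_len(C)) X[, , j] <- apply_minmax(X[, , j], scalers$x[[j]])
  list(X = X, T_scaled = apply_minmax(T_mat, scalers$y), T_raw = T_mat,
       scalers = scalers)
}

#' Fit and predict with the sequence-to-sequence LSTM
#'
#' Trains the network on min-max-scaled training windows and predicts the
#' full horizon sequence at every test window; the value scored downstream
#' is the final horizon step. The learning rate is reduced by `lr_factor`
#' after `lr_patience` epochs without improvement of the validation loss
#' (time-ordered final fraction of the training windows). Training aborts
#' with diagnostics if the loss becomes non-finite. Deterministic given
#' `spec$seed`.
#'
#' @param frame_train,frame_test matching [reframe()] frames.
#' @param spec an [lstm_spec()]; its `history_length`/`horizon_steps` must
#'   match the frames.
#' @return a [forecast_series()] with an attribute `history` holding the
#'   per-epoch training and validation loss.
#' @export
fit_predict_dnn <- function(frame_train, frame_test, spec) {
  if (spec$history_length != frame_train$history_length ||
      spec$horizon_steps != frame_train$horizon)
    stopf("spec dimensions do not match the training frame")
  if (frame_train$history_length != frame_test$history_length ||
      frame_train$horizon != frame_test$horizon ||
      !identical(frame_train$channels, frame_test$channels))
    stopf("train and test frames must share L, H and channels")

  tr <- frame_tensors(frame_train)
  te <- frame_tensors(frame_test, tr$scalers)
  n <- dim(tr$X)[1]; C <- dim(tr$X)[3]
  n_val <- max(1, floor(n * spec$validation_fraction))
  fit_idx <- seq_len(n - n_val); val_idx <- (n - n_val + 1):n

  with_seed(spec$seed, {
    W <- lstm_init(C, spec$hidden_units, spec$dense_units, spec$horizon_steps)
    state <- list(t = 0,
                  m = lapply(W, function(w) w * 0),
                  v = lapply(W, function(w) w * 0))
    lr <- spec$initial_lr
    best_val <- Inf; stall <- 0
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), lr = numeric(0))
    Xv <- tr$X[val_idx, , , drop = FALSE]
    Tv <- tr$T_scaled[val_idx, , drop = FALSE]
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(fit_idx)
      batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        Xb <- tr$X[bi, , , drop = FALSE]
        Tb <- tr$T_scaled[bi, , drop = FALSE]
        fw <- lstm_forward(Xb, W)
        loss <- mean((fw$Y - Tb)^2)
        if (!is.finite(loss))
          stopf("LSTM training diverged (non-finite loss) at epoch %d; lr=%g",
                ep, lr)
        ep_loss <- ep_loss + loss * length(bi)
        G <- lstm_backward(Xb, Tb, W, fw)
        upd <- adam_step(W, G, state, lr)
        W <- upd$W; state <- upd$state
      }
      vw <- lstm_forward(Xv, W, keep_cache = FALSE)
      val_loss <- mean((vw$Y - Tv)^2)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / length(ord),
                                     val_loss = val_loss, lr = lr))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= spec$lr_patience) {
          lr <- lr * spec$lr_factor
          stall <- 0
        }
      }
    }
    fw_te <- lstm_forward(te$X, W, keep_cache = FALSE)
    pred <- invert_minmax(fw_te$Y[, spec$horizon_steps], tr$scalers$y)
    out <- forecast_series(
      target_times = frame_test$target_times,
      predicted = as.numeric(pred),
      reference = te$T_raw[, spec$horizon_steps],
      horizon = frame_test$horizon * minutes_per_step(frame_test),
      model = "dnn", input_mode = frame_test$mode,
      reference_imputed = frame_test$target_imputed)
    attr(out, "history") <- hist
    out
  })
}

#' Repeat LSTM training over several seeds
#'
#' The network's random initialisation makes single runs noisy, so the
#' study protocol trains the same configuration several times (default 10)
#' and reports each metric as mean and standard deviation across runs.
#'
#' @param frame_train,frame_test matching [reframe()] frames.
#' @param spec an [lstm_spec()]; run `r` uses seed `spec$seed + r - 1`.
#' @param runs number of seeded repetitions.
#' @return list of [forecast_series()], one per run.
#' @export
fit_predict_dnn_runs <- function(frame_train, frame_test, spec, runs = 10) {
  lapply(seq_len(runs), function(r) {
    sp <- spec; sp$seed <- spec$seed + r - 1L
    fit_predict_dnn(frame_train, frame_test, sp)
  })
}
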