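#' LSTM classifier configuration
#'
#' Hyperparameters of the two-layer LSTM spectrum classifier. The
#' architecture -- two LSTM layers with batch normalization and dropout
#' between them, then a dense softmax head -- follows the reported design;
#' the numeric settings were not reported and these defaults are the
#' package's own, all exposed here.
#'
#' @param hidden_units Hidden state size per LSTM layer (default 32).
#' @param dropout_rate Dropout between the layers, training only
#'   (default 0.2).
#' @param l2_penalty Ridge penalty on all weight matrices (default 1e-4).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Training epoch cap (default 200).
#' @param patience Early-stopping patience on held-out loss (default 20).
#' @param seed Seed for initialization, shuffling and dropout.
#' @param input_channel `"X"` (reactance) or `"R"` (resistance); recorded
#'   for provenance when training from a cohort.
#' @return List of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 32L, dropout_rate = 0.2,
                        l2_penalty = 1e-4, learning_rate = 1e-3,
                        batch_size = 16L, max_epochs = 200L, patience = 20L,
                        seed = 1L, input_channel = c("X", "R")) {
  input_channel <- match.arg(input_channel)
  stopifnot(hidden_units >= 1L, dropout_rate >= 0, dropout_rate < 1,
            l2_penalty >= 0, learning_rate > 0, batch_size >= 1L,
            max_epochs >= 1L, patience >= 1L)
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate, l2_penalty = l2_penalty,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 input_channel = input_channel), class = "lstm_config")
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialize an LSTM classifier model
#'
#' Glorot-uniform weights, zero biases except a forget-gate bias of 1 (the
#' standard trick that keeps the cell memory open early in training), unit
#' batch-norm scale, identity input standardization. Uses the current RNG
#' state; seed it for reproducibility.
#'
#' @param config An [lstm_config()].
#' @param seq_len Sequence length (number of frequency points, default 36).
#' @param n_classes Number of output classes (default 2).
#' @return List of class `lstm_model` with elements `params` (named list of
#'   tensors), `bn_stats` (running mean/var per time step), `norm`
#'   (per-step input mean/sd), `config`, `classes`, `seq_len`.
#' @export
lstm_init <- function(config, seq_len = 36L, n_classes = 2L) {
  H <- config$hidden_units
  b1 <- numeric(4L * H); b1[(H + 1L):(2L * H)] <- 1
  b2 <- numeric(4L * H); b2[(H + 1L):(2L * H)] <- 1
  params <- list(
    W1 = glorot(1L, 4L * H), U1 = glorot(H, 4L * H), b1 = b1,
    W2 = glorot(H, 4L * H), U2 = glorot(H, 4L * H), b2 = b2,
    gamma = rep(1, H), beta = rep(0, H),
    Wd = glorot(H, n_classes), bd = numeric(n_classes))
  structure(list(params = params,
                 bn_stats = list(mean = matrix(0, seq_len, H),
                                 var = matrix(1, seq_len, H),
                                 momentum = 0.9, eps = 1e-5),
                 norm = list(mean = numeric(seq_len), sd = rep(1, seq_len)),
                 config = config, classes = NULL,
                 seq_len = as.integer(seq_len)),
            class = "lstm_model")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_layer_forward <- function(W, U, b, xs, H) {
  T_len <- length(xs); B <- nrow(xs[[1L]])
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", T_len)
  hs <- vector("list", T_len)
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in seq_len(T_len)) {
    z <- xs[[t]] %*% W + h %*% U + matrix(b, B, 4L * H, byrow = TRUE)
    i_g <- sigmoid(z[, ii, drop = FALSE])
    f_g <- sigmoid(z[, fi, drop = FALSE])
    g_g <- tanh(z[, gi, drop = FALSE])
    o_g <- sigmoid(z[, oi, drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev_cache <- if (t == 1L) matrix(0, B, H) else hs[[t - 1L]]
    h <- o_g * tc
    hs[[t]] <- h
    cache[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g, tc = tc,
                       c_prev = c_prev, h_prev = h_prev_cache, x = xs[[t]])
  }
  list(hs = hs, cache = cache)
}

lstm_layer_backward <- function(W, U, dh_ext, cache, H) {
  T_len <- length(cache); B <- nrow(cache[[1L]]$x)
  D <- ncol(cache[[1L]]$x)
  dW <- matrix(0, D, 4L * H); dU <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dxs <- vector("list", T_len)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- dh_next + if (is.null(dh_ext[[t]])) 0 else dh_ext[[t]]
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    dz <- matrix(0, B, 4L * H)
    dz[, oi] <- dh * cc$tc * cc$o * (1 - cc$o)
    dz[, ii] <- dc * cc$g * cc$i * (1 - cc$i)
    dz[, fi] <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dz[, gi] <- dc * cc$i * (1 - cc$g^2)
    dW <- dW + crossprod(cc$x, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(W)
    dh_next <- dz %*% t(U)
    dc_next <- dc * cc$f
  }
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

#' Forward pass of the two-layer LSTM classifier
#'
#' Runs the network along the frequency axis (ascending): LSTM layer 1,
#' per-time-step feature-wise batch normalization, dropout (training mode
#' only), LSTM layer 2, dense softmax on the final hidden state. In
#' training mode batch statistics are used (and returned as updated running
#' averages in the cache); in evaluation mode the stored running statistics
#' make the pass fully deterministic.
#'
#' @param model An `lstm_model`.
#' @param x Numeric matrix, batch x seq_len, raw feature scale (the model's
#'   stored per-step standardization is applied internally).
#' @param training Logical; enables batch statistics and dropout.
#' @param keep_cache Keep intermediate values for backpropagation.
#' @return List with `probs` (batch x classes, rows summing to 1) and,
#'   when `keep_cache`, `cache`.
#' @export
lstm_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (any(!is.finite(x))) stop("non-finite values in the input batch",
                               call. = FALSE)
  if (ncol(x) != model$seq_len) {
    stop("input sequence length ", ncol(x), " does not match the model (",
         model$seq_len, ")", call. = FALSE)
  }
  p <- model$params
  H <- model$config$hidden_units
  B <- nrow(x); T_len <- model$seq_len
  xs <- lapply(seq_len(T_len), function(t) {
    matrix((x[, t] - model$norm$mean[t]) / model$norm$sd[t], B, 1L)
  })
  l1 <- lstm_layer_forward(p$W1, p$U1, p$b1, xs, H)
  eps <- model$bn_stats$eps
  bn_cache <- vector("list", T_len)
  ys <- vector("list", T_len)
  new_mean <- model$bn_stats$mean; new_var <- model$bn_stats$var
  drop_p <- if (training) model$config$dropout_rate else 0
  masks <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    h <- l1$hs[[t]]
    if (training) {
      mu <- colMeans(h)
      v <- colMeans(sweep(h, 2L, mu)^2)
      mom <- model$bn_stats$momentum
      new_mean[t, ] <- mom * new_mean[t, ] + (1 - mom) * mu
      new_var[t, ] <- mom * new_var[t, ] + (1 - mom) * v
    } else {
      mu <- model$bn_stats$mean[t, ]
      v <- model$bn_stats$var[t, ]
    }
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(h, 2L, mu), 2L, inv_sd, `*`)
    y <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
    if (drop_p > 0) {
      m <- matrix(stats::rbinom(B * H, 1L, 1 - drop_p), B, H) / (1 - drop_p)
      masks[[t]] <- m
      y <- y * m
    }
    ys[[t]] <- y
    bn_cache[[t]] <- list(xhat = xhat, inv_sd = inv_sd, h = h, mu = mu)
  }
  l2 <- lstm_layer_forward(p$W2, p$U2, p$b2, ys, H)
  h_final <- l2$hs[[T_len]]
  logits <- h_final %*% p$Wd + matrix(p$bd, B, length(p$bd), byrow = TRUE)
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(l1 = l1, l2 = l2, bn = bn_cache, masks = masks,
                      h_final = h_final, training = training,
                      bn_running = list(mean = new_mean, var = new_var))
  }
  out
}

l2_weight_names <- c("W1", "U1", "W2", "U2", "Wd")

#' Loss of the classifier on a labeled batch
#'
#' Mean cross-entropy plus the ridge penalty on weight matrices.
#'
#' @param model An `lstm_model`.
#' @param x Batch matrix (batch x seq_len).
#' @param y Integer class labels in `1..n_classes`.
#' @param training Forward in training mode.
#' @param keep_cache Keep the forward cache.
#' @return List with `loss`, `ce` (cross-entropy part), `probs`, optionally
#'   `cache`.
#' @export
lstm_loss <- function(model, x, y, training = TRUE, keep_cache = FALSE) {
  fw <- lstm_forward(model, x, training = training, keep_cache = keep_cache)
  B <- nrow(x)
  ce <- -mean(log(pmax(fw$probs[cbind(seq_len(B), y)], 1e-300)))
  pen <- model$config$l2_penalty *
    sum(vapply(model$params[l2_weight_names],
               function(w) sum(w^2), numeric(1L)))
  out <- list(loss = ce + pen, ce = ce, probs = fw$probs)
  if (keep_cache) out$cache <- fw$cache
  out
}

#' Gradients of the classifier loss by backpropagation through time
#'
#' Full analytic backpropagation across the dense head, LSTM layer 2,
#' dropout, per-step batch normalization (through the batch statistics when
#' in training mode) and LSTM layer 1. The ridge term contributes
#' `2 * l2_penalty * w` on every weight matrix.
#'
#' @inheritParams lstm_loss
#' @return List with `loss` and `grads` (named like `model$params`).
#' @export
lstm_gradients <- function(model, x, y, training = TRUE) {
  ls <- lstm_loss(model, x, y, training = training, keep_cache = TRUE)
  cache <- ls$cache
  p <- model$params
  H <- model$config$hidden_units
  B <- nrow(x); T_len <- model$seq_len
  n_cls <- ncol(ls$probs)
  yy <- matrix(0, B, n_cls); yy[cbind(seq_len(B), y)] <- 1
  dlogits <- (ls$probs - yy) / B
  dWd <- crossprod(cache$h_final, dlogits)
  dbd <- colSums(dlogits)
  dh_final <- dlogits %*% t(p$Wd)
  dh_ext2 <- vector("list", T_len)
  dh_ext2[[T_len]] <- dh_final
  bk2 <- lstm_layer_backward(p$W2, p$U2, dh_ext2, cache$l2$cache, H)
  dgamma <- numeric(H); dbeta <- numeric(H)
  dh_ext1 <- vector("list", T_len)
  eps <- model$bn_stats$eps
  for (t in seq_len(T_len)) {
    dy <- bk2$dxs[[t]]
    if (!is.null(cache$masks[[t]])) dy <- dy * cache$masks[[t]]
    bc <- cache$bn[[t]]
    dgamma <- dgamma + colSums(dy * bc$xhat)
    dbeta <- dbeta + colSums(dy)
    dxhat <- sweep(dy, 2L, p$gamma, `*`)
    if (cache$training) {
      # backprop through the batch mean/variance
      centered <- sweep(bc$h, 2L, bc$mu)
      dvar <- colSums(dxhat * centered) * (-0.5) * bc$inv_sd^3
      dmu <- colSums(dxhat) * (-bc$inv_sd) +
        dvar * colMeans(-2 * centered)
      dh <- sweep(dxhat, 2L, bc$inv_sd, `*`) +
        sweep(centered, 2L, dvar * 2 / B, `*`) +
        matrix(dmu / B, B, H, byrow = TRUE)
    } else {
      dh <- sweep(dxhat, 2L, bc$inv_sd, `*`)
    }
    dh_ext1[[t]] <- dh
  }
  bk1 <- lstm_layer_backward(p$W1, p$U1, dh_ext1, cache$l1$cache, H)
  grads <- list(W1 = bk1$dW, U1 = bk1$dU, b1 = bk1$db,
                W2 = bk2$dW, U2 = bk2$dU, b2 = bk2$db,
                gamma = dgamma, beta = dbeta, Wd = dWd, bd = dbd)
  lam <- model$config$l2_penalty
  for (nm in l2_weight_names) grads[[nm]] <- grads[[nm]] + 2 * lam * p[[nm]]
  list(loss = ls$loss, grads = grads)
}

#' Flatten model parameters to a vector / write a vector back
#'
#' Utilities for finite-difference gradient checking and serialization.
#'
#' @param model An `lstm_model`.
#' @return `lstm_param_vector`: named numeric vector.
#' @export
lstm_param_vector <- function(model) {
  unlist(model$params)
}

#' @rdname lstm_param_vector
#' @param v Numeric vector as produced by [lstm_param_vector()].
#' @return `lstm_set_param_vector`: the model with parameters replaced.
#' @export
lstm_set_param_vector <- function(model, v) {
  pos <- 0L
  for (nm in names(model$params)) {
    n <- length(model$params[[nm]])
    val <- v[pos + seq_len(n)]
    if (is.matrix(model$params[[nm]])) {
      model$params[[nm]] <- matrix(val, nrow(model$params[[nm]]),
                                   ncol(model$params[[nm]]))
    } else {
      model$params[[nm]] <- val
    }
    pos <- pos + n
  }
  model
}
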