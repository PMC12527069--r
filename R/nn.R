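# Minimal neural-network engine.
#
# Activations flow through the network as 3-D arrays of dimension
# (channels, length, batch); dense layers operate on (features, batch)
# matrices. Every layer implements a forward pass returning (output,
# cache) and a backward pass returning (input gradient, parameter
# gradients). Backprop is hand-derived per layer and verified against
# numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_conv1d <- function(in_ch, out_ch, kernel, stride, pad = 0L) {
  list(type = "conv1d",
       W = array(0, c(out_ch, in_ch, kernel)), b = numeric(out_ch),
       in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))
}
layer_relu <- function() list(type = "relu")
layer_dropout <- function(rate) {
  if (rate < 0 || rate >= 1) abort_validation("dropout rate must be in [0,1)")
  list(type = "dropout", rate = rate)
}
layer_maxpool <- function(size = 2L) {
  if (size != 2L) abort_config("only max-pooling of size 2 is supported")
  list(type = "maxpool", size = 2L)
}
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(in_features, out_features) {
  list(type = "dense", W = matrix(0, out_features, in_features),
       b = numeric(out_features),
       in_features = in_features, out_features = out_features)
}
layer_lstm <- function(input_size, hidden_size, return_sequences = FALSE) {
  list(type = "lstm",
       Wx = matrix(0, 4L * hidden_size, input_size),
       Wh = matrix(0, 4L * hidden_size, hidden_size),
       b = numeric(4L * hidden_size),
       input_size = input_size, hidden_size = hidden_size,
       return_sequences = isTRUE(return_sequences))
}
layer_softmax <- function() list(type = "softmax")

# length of the output sequence produced by a conv/pool stage
conv_out_len <- function(len, kernel, stride, pad) {
  (len + 2L * pad - kernel) %/% stride + 1L
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

forward_layer <- function(layer, X, training = FALSE) {
  switch(layer$type,
    conv1d = {
      d <- dim(X)   # (in_ch, L, B)
      if (layer$pad > 0) {
        Xp <- array(0, c(d[1], d[2] + 2L * layer$pad, d[3]))
        Xp[, layer$pad + seq_len(d[2]), ] <- X
      } else Xp <- X
      Lp <- dim(Xp)[2]
      Lout <- (Lp - layer$kernel) %/% layer$stride + 1L
      B <- d[3]
      Ymat <- matrix(0, layer$out_ch, Lout * B)
      for (u in seq_len(layer$kernel)) {
        idx <- seq(u, by = layer$stride, length.out = Lout)
        Xs <- Xp[, idx, , drop = FALSE]
        dim(Xs) <- c(layer$in_ch, Lout * B)
        Ymat <- Ymat + matrix(layer$W[, , u], layer$out_ch,
                              layer$in_ch) %*% Xs
      }
      Ymat <- Ymat + layer$b
      dim(Ymat) <- c(layer$out_ch, Lout, B)
      list(out = Ymat, cache = list(Xp = Xp, Lout = Lout))
    },
    relu = {
      mask <- X > 0
      list(out = X * mask, cache = mask)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array(stats::runif(length(X)) >= layer$rate, dim(X)) /
          (1 - layer$rate)
        list(out = X * mask, cache = mask)
      } else list(out = X, cache = NULL)
    },
    maxpool = {
      d <- dim(X)
      L2 <- d[2] %/% layer$size
      i1 <- seq(1L, by = 2L, length.out = L2)
      A1 <- X[, i1, , drop = FALSE]
      A2 <- X[, i1 + 1L, , drop = FALSE]
      m1 <- A1 >= A2
      list(out = pmax(A1, A2), cache = list(m1 = m1, i1 = i1, dX = d))
    },
    flatten = {
      d <- dim(X)
      Y <- X
      dim(Y) <- c(d[1] * d[2], d[3])
      list(out = Y, cache = d)
    },
    dense = {
      list(out = layer$W %*% X + layer$b, cache = X)
    },
    lstm = {
      d <- dim(X)   # (D, T, B)
      H <- layer$hidden_size
      Tn <- d[2]; B <- d[3]
      h <- matrix(0, H, B); cc <- matrix(0, H, B)
      steps <- vector("list", Tn)
      if (layer$return_sequences) Hs <- array(0, c(H, Tn, B))
      for (t in seq_len(Tn)) {
        Xt <- matrix(X[, t, ], d[1], B)
        G <- layer$Wx %*% Xt + layer$Wh %*% h + layer$b
        i <- sigmoid(G[seq_len(H), , drop = FALSE])
        f <- sigmoid(G[H + seq_len(H), , drop = FALSE])
        o <- sigmoid(G[2L * H + seq_len(H), , drop = FALSE])
        g <- tanh(G[3L * H + seq_len(H), , drop = FALSE])
        c_prev <- cc
        cc <- f * c_prev + i * g
        h_prev <- h
        h <- o * tanh(cc)
        steps[[t]] <- list(Xt = Xt, i = i, f = f, o = o, g = g,
                           c_prev = c_prev, cc = cc, h_prev = h_prev)
        if (layer$return_sequences) Hs[, t, ] <- h
      }
      out <- if (layer$return_sequences) Hs else h
      list(out = out, cache = list(steps = steps, d = d))
    },
    softmax = {
      list(out = softmax_cols(X), cache = NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

backward_layer <- function(layer, dY, cache) {
  switch(layer$type,
    conv1d = {
      Xp <- cache$Xp
      Lout <- cache$Lout
      dp <- dim(Xp); B <- dp[3]
      dYmat <- dY
      dim(dYmat) <- c(layer$out_ch, Lout * B)
      dW <- array(0, dim(layer$W))
      db <- rowSums(dYmat)
      dXp <- array(0, dp)
      for (u in seq_len(layer$kernel)) {
        idx <- seq(u, by = layer$stride, length.out = Lout)
        Xs <- Xp[, idx, , drop = FALSE]
        dim(Xs) <- c(layer$in_ch, Lout * B)
        dW[, , u] <- dYmat %*% t(Xs)
        dXs <- t(matrix(layer$W[, , u], layer$out_ch, layer$in_ch)) %*% dYmat
        dim(dXs) <- c(layer$in_ch, Lout, B)
        dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dXs
      }
      dX <- if (layer$pad > 0) {
        dXp[, layer$pad + seq_len(dp[2] - 2L * layer$pad), , drop = FALSE]
      } else dXp
      list(dX = dX, grads = list(W = dW, b = db))
    },
    relu = list(dX = dY * cache, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache, grads = NULL)
    },
    maxpool = {
      dX <- array(0, cache$dX)
      dX[, cache$i1, ] <- dY * cache$m1
      dX[, cache$i1 + 1L, ] <- dY * !cache$m1
      list(dX = dX, grads = NULL)
    },
    flatten = {
      dX <- dY
      dim(dX) <- cache
      list(dX = dX, grads = NULL)
    },
    dense = {
      list(dX = t(layer$W) %*% dY,
           grads = list(W = dY %*% t(cache), b = rowSums(dY)))
    },
    lstm = {
      d <- cache$d
      H <- layer$hidden_size
      Tn <- d[2]; B <- d[3]
      dWx <- matrix(0, 4L * H, layer$input_size)
      dWh <- matrix(0, 4L * H, H)
      db <- numeric(4L * H)
      dX <- array(0, d)
      dh_next <- matrix(0, H, B)
      dc_next <- matrix(0, H, B)
      for (t in rev(seq_len(Tn))) {
        st <- cache$steps[[t]]
        dh <- dh_next
        if (layer$return_sequences) dh <- dh + matrix(dY[, t, ], H, B)
        else if (t == Tn) dh <- dh + dY
        tc <- tanh(st$cc)
        do_ <- dh * tc
        dc <- dc_next + dh * st$o * (1 - tc^2)
        di <- dc * st$g
        dg <- dc * st$i
        df <- dc * st$c_prev
        dc_next <- dc * st$f
        dG <- rbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    do_ * st$o * (1 - st$o),
                    dg * (1 - st$g^2))
        dWx <- dWx + dG %*% t(st$Xt)
        dWh <- dWh + dG %*% t(st$h_prev)
        db <- db + rowSums(dG)
        dX[, t, ] <- t(layer$Wx) %*% dG
        dh_next <- t(layer$Wh) %*% dG
      }
      list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    softmax = stop("softmax has no standalone backward; train on logits"),
    stop("unknown layer type: ", layer$type)
  )
}

# Forward through the whole network. `segments` is a (batch x len) matrix.
# Returns logits (the input of the final softmax layer) plus caches when
# `keep_caches`.
nn_forward <- function(model, segments, training = FALSE,
                       keep_caches = FALSE) {
  B <- nrow(segments)
  X <- array(t(segments), c(1L, ncol(segments), B))
  caches <- vector("list", length(model$layers))
  for (k in seq_along(model$layers)) {
    layer <- model$layers[[k]]
    if (layer$type == "softmax") break
    fw <- forward_layer(layer, X, training = training)
    X <- fw$out
    if (keep_caches) caches[[k]] <- fw$cache
  }
  list(logits = X, caches = caches)
}

# Backward from logit gradients; returns per-layer parameter gradients.
nn_backward <- function(model, dlogits, caches) {
  n <- length(model$layers)
  grads <- vector("list", n)
  dY <- dlogits
  for (k in rev(seq_len(n))) {
    layer <- model$layers[[k]]
    if (layer$type == "softmax") next
    bw <- backward_layer(layer, dY, caches[[k]])
    dY <- bw$dX
    if (!is.null(bw$grads)) grads[[k]] <- bw$grads
  }
  grads
}

#' Class probabilities for a batch of segments
#' @param model A model built by [build_cnn()], [build_lstm()] or
#'   [build_hybrid()].
#' @param segments Numeric matrix, one beat per row.
#' @return Matrix (rows = beats, columns = the five classes) of
#'   probabilities; each row sums to 1.
#' @export
predict_proba <- function(model, segments) {
  logits <- nn_forward(model, segments)$logits
  p <- t(softmax_cols(logits))
  colnames(p) <- AAMI_CLASSES
  p
}

#' Predicted integer class labels (0-4)
#' @inheritParams predict_proba
#' @return Integer vector of labels.
#' @export
predict_classes <- function(model, segments) {
  max.col(predict_proba(model, segments)) - 1L
}

#' Number of trainable parameters of a model
#' @param model A built model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(intersect(names(l), c("W", "b", "Wx", "Wh")),
               function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}
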