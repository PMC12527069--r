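# Training: weighted cross-entropy, Adam/AdamW, seeded mini-batch loop.

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size (default 20).
#' @param learning_rate Step size (> 0).
#' @param optimizer_name "adam" or "adamw" (decoupled weight decay 0.01).
#' @param class_weights Five nonnegative per-class loss weights, or NULL
#'   to use inverse-frequency weights computed from the training labels.
#' @param seed Integer seed controlling shuffling, dropout and any weight
#'   initialization performed by the caller.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 20L,
                         learning_rate = 1e-3,
                         optimizer_name = c("adam", "adamw"),
                         class_weights = NULL, seed = 1L) {
  optimizer_name <- match.arg(optimizer_name)
  if (!is_count(epochs) || !is_count(batch_size))
    abort_validation("epochs and batch_size must be counts >= 1")
  if (learning_rate < 0) abort_validation("learning_rate must be >= 0")
  if (!is.null(class_weights) &&
      (length(class_weights) != 5 || any(class_weights < 0)))
    abort_validation("class_weights must be five nonnegative weights")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_name = optimizer_name,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `w[y_i] * (-log p_i[y_i])`, normalized by the
#' mean weight of the batch's labels (so uniform weights reduce exactly to
#' unweighted cross-entropy). Probabilities of 0 at the true label are
#' clamped at 1e-12 with a warning.
#'
#' @param probabilities Matrix of class probabilities, one row per sample.
#' @param labels Integer labels 0-based (0..ncol-1).
#' @param class_weights Nonnegative per-class weights (default uniform).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, labels,
                                   class_weights =
                                     rep(1, ncol(probabilities))) {
  p <- probabilities[cbind(seq_along(labels), labels + 1L)]
  if (any(p <= 0)) {
    warning("probability 0 at the true label; clamping at 1e-12")
    p <- pmax(p, 1e-12)
  }
  w <- class_weights[labels + 1L]
  sum(w * -log(p)) / sum(w)
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `1 / count` for classes present (absent classes
#' get weight 0), normalized to mean 1 over present classes.
#'
#' @param labels Integer labels 0-4.
#' @return Numeric vector of five weights.
#' @export
inverse_frequency_weights <- function(labels) {
  counts <- as.numeric(table(factor(labels, levels = 0:4)))
  w <- ifelse(counts > 0, 1 / pmax(counts, 1), 0)
  present <- counts > 0
  w[present] <- w[present] / mean(w[present])
  w
}

# loss and logit gradient for one batch (logits: classes x batch)
wce_from_logits <- function(logits, labels, class_weights) {
  p <- softmax_cols(logits)
  B <- ncol(logits)
  w <- class_weights[labels + 1L]
  idx <- cbind(labels + 1L, seq_len(B))
  loss <- sum(w * -log(pmax(p[idx], 1e-12))) / sum(w)
  Y <- matrix(0, nrow(logits), B)
  Y[idx] <- 1
  dlogits <- (p - Y) * rep(w, each = nrow(logits)) / sum(w)
  list(loss = loss, dlogits = dlogits,
       correct = sum(max.col(t(p)) - 1L == labels))
}

# one Adam/AdamW step over the model's parameter tensors, updating in
# place; `state` holds first/second moments and the step counter
optimizer_step <- function(model, grads, state, cfg) {
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  wd <- if (cfg$optimizer_name == "adamw") 0.01 else 0
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (k in seq_along(model$layers)) {
    g <- grads[[k]]
    if (is.null(g)) next
    for (nm in names(g)) {
      key <- paste0(k, ".", nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g[[nm]] * 0
        state$v[[key]] <- g[[nm]] * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g[[nm]]
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g[[nm]]^2
      upd <- (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
      w <- model$layers[[k]][[nm]]
      if (wd > 0 && nm != "b") w <- w - lr * wd * w
      model$layers[[k]][[nm]] <- w - lr * upd
    }
  }
  list(model = model, state = state)
}

#' Train a model with seeded mini-batch gradient descent
#'
#' Runs `cfg$epochs` epochs of shuffled mini-batches with the configured
#' optimizer and weighted cross-entropy on the softmax logits. The history
#' records running train loss/accuracy and full validation loss/accuracy
#' per epoch. Re-running with the same seed and configuration reproduces
#' the history exactly.
#'
#' @param model A built (and typically [kaiming_init()]-ialized) model.
#' @param train,valid [beat_dataset()]s; validation may be NULL.
#' @param cfg A [train_config()].
#' @return List with `model` (final-epoch weights), `history` (data frame
#'   with epoch, train_loss, train_acc, valid_loss, valid_acc) and
#'   `best_epoch` (epoch of highest validation accuracy).
#' @export
train_model <- function(model, train, valid = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "ecg_model"), inherits(train, "beat_dataset"))
  if (nrow(train$segments) == 0) abort_validation("training set is empty")
  if (any(!is.finite(train$segments)))
    abort_validation("training segments must be finite")
  cw <- cfg$class_weights
  if (is.null(cw)) cw <- inverse_frequency_weights(train$labels)
  n <- nrow(train$segments)
  bs <- min(cfg$batch_size, n)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), valid_loss = numeric(0),
                        valid_acc = numeric(0))
  state <- list(t = 0L, m = list(), v = list())
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- train$segments[idx, , drop = FALSE]
        yb <- train$labels[idx]
        fw <- nn_forward(model, xb, training = TRUE, keep_caches = TRUE)
        lo <- wce_from_logits(fw$logits, yb, cw)
        if (!is.finite(lo$loss))
          stop(sprintf(
            "non-finite loss at epoch %d (learning_rate=%g, batch=%d)",
            ep, cfg$learning_rate, length(idx)))
        grads <- nn_backward(model, lo$dlogits, fw$caches)
        st <- optimizer_step(model, grads, state, cfg)
        model <- st$model; state <- st$state
        tot_loss <- tot_loss + lo$loss * length(idx)
        tot_correct <- tot_correct + lo$correct
      }
      vl <- NA_real_; va <- NA_real_
      if (!is.null(valid) && nrow(valid$segments) > 0) {
        logits <- nn_forward(model, valid$segments)$logits
        ev <- wce_from_logits(logits, valid$labels, cw)
        vl <- ev$loss
        va <- ev$correct / nrow(valid$segments)
      }
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tot_loss / n, train_acc = tot_correct / n,
        valid_loss = vl, valid_acc = va))
      log_msg(sprintf("epoch %d: loss %.4f acc %.3f val_acc %.3f",
                      ep, tot_loss / n, tot_correct / n, va))
    }
  })
  best <- if (all(is.na(history$valid_acc))) nrow(history)
          else which.max(history$valid_acc)
  list(model = model, history = history, best_epoch = best)
}
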