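# Model configurations and builders: the 1D-CNN, the stacked LSTM and the
# hybrid convolutional-recurrent classifier, plus the reference LSTM cell.

#' 1D-CNN configuration
#'
#' Defaults follow the two-block architecture used throughout the package:
#' Conv(1->256, kernel 8, stride 5, pad 1) and Conv(256->128, kernel 7,
#' stride 4, pad 1), each followed by ReLU, dropout (0.15 / 0.10) and
#' max-pooling of 2, then a 128-unit dense layer and a softmax over the
#' five classes.
#'
#' @param filters,kernel_sizes,strides,paddings,dropout_rates Length-2
#'   vectors, one entry per conv block.
#' @param dense_units Width of the penultimate dense layer.
#' @param n_classes Number of output classes (5).
#' @param input_len Beat segment length in samples.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(filters = c(256L, 128L),
                       kernel_sizes = c(8L, 7L),
                       strides = c(5L, 4L),
                       paddings = c(1L, 1L),
                       dropout_rates = c(0.15, 0.10),
                       dense_units = 128L,
                       n_classes = 5L,
                       input_len = 280L) {
  stopifnot(length(filters) == 2, length(kernel_sizes) == 2,
            length(strides) == 2)
  if (any(filters < 1) || any(kernel_sizes < 1) || any(strides < 1) ||
      dense_units < 1)
    abort_validation("all architecture counts must be >= 1")
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    abort_validation("dropout rates must lie in [0, 1)")
  structure(as.list(environment()), class = "cnn_config")
}

#' Stacked-LSTM configuration
#'
#' Three recurrent layers of decreasing width (64, 32, 16 by default) with
#' inter-layer dropout 0.4, a dense layer on the final hidden state and a
#' softmax over the five classes. Input is the beat as a length-`input_len`
#' sequence of scalars.
#'
#' @param layer_sizes Hidden sizes of the stacked recurrent layers.
#' @param inter_layer_dropout Dropout between recurrent layers.
#' @param n_classes,input_len As in [cnn_config()].
#' @return Object of class `lstm_config`.
#' @export
lstm_config <- function(layer_sizes = c(64L, 32L, 16L),
                        inter_layer_dropout = 0.4,
                        n_classes = 5L,
                        input_len = 280L) {
  if (any(layer_sizes < 1)) abort_validation("layer sizes must be >= 1")
  if (inter_layer_dropout < 0 || inter_layer_dropout >= 1)
    abort_validation("dropout must lie in [0, 1)")
  structure(as.list(environment()), class = "lstm_config")
}

#' Hybrid convolutional-recurrent configuration
#'
#' The CNN front end (the two conv blocks of [cnn_config()]) extracts a
#' feature map whose remaining spatial positions are handed to a single
#' LSTM layer as a sequence (time steps = positions, features = channels),
#' followed by a dense layer and softmax.
#'
#' @inheritParams cnn_config
#' @param lstm_hidden Hidden units of the recurrent layer.
#' @return Object of class `hybrid_config`.
#' @export
hybrid_config <- function(filters = c(256L, 128L),
                          kernel_sizes = c(8L, 7L),
                          strides = c(5L, 4L),
                          paddings = c(1L, 1L),
                          dropout_rates = c(0.15, 0.10),
                          lstm_hidden = 64L,
                          n_classes = 5L,
                          input_len = 280L) {
  if (any(filters < 1) || any(kernel_sizes < 1) || any(strides < 1) ||
      lstm_hidden < 1)
    abort_validation("all architecture counts must be >= 1")
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    abort_validation("dropout rates must lie in [0, 1)")
  structure(as.list(environment()), class = "hybrid_config")
}

# length of the feature map after the two conv blocks; errors (naming the
# failing stage) if any stage collapses below one position
conv_stack_len <- function(cfg) {
  len <- cfg$input_len
  for (blk in 1:2) {
    len <- conv_out_len(len, cfg$kernel_sizes[blk], cfg$strides[blk],
                        cfg$paddings[blk])
    if (len < 1)
      abort_config(sprintf(
        "input too short: conv block %d would produce an empty feature map",
        blk))
    len <- len %/% 2L
    if (len < 1)
      abort_config(sprintf(
        "input too short: max-pool after conv block %d would be empty", blk))
  }
  len
}

new_model <- function(layers, kind, cfg) {
  structure(list(layers = layers, kind = kind, config = cfg),
            class = "ecg_model")
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model:%s> %d layers, %d trainable parameters\n",
              x$kind, length(x$layers), count_parameters(x)))
  invisible(x)
}

#' Build the 1D-CNN classifier
#'
#' @param cfg A [cnn_config()].
#' @return An `ecg_model` with zero-valued weights; initialize with
#'   [kaiming_init()].
#' @export
build_cnn <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  flat_len <- conv_stack_len(cfg) * cfg$filters[2]
  layers <- list(
    layer_conv1d(1L, cfg$filters[1], cfg$kernel_sizes[1], cfg$strides[1],
                 cfg$paddings[1]),
    layer_relu(),
    layer_dropout(cfg$dropout_rates[1]),
    layer_maxpool(2L),
    layer_conv1d(cfg$filters[1], cfg$filters[2], cfg$kernel_sizes[2],
                 cfg$strides[2], cfg$paddings[2]),
    layer_relu(),
    layer_dropout(cfg$dropout_rates[2]),
    layer_maxpool(2L),
    layer_flatten(),
    layer_dense(flat_len, cfg$dense_units),
    layer_relu(),
    layer_dense(cfg$dense_units, cfg$n_classes),
    layer_softmax()
  )
  new_model(layers, "cnn", cfg)
}

#' Build the stacked LSTM classifier
#' @param cfg An [lstm_config()].
#' @return An `ecg_model`.
#' @export
build_lstm <- function(cfg = lstm_config()) {
  stopifnot(inherits(cfg, "lstm_config"))
  sizes <- cfg$layer_sizes
  layers <- list()
  in_size <- 1L
  for (k in seq_along(sizes)) {
    last <- k == length(sizes)
    layers <- c(layers, list(layer_lstm(in_size, sizes[k],
                                        return_sequences = !last)))
    if (!last)
      layers <- c(layers, list(layer_dropout(cfg$inter_layer_dropout)))
    in_size <- sizes[k]
  }
  layers <- c(layers, list(layer_dense(in_size, cfg$n_classes),
                           layer_softmax()))
  new_model(layers, "lstm", cfg)
}

#' Build the hybrid convolutional-recurrent classifier
#'
#' The conv feature map (channels x positions) is fed to the recurrent
#' layer as a sequence with one time step per remaining spatial position,
#' so the recurrent stage sees the temporal order of the extracted
#' features.
#'
#' @param cfg A [hybrid_config()].
#' @return An `ecg_model`.
#' @export
build_hybrid <- function(cfg = hybrid_config()) {
  stopifnot(inherits(cfg, "hybrid_config"))
  seq_len_out <- conv_stack_len(cfg)
  layers <- list(
    layer_conv1d(1L, cfg$filters[1], cfg$kernel_sizes[1], cfg$strides[1],
                 cfg$paddings[1]),
    layer_relu(),
    layer_dropout(cfg$dropout_rates[1]),
    layer_maxpool(2L),
    layer_conv1d(cfg$filters[1], cfg$filters[2], cfg$kernel_sizes[2],
                 cfg$strides[2], cfg$paddings[2]),
    layer_relu(),
    layer_dropout(cfg$dropout_rates[2]),
    layer_maxpool(2L),
    # feature map (channels, positions, batch) flows straight into the
    # recurrent layer: features = channels, time steps = positions
    layer_lstm(cfg$filters[2], cfg$lstm_hidden, return_sequences = FALSE),
    layer_dense(cfg$lstm_hidden, cfg$n_classes),
    layer_softmax()
  )
  m <- new_model(layers, "hybrid", cfg)
  m$seq_len <- seq_len_out
  m
}

#' One step of the LSTM cell, gate by gate
#'
#' Reference implementation of the cell equations with separate weight
#' matrices per gate: input gate `i = sigmoid(W_i x + W_hi h + b_i)`,
#' forget gate `f = sigmoid(W_f x + W_fi h + b_f)`, output gate
#' `o = sigmoid(W_o x + W_oi h + b_o)`, candidate
#' `g = tanh(W_c x + W_hc h + b_c)`, then `c_t = f * c_prev + i * g` and
#' `h_t = o * tanh(c_t)`. Used as the equation-level oracle for the
#' vectorized recurrent layer.
#'
#' @param x_t Input vector at time t (length = input size).
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @param w List with matrices `W_i`, `W_f`, `W_o`, `W_c` (input -> gate),
#'   `W_hi`, `W_fi`, `W_oi`, `W_hc` (hidden -> gate) and biases `b_i`,
#'   `b_f`, `b_o`, `b_c`.
#' @return List with `h_t` and `c_t`.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, w) {
  need <- c("W_i", "W_f", "W_o", "W_c", "W_hi", "W_fi", "W_oi", "W_hc",
            "b_i", "b_f", "b_o", "b_c")
  if (!all(need %in% names(w)))
    abort_validation("weight list is missing gate matrices or biases")
  H <- length(h_prev)
  if (ncol(w$W_i) != length(x_t) || nrow(w$W_i) != H ||
      ncol(w$W_hi) != H || length(c_prev) != H)
    abort_validation("weight shapes inconsistent with the state sizes")
  i <- sigmoid(w$W_i %*% x_t + w$W_hi %*% h_prev + w$b_i)
  f <- sigmoid(w$W_f %*% x_t + w$W_fi %*% h_prev + w$b_f)
  o <- sigmoid(w$W_o %*% x_t + w$W_oi %*% h_prev + w$b_o)
  g <- tanh(w$W_c %*% x_t + w$W_hc %*% h_prev + w$b_c)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h_t = as.numeric(h_t), c_t = as.numeric(c_t))
}

#' Kaiming (He) normal initialization
#'
#' Draws every convolutional, dense and recurrent weight from
#' `N(0, 2 / fan_in)` (fan-in = inputs feeding one unit: `in_ch * kernel`
#' for conv, input width for dense, input size for the input-to-gate
#' matrices and hidden size for the recurrent matrices). All biases are
#' set to zero. Seeded and deterministic.
#'
#' @param model A built `ecg_model`.
#' @param seed Integer seed.
#' @return The initialized model.
#' @export
kaiming_init <- function(model, seed = 1L) {
  stopifnot(inherits(model, "ecg_model"))
  with_seed(seed, {
    for (k in seq_along(model$layers)) {
      l <- model$layers[[k]]
      if (l$type == "conv1d") {
        fan_in <- l$in_ch * l$kernel
        l$W[] <- stats::rnorm(length(l$W), 0, sqrt(2 / fan_in))
        l$b[] <- 0
      } else if (l$type == "dense") {
        fan_in <- ncol(l$W)
        l$W[] <- stats::rnorm(length(l$W), 0, sqrt(2 / fan_in))
        l$b[] <- 0
      } else if (l$type == "lstm") {
        l$Wx[] <- stats::rnorm(length(l$Wx), 0, sqrt(2 / l$input_size))
        l$Wh[] <- stats::rnorm(length(l$Wh), 0, sqrt(2 / l$hidden_size))
        l$b[] <- 0
      }
      model$layers[[k]] <- l
    }
    model
  })
}
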