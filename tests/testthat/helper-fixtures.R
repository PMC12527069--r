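# Shared helpers for the test suite. Fixtures are built in code; nothing
# is read from disk except files the tests themselves write to tempdirs.

ns <- asNamespace("ecgwolf")

# split the fused gate matrices of a vectorized recurrent layer into the
# per-gate weight list consumed by lstm_cell_step (gate order i, f, o, c)
split_gate_weights <- function(layer) {
  H <- layer$hidden_size
  list(W_i = layer$Wx[1:H, , drop = FALSE],
       W_f = layer$Wx[H + 1:H, , drop = FALSE],
       W_o = layer$Wx[2 * H + 1:H, , drop = FALSE],
       W_c = layer$Wx[3 * H + 1:H, , drop = FALSE],
       W_hi = layer$Wh[1:H, , drop = FALSE],
       W_fi = layer$Wh[H + 1:H, , drop = FALSE],
       W_oi = layer$Wh[2 * H + 1:H, , drop = FALSE],
       W_hc = layer$Wh[3 * H + 1:H, , drop = FALSE],
       b_i = layer$b[1:H], b_f = layer$b[H + 1:H],
       b_o = layer$b[2 * H + 1:H], b_c = layer$b[3 * H + 1:H])
}

# a small, well-separated two-template dataset for training sanity checks
make_separable_dataset <- function(n_per_class = 40, len = 64, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = len)
  a <- sin(2 * pi * 3 * t)
  b <- 1.5 * exp(-((t - 0.5) / 0.08)^2)
  segs <- rbind(
    matrix(rep(a, n_per_class), n_per_class, len, byrow = TRUE),
    matrix(rep(b, n_per_class), n_per_class, len, byrow = TRUE)
  ) + matrix(rnorm(2 * n_per_class * len, 0, 0.1), 2 * n_per_class, len)
  beat_dataset(segs, rep(c(0L, 2L), each = n_per_class))
}

random_confusion_matrix <- function() {
  cm <- matrix(sample(0:60, 25, replace = TRUE), 5, 5)
  n <- 5000L
  truth <- sample(0:4, n, replace = TRUE)
  pred <- sample(0:4, n, replace = TRUE)
  confusion(truth, pred)
}
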