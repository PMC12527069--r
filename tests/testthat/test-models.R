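test_that("the zero-weight LSTM cell has the closed-form half-gate output", {
  H <- 4; D <- 3
  w <- list(W_i = matrix(0, H, D), W_f = matrix(0, H, D),
            W_o = matrix(0, H, D), W_c = matrix(0, H, D),
            W_hi = matrix(0, H, H), W_fi = matrix(0, H, H),
            W_oi = matrix(0, H, H), W_hc = matrix(0, H, H),
            b_i = numeric(H), b_f = numeric(H), b_o = numeric(H),
            b_c = numeric(H))
  c_prev <- c(1, -2, 0.5, 3)
  st <- lstm_cell_step(rnorm(D), rnorm(H), c_prev, w)
  expect_equal(st$c_t, 0.5 * c_prev, tolerance = 1e-12)
  expect_equal(st$h_t, 0.5 * tanh(0.5 * c_prev), tolerance = 1e-12)

  # saturated forget gate preserves the cell state
  w$b_f <- rep(50, H)
  st2 <- lstm_cell_step(rnorm(D), rnorm(H), c_prev, w)
  expect_equal(st2$c_t, c_prev, tolerance = 1e-6)

  expect_error(lstm_cell_step(rnorm(2), rnorm(H), c_prev, w), "shapes")
  expect_error(lstm_cell_step(rnorm(D), rnorm(H), c_prev, w[-1]), "missing")
})

test_that("the gate-by-gate cell and the vectorized recurrent layer agree", {
  set.seed(101)
  worst <- 0
  for (trial in 1:100) {
    D <- sample(1:6, 1); H <- sample(1:8, 1); Tn <- sample(2:6, 1)
    l <- ns$layer_lstm(D, H)
    l$Wx[] <- rnorm(length(l$Wx)); l$Wh[] <- rnorm(length(l$Wh))
    l$b[] <- rnorm(length(l$b))
    w <- split_gate_weights(l)
    X <- array(rnorm(D * Tn), c(D, Tn, 1))
    out <- ns$forward_layer(l, X)$out
    h <- numeric(H); cc <- numeric(H)
    for (t in seq_len(Tn)) {
      st <- lstm_cell_step(X[, t, 1], h, cc, w)
      h <- st$h_t; cc <- st$c_t
    }
    worst <- max(worst, max(abs(out - h)))
  }
  expect_lt(worst, 1e-5)
})

test_that("model outputs are probability simplices and short inputs fail loudly", {
  set.seed(7)
  X <- matrix(rnorm(4 * 280), 4, 280)
  for (m in list(kaiming_init(build_cnn(), seed = 1),
                 kaiming_init(build_hybrid(), seed = 1))) {
    p <- predict_proba(m, X)
    expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  ml <- kaiming_init(build_lstm(lstm_config(input_len = 40L)), seed = 2)
  p <- predict_proba(ml, matrix(rnorm(2 * 40), 2, 40))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)

  expect_error(build_cnn(cnn_config(input_len = 40L)), "conv block|max-pool")
  expect_error(build_hybrid(hybrid_config(input_len = 30L)),
               "conv block|max-pool")
})

test_that("parameter counts match the closed-form layer arithmetic", {
  # default CNN at input 280: conv stack 280 ->(k8,s5,p1) 55 ->pool 27
  # ->(k7,s4,p1) 6 ->pool 3; flatten 128*3 = 384
  cnn <- build_cnn()
  expected_cnn <- (256 * 1 * 8 + 256) +        # conv1
    (128 * 256 * 7 + 128) +                     # conv2
    (128 * 384 + 128) +                         # dense
    (5 * 128 + 5)                               # classifier
  expect_equal(count_parameters(cnn), expected_cnn)

  lstm <- build_lstm()
  lstm_layer <- function(D, H) 4 * H * D + 4 * H * H + 4 * H
  expected_lstm <- lstm_layer(1, 64) + lstm_layer(64, 32) +
    lstm_layer(32, 16) + (5 * 16 + 5)
  expect_equal(count_parameters(lstm), expected_lstm)

  hyb <- build_hybrid()
  expected_hyb <- (256 * 8 + 256) + (128 * 256 * 7 + 128) +
    lstm_layer(128, 64) + (5 * 64 + 5)
  expect_equal(count_parameters(hyb), expected_hyb)
  # the default hybrid sits in the 1e5-1e6 parameter decade
  expect_gt(count_parameters(hyb), 1e5)
  expect_lt(count_parameters(hyb), 1e6)
})

test_that("Kaiming initialization has the He-normal scale, zero biases, seeded", {
  m <- kaiming_init(build_cnn(), seed = 9)
  conv2 <- m$layers[[5]]
  expect_equal(length(conv2$W), 128 * 256 * 7)
  expect_lt(abs(sd(conv2$W) - sqrt(2 / (256 * 7))) / sqrt(2 / (256 * 7)),
            0.05)
  expect_true(all(conv2$b == 0))
  dense <- m$layers[[10]]
  expect_lt(abs(sd(dense$W) - sqrt(2 / ncol(dense$W))) /
              sqrt(2 / ncol(dense$W)), 0.05)
  m2 <- kaiming_init(build_cnn(), seed = 9)
  expect_identical(m$layers, m2$layers)
  m3 <- kaiming_init(build_cnn(), seed = 10)
  expect_false(identical(m$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("weighted cross-entropy reduces to the unweighted loss and hand values", {
  probs <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0))
  expect_equal(weighted_cross_entropy(probs, c(0L, 2L)), 0)
  set.seed(11)
  p <- matrix(runif(40), 8, 5); p <- p / rowSums(p)
  y <- sample(0:4, 8, replace = TRUE)
  expect_lt(abs(weighted_cross_entropy(p, y) -
                  mean(-log(p[cbind(1:8, y + 1)]))), 1e-9)
  # two-class toy with weights (2, 1): hand computation
  p2 <- rbind(c(0.8, 0.2, 0, 0, 0), c(0.3, 0.7, 0, 0, 0))
  hand <- (2 * -log(0.8) + 1 * -log(0.7)) / 3
  expect_equal(weighted_cross_entropy(p2, c(0L, 1L), c(2, 1, 1, 1, 1)),
               hand, tolerance = 1e-12)
  expect_warning(weighted_cross_entropy(rbind(c(0, 1, 0, 0, 0)), 0L),
                 "clamping")
})

test_that("imbalance-aware weights penalize the always-majority classifier", {
  set.seed(12)
  y <- c(rep(0L, 90), rep(2L, 10))
  w <- inverse_frequency_weights(y)
  always_major <- matrix(rep(c(0.96, 0.01, 0.01, 0.01, 0.01), 100),
                         100, 5, byrow = TRUE)
  balanced <- matrix(0.01, 100, 5)
  balanced[cbind(1:100, y + 1)] <- 0.96
  expect_gt(weighted_cross_entropy(always_major, y, w),
            weighted_cross_entropy(balanced, y, w))
})

test_that("backpropagation matches numerical gradients on a small hybrid", {
  set.seed(13)
  cfg <- hybrid_config(filters = c(4L, 3L), kernel_sizes = c(5L, 3L),
                       strides = c(2L, 2L), dropout_rates = c(0, 0),
                       lstm_hidden = 4L, input_len = 40L)
  m <- kaiming_init(build_hybrid(cfg), seed = 2)
  X <- matrix(rnorm(3 * 40), 3, 40)
  y <- c(0L, 2L, 4L)
  w <- c(1, 1, 2, 1, 1)
  fw <- ns$nn_forward(m, X, keep_caches = TRUE)
  lo <- ns$wce_from_logits(fw$logits, y, w)
  gr <- ns$nn_backward(m, lo$dlogits, fw$caches)
  eps <- 1e-6
  worst <- 0
  for (k in seq_along(m$layers)) {
    g <- gr[[k]]
    if (is.null(g)) next
    for (nm in names(g)) {
      arr <- m$layers[[k]][[nm]]
      for (j in sample(length(arr), min(6, length(arr)))) {
        m2 <- m; m2$layers[[k]][[nm]][j] <- arr[j] + eps
        lp <- ns$wce_from_logits(ns$nn_forward(m2, X)$logits, y, w)$loss
        m2$layers[[k]][[nm]][j] <- arr[j] - eps
        lm <- ns$wce_from_logits(ns$nn_forward(m2, X)$logits, y, w)$loss
        num <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(num - g[[nm]][j]) /
                       max(1e-8, abs(num) + abs(g[[nm]][j])))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training is deterministic, a zero learning rate is a null update, and separable data is learned", {
  ds <- make_separable_dataset()
  cfg0 <- train_config(epochs = 1L, learning_rate = 0, seed = 5)
  m <- kaiming_init(build_hybrid(hybrid_config(
    filters = c(8L, 6L), kernel_sizes = c(5L, 3L), strides = c(2L, 2L),
    dropout_rates = c(0.1, 0.1), lstm_hidden = 6L, input_len = 64L)),
    seed = 5)
  fit0 <- train_model(m, ds, NULL, cfg0)
  expect_equal(nrow(fit0$history), 1)
  expect_identical(fit0$model$layers, m$layers)

  cfg <- train_config(epochs = 20L, batch_size = 16L, learning_rate = 2e-3,
                      optimizer_name = "adam", seed = 6)
  fit1 <- train_model(m, ds, ds, cfg)
  fit2 <- train_model(m, ds, ds, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_gte(fit1$history$train_acc[20], 0.95)

  expect_error(train_model(m, beat_dataset(matrix(0, 0, 64), integer(0)),
                           NULL, cfg), "empty")
})
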