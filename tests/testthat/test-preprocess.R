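test_that("z-scoring centers and scales with the zero-variance convention", {
  expect_equal(zscore(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(zscore(c(0, 2)), c(-1, 1))  # population SD
  set.seed(4)
  v <- zscore(rnorm(100, 5, 3))
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  # idempotence
  expect_equal(zscore(v), v, tolerance = 1e-9)
  expect_error(zscore(c(1, NA, 2)), "finite")
})

test_that("majority subsampling is a per-beat Bernoulli draw that spares minorities", {
  ds <- generate_beat_dataset(synthetic_spec(400, seed = 31), segment_len = 40L)
  expect_identical(subsample_majority(ds, keep_prob = 1, seed = 1), ds)
  none <- subsample_majority(ds, keep_prob = 0, seed = 1)
  expect_equal(unname(none$class_counts["N"]), 0L)
  some <- subsample_majority(ds, keep_prob = 0.15, seed = 2)
  # minority classes exactly unchanged, survivor order preserved
  expect_equal(some$class_counts[-1], ds$class_counts[-1])
  surv <- some$segments[some$labels != 0L, , drop = FALSE]
  expect_equal(surv, ds$segments[ds$labels != 0L, , drop = FALSE])
  expect_error(subsample_majority(ds, keep_prob = 1.5), "keep_prob")
})

test_that("retention rate concentrates on the keep probability", {
  # binomial bound on a large pure-majority dataset across seeds
  n <- 100000L
  ds <- generate_beat_dataset(synthetic_spec(n, c(1, 0, 0, 0, 0),
                                             noise_sd = 0, baseline_amp = 0,
                                             seed = 1),
                              segment_len = 32L)
  tol <- 3 * sqrt(0.15 * 0.85 / n)
  for (s in 1:10) {
    kept <- subsample_majority(ds, keep_prob = 0.15, seed = s)
    expect_lt(abs(nrow(kept$segments) / n - 0.15), tol)
  }
})

test_that("non-finite segments are removed exactly", {
  ds <- generate_beat_dataset(synthetic_spec(20, seed = 3), segment_len = 40L)
  expect_identical(clean_nonfinite(ds), ds)
  bad <- ds
  bad$segments[3, 5] <- NaN
  bad$segments[7, 1] <- Inf
  bad$segments[11, 40] <- NA
  cleaned <- clean_nonfinite(beat_dataset(bad$segments, bad$labels))
  expect_equal(nrow(cleaned$segments), 17)
  expect_true(all(is.finite(cleaned$segments)))
})

test_that("noise scale estimator equals median absolute coefficient over 0.6745", {
  expect_equal(estimate_sigma(c(0, 0, 0)), 0)
  expect_equal(estimate_sigma(c(0.6745, -0.6745, 0.6745)), 1.0)
  expect_equal(estimate_sigma(c(1, -1, 2, -2)), 1.5 / 0.6745)
  expect_error(estimate_sigma(numeric(0)), "nonempty")
})

test_that("universal threshold follows sigma * sqrt(2 ln n)", {
  expect_equal(universal_threshold(3.7, 1), 0)
  expect_equal(universal_threshold(0, 999), 0)
  expect_equal(universal_threshold(1, 1024), sqrt(2 * log(1024)))
  expect_error(universal_threshold(1, 0), "count")
  expect_error(universal_threshold(-1, 10), "nonnegative")
})

test_that("estimator and threshold match brute-force recomputation on random draws", {
  set.seed(77)
  for (i in 1:20) {
    cd <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 3))
    # independent route: explicit sort-based median
    sv <- sort(abs(cd))
    m <- length(sv)
    med <- if (m %% 2 == 1) sv[(m + 1) / 2] else (sv[m / 2] + sv[m / 2 + 1]) / 2
    expect_lt(abs(estimate_sigma(cd) - med / 0.6745), 1e-12)
    n <- sample(2:5000, 1)
    expect_lt(abs(universal_threshold(med / 0.6745, n) -
                    (med / 0.6745) * sqrt(2 * log(n))), 1e-12)
  }
})

test_that("hard thresholding contracts details and zero lambda is the identity", {
  set.seed(5)
  x <- rnorm(280)
  expect_lt(max(abs(denoise_dwt(x, lambda = 0) - x)), 1e-8)
  expect_equal(denoise_dwt(numeric(64) + 0), numeric(64))
  # details never grow in magnitude
  wd <- wavedec(x, 3, "sym5")
  sigma <- estimate_sigma(wd$details[[3]])
  lam <- universal_threshold(sigma, 280)
  y <- denoise_dwt(x)
  wdy <- wavedec(y, 3, "sym5")
  for (k in 1:3) {
    thr <- wd$details[[k]]
    thr[abs(thr) <= lam] <- 0
    expect_true(all(abs(thr) <= abs(wd$details[[k]]) + 1e-12))
  }
  expect_error(denoise_dwt(x, wavelet_name = "nope"), "unknown wavelet")
})

test_that("denoising reduces the error against the clean template", {
  tpl <- beat_templates()$N
  clean <- ns$place_template(tpl$waveform, tpl$r_offset, 280L, 99L)
  better <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    noisy <- clean + rnorm(280, 0, 0.1)
    den <- denoise_dwt(noisy)
    if (mean((den - clean)^2) < mean((noisy - clean)^2)) better <- better + 1
  }
  expect_equal(better, 50)
})

test_that("R peaks are recovered from annotations and detected without them", {
  spec0 <- synthetic_spec(10, rep(0.2, 5), noise_sd = 0, baseline_amp = 0,
                          seed = 41)
  rec0 <- generate_record(spec0, 75)
  p <- detect_r_peaks(rec0)
  expect_equal(length(p), 10)
  expect_true(all(abs(p - rec0$annotations$sample) <= 2))
  expect_false(is.unsorted(p, strictly = TRUE))

  flat <- ecg_record(rep(0, 2000), 360)
  expect_length(detect_r_peaks(flat, use_annotations = FALSE), 0)
  expect_error(detect_r_peaks(ecg_record(rnorm(100), 360)), "shorter")

  # detector sensitivity on a noisy record without annotations
  spec <- synthetic_spec(60, noise_sd = 0.05, seed = 42)
  rec <- generate_record(spec, 75)
  det <- detect_r_peaks(ecg_record(rec$signal, rec$fs),
                        use_annotations = FALSE)
  tol <- round(0.05 * rec$fs)
  sens <- mean(vapply(rec$annotations$sample,
                      function(s) any(abs(det - s) <= tol), logical(1)))
  expect_gte(sens, 0.95)
  expect_true(all(diff(det) >= round(0.2 * rec$fs)))
})

test_that("segmentation drops boundary windows and aligns the R peak", {
  spec <- synthetic_spec(12, rep(0.2, 5), noise_sd = 0, baseline_amp = 0,
                         seed = 43)
  rec <- generate_record(spec, 75)
  cfg <- segmentation_config(pre_samples = 99, post_samples = 180)
  # a peak too close to the start is dropped
  ds <- segment_beats(rec, c(50L, detect_r_peaks(rec)), cfg)
  expect_equal(ncol(ds$segments), 280)
  interior <- detect_r_peaks(rec)
  interior <- interior[interior - 99 >= 1 &
                         interior + 180 <= length(rec$signal)]
  expect_equal(nrow(ds$segments), length(interior))
  # each segment's maximum sits at the anchor index (within 2)
  for (i in seq_len(nrow(ds$segments))) {
    expect_lte(abs(which.max(ds$segments[i, ]) - 100), 2)
  }
})

test_that("the composed pipeline yields a finite labeled fixed-length dataset", {
  spec <- synthetic_spec(40, noise_sd = 0.05, seed = 44)
  rec <- generate_record(spec, 75)
  ds <- preprocess_record(rec, seed = 2)
  expect_s3_class(ds, "beat_dataset")
  expect_true(all(is.finite(ds$segments)))
  expect_equal(ncol(ds$segments), 280)
  expect_true(all(ds$labels %in% 0:4))
  # z-scoring is applied before denoising: row means near zero
  expect_lt(max(abs(rowMeans(ds$segments))), 0.5)
})
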