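test_that("symbol consolidation follows the standard five-class mapping", {
  expect_equal(map_to_aami("V"), "V")
  expect_equal(map_to_aami("F"), "F")
  expect_equal(map_to_aami("+"), "excluded")
  expect_equal(map_to_aami(c("N", "L", "R", "e", "j")), rep("N", 5))
  expect_equal(map_to_aami(c("A", "a", "J", "S")), rep("S", 5 - 1))
  expect_equal(map_to_aami(c("V", "E")), rep("V", 2))
  expect_equal(map_to_aami(c("/", "f", "Q")), rep("Q", 3))
  # unknown symbols are excluded, never an error
  expect_equal(map_to_aami("~"), "excluded")
  expect_equal(map_to_aami("zz"), "excluded")
})

test_that("beat_dataset enforces consistency invariants", {
  expect_error(beat_dataset(matrix(0, 3, 4), c(0L, 1L)), "row count")
  expect_error(beat_dataset(matrix(0, 2, 4), c(0L, 7L)), "labels")
  ds <- beat_dataset(matrix(rnorm(12), 3, 4), c(0L, 2L, 2L))
  expect_equal(sum(ds$class_counts), 3L)
  expect_equal(unname(ds$class_counts["V"]), 2L)
})

test_that("stratified split allocates counts by floor plus largest remainder", {
  # exact divisibility: 10 per class at 0.8 -> 8/2 per class
  segs <- matrix(rnorm(50 * 8), 50, 8)
  ds <- beat_dataset(segs, rep(0:4, each = 10))
  sp <- stratified_split(ds, 0.8, seed = 1)
  expect_equal(unname(sp$train$class_counts), rep(8L, 5))
  expect_equal(unname(sp$test$class_counts), rep(2L, 5))

  # independently enumerated allocation for n_c = (100, 37, 19, 7, 11):
  # exact shares (80, 29.6, 15.2, 5.6, 8.8), floors sum 137, target
  # round(174*0.8) = 139, two leftover slots go to the largest remainders
  # (.8 for Q, then the .6 tie broken by class order -> S)
  counts <- c(100L, 37L, 19L, 7L, 11L)
  ds2 <- beat_dataset(matrix(0, sum(counts), 4),
                      rep(0:4, times = counts))
  sp2 <- stratified_split(ds2, 0.8, seed = 3)
  expect_equal(unname(sp2$train$class_counts), c(80L, 30L, 15L, 5L, 9L))
})

test_that("the split partitions the input and is seed-stable", {
  ds <- generate_beat_dataset(synthetic_spec(300, seed = 5), segment_len = 40L)
  sp <- stratified_split(ds, 0.8, seed = 11)
  expect_equal(nrow(sp$train$segments) + nrow(sp$test$segments), 300)
  # multiset union equals input: sort rows lexicographically and compare
  key <- function(m) sort(apply(m, 1, function(r) paste(signif(r, 12), collapse = ",")))
  expect_equal(sort(c(key(sp$train$segments), key(sp$test$segments))),
               key(ds$segments))
  # per-class train fraction within one beat of 0.8
  expect_true(all(abs(sp$train$class_counts - 0.8 * ds$class_counts) < 1))

  sp_b <- stratified_split(ds, 0.8, seed = 11)
  expect_identical(sp$train, sp_b$train)
  sp_c <- stratified_split(ds, 0.8, seed = 12)
  expect_equal(sp_c$train$class_counts, sp$train$class_counts)
  expect_false(identical(sp_c$train$segments, sp$train$segments))

  expect_error(stratified_split(beat_dataset(matrix(0, 0, 4), integer(0))),
               "empty")
})

test_that("beat datasets round-trip through the delimited container", {
  ds <- generate_beat_dataset(synthetic_spec(30, seed = 2), segment_len = 48L)
  path <- file.path(tempdir(), "beats.csv")
  write_beat_dataset(ds, path, meta = list(seed = 2))
  back <- read_beat_dataset(path)
  expect_equal(back$segments, ds$segments, tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$n_beats, 30)
  expect_error(read_beat_dataset(file.path(tempdir(), "nope.csv")), "no such")
})

test_that("WFDB records round-trip within quantization tolerance", {
  spec <- synthetic_spec(5, rep(0.2, 5), noise_sd = 0.02, seed = 8)
  rec <- generate_record(spec, 75)
  d <- file.path(tempdir(), "wfdbrt")
  write_wfdb(rec, d, "r1")
  back <- read_wfdb(file.path(d, "r1"))
  expect_equal(back$fs, rec$fs)
  # gain 1000 => half-LSB quantization error 5e-4
  expect_lt(max(abs(back$signal - rec$signal)), 5.01e-4)
  expect_equal(as.integer(back$annotations$sample),
               as.integer(rec$annotations$sample))
  expect_identical(back$annotations$symbol, rec$annotations$symbol)
  # annotations come back in increasing order
  expect_false(is.unsorted(back$annotations$sample, strictly = TRUE))
})

test_that("long annotation gaps survive via SKIP intervals", {
  rec <- ecg_record(rnorm(200000), 360,
                    data.frame(sample = c(50L, 100000L, 199999L),
                               symbol = c("N", "V", "f")))
  d <- file.path(tempdir(), "wfdbskip")
  write_wfdb(rec, d, "g")
  back <- read_wfdb(file.path(d, "g"))
  expect_equal(as.integer(back$annotations$sample),
               c(50L, 100000L, 199999L))
  expect_identical(back$annotations$symbol, c("N", "V", "f"))
})

test_that("malformed WFDB inputs raise format errors", {
  d <- file.path(tempdir(), "wfdbbad")
  dir.create(d, showWarnings = FALSE)
  # header declares 2 channels / more samples than the signal file holds
  writeLines(c("bad 2 360 5000",
               "bad.dat 16 1000(0)/mV 16 0 0 0 0 ECG",
               "bad.dat 16 1000(0)/mV 16 0 0 0 0 ECG"),
             file.path(d, "bad.hea"))
  con <- file(file.path(d, "bad.dat"), "wb")
  writeBin(integer(100), con, size = 2); close(con)
  expect_error(read_wfdb(file.path(d, "bad")), "declares")
  expect_error(read_wfdb(file.path(d, "missing")), "missing header")
})
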