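# Preprocessing pipeline: R-peak detection, beat segmentation, z-score
# normalization, probabilistic majority-class subsampling, non-finite
# cleanup, and DWT denoising with the universal hard threshold.

#' Beat segmentation window
#'
#' @param pre_samples Samples before the R peak (default 99).
#' @param post_samples Samples after the R peak (default 180); segment
#'   length is `pre_samples + post_samples + 1`.
#' @param use_annotations Use the record's annotations (refined to the
#'   local maximum) instead of the built-in detector.
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(pre_samples = 99L, post_samples = 180L,
                                use_annotations = TRUE) {
  if (!is_count(pre_samples) || !is_count(post_samples))
    abort_validation("pre_samples and post_samples must be counts >= 1")
  structure(list(pre_samples = as.integer(pre_samples),
                 post_samples = as.integer(post_samples),
                 use_annotations = isTRUE(use_annotations)),
            class = "segmentation_config")
}

#' Detect R peaks in an ECG record
#'
#' When the record carries annotations (and `use_annotations` is TRUE),
#' each annotated index is refined to the local signal maximum within
#' +/- 0.05 s. Otherwise a Pan-Tompkins-style energy detector runs:
#' band-pass (2-20 Hz) -> squaring -> moving-window integration ->
#' adaptive threshold, with a 0.2 s refractory period between peaks.
#'
#' @param rec An [ecg_record()].
#' @param use_annotations Prefer annotated beat locations when available.
#' @return Strictly increasing integer vector of R-peak sample indices.
#' @export
detect_r_peaks <- function(rec, use_annotations = TRUE) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  x <- rec$signal
  if (length(x) < 2 * fs)
    abort_validation("signal shorter than two seconds")
  half_win <- round(0.05 * fs)
  if (use_annotations && !is.null(rec$annotations) &&
      nrow(rec$annotations) > 0) {
    peaks <- vapply(rec$annotations$sample, function(s) {
      lo <- max(1, s - half_win)
      hi <- min(length(x), s + half_win)
      lo + which.max(x[lo:hi]) - 1
    }, numeric(1))
    return(sort(unique(as.integer(peaks))))
  }
  pan_tompkins(x, fs)
}

# Pan-Tompkins-style QRS detection for unannotated signals. The derivative
# stage of the classical detector is replaced by plain energy (squared
# band-passed signal): differentiation suppresses wide low-frequency
# complexes (fusion / unclassifiable morphologies) far below the noise
# floor, whereas band-limited energy keeps them detectable. The pass band
# is 2-20 Hz so those complexes stay inside it while baseline wander and
# high-frequency noise are rejected.
pan_tompkins <- function(x, fs) {
  ny <- fs / 2
  bf <- signal::butter(2, c(2, 20) / ny, type = "pass")
  filt <- signal::filtfilt(bf, x - mean(x))
  sq <- filt^2
  win <- max(1L, round(0.15 * fs))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  if (max(integ) <= 0) return(integer(0))
  # adaptive threshold: a fraction of the strongest complex, floored at a
  # multiple of the quiet-baseline energy (10th percentile)
  thr <- max(0.08 * max(integ),
             3 * stats::quantile(integ, 0.1, names = FALSE))
  refractory <- round(0.2 * fs)
  above <- integ > thr
  # group contiguous above-threshold samples into one QRS candidate each
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s + which.max(integ[s:e]) - 1L,
                 starts[runs$values], ends[runs$values])
  peaks <- integer(0)
  half_win <- round(0.15 * fs)
  for (p in cand) {
    lo <- max(1L, p - half_win)
    hi <- min(length(x), p + half_win)
    refined <- as.integer(lo + which.max(x[lo:hi]) - 1L)
    if (length(peaks) && refined - peaks[length(peaks)] < refractory) next
    peaks <- c(peaks, refined)
  }
  peaks
}

#' Segment a record into fixed-length beats anchored at R peaks
#'
#' One segment of `pre + post + 1` samples per peak whose full window lies
#' inside the signal; peaks whose window would overrun a boundary are
#' dropped (and counted in a log message). Labels are carried from the
#' record's annotations via [map_to_aami()] by nearest annotated beat;
#' beats whose symbol maps to "excluded" are dropped.
#'
#' @param rec An [ecg_record()].
#' @param peaks Integer vector of R-peak indices.
#' @param cfg A [segmentation_config()].
#' @return A [beat_dataset()].
#' @export
segment_beats <- function(rec, peaks, cfg = segmentation_config()) {
  stopifnot(inherits(rec, "ecg_record"))
  n <- length(rec$signal)
  ok <- peaks - cfg$pre_samples >= 1 & peaks + cfg$post_samples <= n
  dropped <- sum(!ok)
  if (dropped > 0)
    log_msg(dropped, " boundary peak(s) dropped during segmentation")
  peaks <- peaks[ok]
  labels <- rep(0L, length(peaks))
  keep <- rep(TRUE, length(peaks))
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0) {
    tol <- round(0.05 * rec$fs)
    for (i in seq_along(peaks)) {
      d <- abs(rec$annotations$sample - peaks[i])
      j <- which.min(d)
      cls <- if (d[j] <= tol) map_to_aami(rec$annotations$symbol[j])
             else "excluded"
      if (cls == "excluded") keep[i] <- FALSE
      else labels[i] <- aami_code(cls)
    }
  }
  if (any(!keep))
    log_msg(sum(!keep), " beat(s) without a beat annotation excluded")
  peaks <- peaks[keep]; labels <- labels[keep]
  len <- cfg$pre_samples + cfg$post_samples + 1L
  segs <- matrix(0, length(peaks), len)
  for (i in seq_along(peaks)) {
    segs[i, ] <- rec$signal[(peaks[i] - cfg$pre_samples):
                              (peaks[i] + cfg$post_samples)]
  }
  beat_dataset(segs, labels)
}

#' Z-score normalization
#'
#' Centers to mean 0 and scales to (population) SD 1. Constant segments
#' return all zeros.
#'
#' @param segment Finite numeric vector.
#' @return Normalized vector of the same length.
#' @export
zscore <- function(segment) {
  if (any(!is.finite(segment)))
    abort_validation("zscore requires a finite segment")
  mu <- mean(segment)
  sdev <- sqrt(mean((segment - mu)^2))
  if (sdev == 0) return(segment * 0)
  (segment - mu) / sdev
}

#' Z-score every segment of a dataset
#' @param ds A [beat_dataset()].
#' @return The dataset with each row normalized.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "beat_dataset"))
  segs <- t(apply(ds$segments, 1, zscore))
  beat_dataset(segs, ds$labels)
}

#' Probabilistic subsampling of the majority class
#'
#' Every beat outside the target class is retained; each target-class beat
#' is retained by an independent seeded Bernoulli(`keep_prob`) draw. The
#' order of survivors is preserved, so minority-class counts are exactly
#' unchanged.
#'
#' @param ds A [beat_dataset()].
#' @param keep_prob Retention probability in [0, 1] (default 0.15, the
#'   majority-class retention rate used throughout the package).
#' @param target_class Class symbol to subsample (default "N").
#' @param seed Integer seed.
#' @return A [beat_dataset()].
#' @export
subsample_majority <- function(ds, keep_prob = 0.15, target_class = "N",
                               seed = 1L) {
  stopifnot(inherits(ds, "beat_dataset"))
  if (keep_prob < 0 || keep_prob > 1)
    abort_validation("keep_prob must lie in [0, 1]")
  code <- aami_code(target_class)
  with_seed(seed, {
    is_target <- ds$labels == code
    u <- stats::runif(nrow(ds$segments))
    keep <- !is_target | (u < keep_prob)
    log_msg(sum(is_target & !keep), " ", target_class,
            " beat(s) removed by subsampling")
    beat_dataset(ds$segments[keep, , drop = FALSE], ds$labels[keep])
  })
}

#' Remove segments containing non-finite values
#' @param ds A [beat_dataset()].
#' @return A [beat_dataset()] whose segments are entirely finite.
#' @export
clean_nonfinite <- function(ds) {
  stopifnot(inherits(ds, "beat_dataset"))
  bad <- !apply(is.finite(ds$segments), 1, all)
  if (any(bad)) log_msg(sum(bad), " segment(s) with non-finite values removed")
  beat_dataset(ds$segments[!bad, , drop = FALSE], ds$labels[!bad])
}

#' Noise-scale estimate from detail coefficients
#'
#' Returns `median(|cd|) / 0.6745`, the robust noise-scale estimator for
#' Gaussian noise applied to the finest detail band.
#'
#' @param detail_coeffs Nonempty numeric vector of detail coefficients.
#' @return Nonnegative noise scale.
#' @export
estimate_sigma <- function(detail_coeffs) {
  if (length(detail_coeffs) == 0)
    abort_validation("detail coefficients must be nonempty")
  stats::median(abs(detail_coeffs)) / 0.6745
}

#' Universal (hard) threshold
#'
#' `lambda = sigma * sqrt(2 * ln(n))` for signal length `n` (natural log).
#'
#' @param sigma Nonnegative noise scale.
#' @param n Signal length (>= 1).
#' @return The threshold value.
#' @export
universal_threshold <- function(sigma, n) {
  if (!is_count(n)) abort_validation("n must be a count >= 1")
  if (sigma < 0) abort_validation("sigma must be nonnegative")
  sigma * sqrt(2 * log(n))
}

#' Wavelet denoising with the universal hard threshold
#'
#' Decomposes the segment to `levels` with the named wavelet, estimates the
#' noise scale from the finest detail band ([estimate_sigma()]), computes
#' the universal threshold with `n` = segment length, zeroes every detail
#' coefficient with magnitude at or below the threshold (hard
#' thresholding; approximation coefficients untouched), and reconstructs.
#'
#' @param segment Numeric vector of length >= `2^levels`.
#' @param wavelet_name Mother wavelet (default "sym5").
#' @param levels Decomposition depth (default 3).
#' @param lambda Optional threshold override; `NULL` (default) uses the
#'   estimator, 0 gives a pure round-trip.
#' @return Denoised vector at the original length.
#' @export
denoise_dwt <- function(segment, wavelet_name = "sym5", levels = 3L,
                        lambda = NULL) {
  wd <- wavedec(segment, levels = levels, wavelet_name = wavelet_name)
  if (is.null(lambda)) {
    sigma <- estimate_sigma(wd$details[[levels]])  # finest band
    lambda <- universal_threshold(sigma, length(segment))
  }
  wd$details <- lapply(wd$details, function(d) {
    d[abs(d) <= lambda] <- 0
    d
  })
  waverec(wd)
}

#' Denoise every segment of a dataset
#' @inheritParams denoise_dwt
#' @param ds A [beat_dataset()].
#' @return The dataset with each row denoised.
#' @export
denoise_dataset <- function(ds, wavelet_name = "sym5", levels = 3L) {
  stopifnot(inherits(ds, "beat_dataset"))
  segs <- t(apply(ds$segments, 1, denoise_dwt, wavelet_name = wavelet_name,
                  levels = levels))
  beat_dataset(segs, ds$labels)
}

#' Full preprocessing pipeline for one record
#'
#' Composition in pipeline order: R peaks -> segmentation -> z-score
#' normalization -> majority-class subsampling -> non-finite cleanup ->
#' per-segment DWT denoising.
#'
#' @param rec An [ecg_record()].
#' @param cfg A [segmentation_config()].
#' @param keep_prob Majority-class retention probability.
#' @param wavelet_name,levels Denoising parameters.
#' @param seed Seed for the subsampling draw.
#' @return A finite, fixed-length, labeled [beat_dataset()].
#' @export
preprocess_record <- function(rec, cfg = segmentation_config(),
                              keep_prob = 0.15, wavelet_name = "sym5",
                              levels = 3L, seed = 1L) {
  peaks <- detect_r_peaks(rec, use_annotations = cfg$use_annotations)
  ds <- segment_beats(rec, peaks, cfg)
  ds <- normalize_dataset(ds)
  ds <- subsample_majority(ds, keep_prob = keep_prob, seed = seed)
  ds <- clean_nonfinite(ds)
  denoise_dataset(ds, wavelet_name = wavelet_name, levels = levels)
}
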