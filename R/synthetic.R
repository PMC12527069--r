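# Synthetic annotated ECG generation.
#
# The generator emulates the study conditions of a single-lead 360 Hz
# ambulatory recording: five beat morphologies with the severe class
# imbalance of an ambulatory arrhythmia database, additive white
# measurement noise and sinusoidal baseline wander (respiratory drift).

#' Default class mixture
#'
#' Per-class proportions of the five AAMI classes as observed in the
#' consolidated ambulatory arrhythmia corpus the package emulates
#' (N 66.7%, S 5.8%, V 16.4%, F 1.9%, Q 9.2%).
#' @return Named numeric vector of five proportions summing to 1.
#' @export
default_class_proportions <- function() {
  p <- c(N = 27872, S = 2441, V = 6840, F = 787, Q = 3856)
  p / sum(p)
}

#' Specification of a synthetic ECG dataset or record
#'
#' @param n_beats Number of beats to generate (>= 5).
#' @param class_proportions Five nonnegative fractions summing to 1
#'   (order N, S, V, F, Q). Defaults to the imbalanced ambulatory mixture
#'   of [default_class_proportions()].
#' @param noise_sd SD of additive white noise in mV (>= 0).
#' @param baseline_amp,baseline_freq Amplitude (mV) and frequency (Hz) of
#'   sinusoidal baseline wander.
#' @param seed Integer seed; identical specs produce bit-identical output.
#' @param fs Sampling rate in Hz.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_beats,
                           class_proportions = default_class_proportions(),
                           noise_sd = 0.05,
                           baseline_amp = 0.1,
                           baseline_freq = 0.3,
                           seed = 1L,
                           fs = 360) {
  if (!is_count(n_beats, min = 5))
    abort_validation("n_beats must be an integer >= 5")
  if (length(class_proportions) != 5 || any(!is.finite(class_proportions)) ||
      any(class_proportions < 0))
    abort_validation("class_proportions must be five nonnegative fractions")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    abort_validation("class_proportions must sum to 1 (within 1e-9)")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    abort_validation("noise_sd must be a nonnegative scalar")
  if (baseline_amp < 0 || baseline_freq < 0)
    abort_validation("baseline_amp and baseline_freq must be nonnegative")
  structure(list(n_beats = as.integer(n_beats),
                 class_proportions = unname(class_proportions),
                 noise_sd = noise_sd,
                 baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq,
                 seed = as.integer(seed),
                 fs = fs),
            class = "synthetic_spec")
}

# Crop/pad a template so that its R peak lands at index `pre + 1` of a
# window of `len` samples; regions outside the template are zero.
place_template <- function(waveform, r_offset, len, pre) {
  seg <- numeric(len)
  src <- seq_along(waveform) - r_offset + pre + 1L  # destination indices
  keep <- src >= 1L & src <= len
  seg[src[keep]] <- waveform[keep]
  seg
}

#' Generate a labeled dataset of pre-segmented heartbeats
#'
#' Draws `n_beats` class labels from the spec's mixture (a multinomial draw
#' under the spec's seed), places the class template with the R peak at
#' index `pre_samples + 1`, and corrupts each segment with white noise and
#' a random-phase baseline-wander sinusoid.
#'
#' @param spec A [synthetic_spec()].
#' @param segment_len Segment length in samples (>= 32; default 280).
#' @param pre_samples Samples before the R peak (default 99, i.e. the R
#'   peak sits at index 100 of each 280-sample segment).
#' @return A [beat_dataset()] with integer labels 0-4.
#' @examples
#' ds <- generate_beat_dataset(synthetic_spec(50, seed = 1))
#' dim(ds$segments)
#' @export
generate_beat_dataset <- function(spec, segment_len = 280L,
                                  pre_samples = 99L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is_count(segment_len, min = 32))
    abort_validation("segment_len must be an integer >= 32")
  tpl <- beat_templates(spec$fs)
  with_seed(spec$seed, {
    labels <- sample(0:4, spec$n_beats, replace = TRUE,
                     prob = spec$class_proportions)
    segs <- matrix(0, spec$n_beats, segment_len)
    tt <- (seq_len(segment_len) - 1) / spec$fs
    for (i in seq_len(spec$n_beats)) {
      tp <- tpl[[labels[i] + 1L]]
      x <- place_template(tp$waveform, tp$r_offset, segment_len,
                          as.integer(pre_samples))
      if (spec$baseline_amp > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + spec$baseline_amp *
          sin(2 * pi * spec$baseline_freq * tt + phase)
      }
      if (spec$noise_sd > 0)
        x <- x + stats::rnorm(segment_len, 0, spec$noise_sd)
      segs[i, ] <- x
    }
    beat_dataset(segs, labels)
  })
}

#' Generate a continuous annotated synthetic ECG record
#'
#' Concatenates noise-corrupted class templates at a fixed beat interval
#' derived from the heart rate, and returns the signal together with
#' ground-truth R-peak annotations (sample index + class symbol). With
#' `noise_sd = 0` and `baseline_amp = 0` the signal is exactly the
#' overlap-added template train.
#'
#' @param spec A [synthetic_spec()].
#' @param heart_rate_bpm Heart rate in beats per minute (30-220).
#' @return An [ecg_record()].
#' @export
generate_record <- function(spec, heart_rate_bpm = 75) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(heart_rate_bpm) || heart_rate_bpm < 30 ||
      heart_rate_bpm > 220)
    abort_validation("heart_rate_bpm must lie in [30, 220]")
  tpl <- beat_templates(spec$fs)
  interval <- round(spec$fs * 60 / heart_rate_bpm)
  tpl_len <- length(tpl[[1]]$waveform)
  n <- spec$n_beats
  total <- (n - 1L) * interval + tpl_len
  with_seed(spec$seed, {
    labels <- sample(0:4, n, replace = TRUE, prob = spec$class_proportions)
    sig <- numeric(total)
    ann_idx <- integer(n)
    for (i in seq_len(n)) {
      tp <- tpl[[labels[i] + 1L]]
      s0 <- (i - 1L) * interval
      rng <- (s0 + 1L):(s0 + tpl_len)
      sig[rng] <- sig[rng] + tp$waveform   # overlap-add at high rates
      ann_idx[i] <- s0 + tp$r_offset
    }
    if (spec$baseline_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(total) - 1) / spec$fs
      sig <- sig + spec$baseline_amp *
        sin(2 * pi * spec$baseline_freq * tt + phase)
    }
    if (spec$noise_sd > 0) sig <- sig + stats::rnorm(total, 0, spec$noise_sd)
    ecg_record(sig, fs = spec$fs,
               annotations = data.frame(sample = ann_idx,
                                        symbol = AAMI_CLASSES[labels + 1L],
                                        stringsAsFactors = FALSE))
  })
}
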