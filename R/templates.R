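# Parameterized heartbeat morphology templates.
#
# Each template is a sum of Gaussian deflections standing in for the P wave,
# the QRS complex and the T wave, with per-class parameter sets chosen to
# mimic the qualitative morphology of the five AAMI classes: a full
# P-QRS-T normal beat (N), a P-less narrow-complex supraventricular beat
# (S), a wide bizarre complex with discordant T (V), an intermediate fused
# morphology (F) and a low-amplitude atypical complex (Q).

gauss_bump <- function(t, mu, sd, amp) amp * exp(-0.5 * ((t - mu) / sd)^2)

#' Heartbeat morphology templates for the five AAMI classes
#'
#' Builds one fixed template per class from parameterized Gaussian
#' deflections at the given sampling rate. Templates span 0.3 s before to
#' roughly 0.53 s after the R peak; the R peak is the global maximum of each
#' waveform and its sample index is returned as `r_offset`.
#'
#' @param fs Sampling rate in Hz (default 360).
#' @return Named list (N, S, V, F, Q) of templates; each is a list with
#'   `class_label`, `waveform` (numeric, mV) and `r_offset` (1-based sample
#'   index of the R peak).
#' @examples
#' tpl <- beat_templates()
#' which.max(tpl$N$waveform) == tpl$N$r_offset
#' @export
beat_templates <- function(fs = 360) {
  n <- round(0.833 * fs)              # ~300 samples at 360 Hz
  r_off <- round(0.3 * fs) + 1L       # R peak 0.3 s into the template
  t <- (seq_len(n) - r_off) / fs      # seconds relative to the R peak

  shapes <- list(
    N = list(c(-0.17, 0.025, 0.15),   # P
             c(-0.028, 0.010, -0.12), # Q
             c(0, 0.012, 1.00),       # R
             c(0.028, 0.010, -0.25),  # S
             c(0.30, 0.060, 0.35)),   # T
    S = list(c(0, 0.010, 0.95),
             c(0.026, 0.009, -0.22),
             c(0.22, 0.050, 0.25)),
    V = list(c(-0.015, 0.020, -0.15),
             c(0, 0.045, 1.00),       # wide R
             c(0.095, 0.035, -0.50),
             c(0.32, 0.070, -0.40)),  # discordant (inverted) T
    F = list(c(-0.16, 0.025, 0.08),
             c(0, 0.028, 0.80),
             c(0.055, 0.020, -0.20),
             c(0.30, 0.060, 0.20)),
    Q = list(c(0, 0.060, 0.55),       # low, smeared complex
             c(0.18, 0.080, 0.22),
             c(0.38, 0.060, -0.10))
  )

  out <- lapply(names(shapes), function(cl) {
    w <- Reduce(`+`, lapply(shapes[[cl]], function(p) {
      gauss_bump(t, p[1], p[2], p[3])
    }))
    list(class_label = cl, waveform = w, r_offset = r_off)
  })
  names(out) <- names(shapes)
  out
}
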