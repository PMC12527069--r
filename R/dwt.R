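# Discrete wavelet transform (Mallat filter-bank algorithm) with symmetric
# signal extension, plus multi-level decomposition/reconstruction.
#
# Filter banks are stored at full double precision. With orthogonal
# wavelets the symmetric-extension analysis/synthesis pair below is an
# exact inverse (perfect reconstruction), which the denoiser relies on.

.WAVELETS <- list(
  sym5 = list(
    dec_lo = c(0.027333068345077982, 0.029519490925774643,
               -0.039134249302383094, 0.1993975339773936,
               0.7234076904024206, 0.6339789634582119,
               0.01660210576452232, -0.17532808990845047,
               -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855,
               0.17532808990845047, 0.01660210576452232,
               -0.6339789634582119, 0.7234076904024206,
               -0.1993975339773936, -0.039134249302383094,
               -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855,
               -0.17532808990845047, 0.01660210576452232,
               0.6339789634582119, 0.7234076904024206,
               0.1993975339773936, -0.039134249302383094,
               0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643,
               -0.039134249302383094, -0.1993975339773936,
               0.7234076904024206, -0.6339789634582119,
               0.01660210576452232, 0.17532808990845047,
               -0.021101834024758855, -0.019538882735286728)),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852,
               0.030841381835560764, -0.18703481171909309,
               -0.027983769416859854, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157,
               -0.6308807679298589, -0.027983769416859854,
               0.18703481171909309, 0.030841381835560764,
               -0.0328830116668852, -0.010597401785069032),
    rec_lo = c(0.2303778133088965, 0.7148465705529157,
               0.6308807679298589, -0.027983769416859854,
               -0.18703481171909309, 0.030841381835560764,
               0.0328830116668852, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.0328830116668852,
               0.030841381835560764, 0.18703481171909309,
               -0.027983769416859854, -0.6308807679298589,
               0.7148465705529157, -0.2303778133088965)),
  haar = list(
    dec_lo = c(0.7071067811865476, 0.7071067811865476),
    dec_hi = c(-0.7071067811865476, 0.7071067811865476),
    rec_lo = c(0.7071067811865476, 0.7071067811865476),
    rec_hi = c(0.7071067811865476, -0.7071067811865476))
)

#' Filter bank of a supported mother wavelet
#' @param wavelet_name One of "sym5", "db4", "haar".
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` filter vectors.
#' @export
wavelet_filters <- function(wavelet_name) {
  fb <- .WAVELETS[[wavelet_name]]
  if (is.null(fb))
    abort_config(paste0("unknown wavelet: ", wavelet_name,
                        " (supported: ",
                        paste(names(.WAVELETS), collapse = ", "), ")"))
  fb
}

# full (polynomial) convolution; direct form keeps it exact for the short
# filters used here
conv_full <- function(a, b) {
  la <- length(a)
  out <- numeric(la + length(b) - 1L)
  for (j in seq_along(b)) {
    rng <- j:(j + la - 1L)
    out[rng] <- out[rng] + a * b[j]
  }
  out
}

# symmetric (half-point) extension by m samples on each side
sym_extend <- function(x, m) {
  n <- length(x)
  left <- x[pmin(m:1, n)]
  right <- x[pmax(n - (1:m) + 1L, 1L)]
  c(left, x, right)
}

#' Single-level DWT (symmetric extension)
#'
#' @param x Numeric signal of length >= 2.
#' @param wavelet_name Mother wavelet name.
#' @return List with approximation `cA` and detail `cD`, each of length
#'   `floor((n + F - 1) / 2)` for filter length `F`.
#' @export
dwt_step <- function(x, wavelet_name = "sym5") {
  fb <- wavelet_filters(wavelet_name)
  fl <- length(fb$dec_lo)
  n <- length(x)
  if (n < 2) abort_validation("signal too short for a DWT step")
  ext <- sym_extend(x, fl - 1L)
  out_len <- (n + fl - 1L) %/% 2L
  lo <- conv_full(ext, fb$dec_lo)
  hi <- conv_full(ext, fb$dec_hi)
  # valid part of the convolution, downsampled at odd offsets
  valid <- fl:(length(ext))
  idx <- valid[seq(2, by = 2, length.out = out_len)]
  list(cA = lo[idx], cD = hi[idx])
}

#' Single-level inverse DWT (symmetric extension)
#'
#' @param cA,cD Approximation and detail coefficients of equal length.
#' @param wavelet_name Mother wavelet name.
#' @param out_len Target signal length; defaults to `2 * length(cA) - F + 2`.
#' @return Reconstructed numeric signal.
#' @export
idwt_step <- function(cA, cD, wavelet_name = "sym5", out_len = NULL) {
  fb <- wavelet_filters(wavelet_name)
  fl <- length(fb$rec_lo)
  if (length(cA) != length(cD))
    abort_validation("cA and cD must have equal length")
  L <- length(cA)
  up_a <- numeric(2L * L); up_a[seq(1, 2 * L, by = 2)] <- cA
  up_d <- numeric(2L * L); up_d[seq(1, 2 * L, by = 2)] <- cD
  y <- conv_full(up_a, fb$rec_lo) + conv_full(up_d, fb$rec_hi)
  full_len <- 2L * L - fl + 2L
  if (is.null(out_len)) out_len <- full_len
  if (out_len > full_len)
    abort_validation("out_len exceeds the reconstructable length")
  y[(fl - 2L) + seq_len(out_len)]
}

#' Multi-level wavelet decomposition
#'
#' @param x Numeric signal.
#' @param levels Number of decomposition levels (>= 1).
#' @param wavelet_name Mother wavelet name (default "sym5").
#' @return Object of class `wavedec`: list with `cA` (coarsest
#'   approximation), `details` (list of detail vectors, element 1 =
#'   coarsest, last element = finest), `lengths` (input length per level,
#'   used for exact reconstruction) and `wavelet_name`.
#' @export
wavedec <- function(x, levels = 3L, wavelet_name = "sym5") {
  if (!is_count(levels)) abort_validation("levels must be a count >= 1")
  if (length(x) < 2^levels)
    abort_validation("signal shorter than 2^levels samples")
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (lev in seq_len(levels)) {
    lens[lev] <- length(cur)
    st <- dwt_step(cur, wavelet_name)
    details[[levels - lev + 1L]] <- st$cD
    cur <- st$cA
  }
  structure(list(cA = cur, details = details, lengths = rev(lens),
                 wavelet_name = wavelet_name),
            class = "wavedec")
}

#' Reconstruct a signal from a multi-level decomposition
#' @param wd A [wavedec()] object (coefficients may have been modified).
#' @return Numeric signal at the original length.
#' @export
waverec <- function(wd) {
  stopifnot(inherits(wd, "wavedec"))
  cur <- wd$cA
  levels <- length(wd$details)
  for (lev in seq_len(levels)) {
    target <- wd$lengths[lev]
    cur <- idwt_step(cur, wd$details[[lev]], wd$wavelet_name,
                     out_len = target)
  }
  cur
}
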