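# Minimal WFDB-compatible record I/O.
#
# Supports the pieces needed for annotated ambulatory ECG: text .hea
# headers, signal files in format 16 (16-bit little-endian, written and
# read) and format 212 (packed 12-bit pairs, read), and MIT-format .atr
# beat annotations (including SKIP long intervals and AUX/NUM/SUBTYP/CHAN
# payload skipping on read).

# WFDB annotation type codes <-> symbols (beat + common non-beat codes).
.WFDB_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "~" = 14L, "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L,
  "\"" = 22L, "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L,
  "+" = 28L, "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L, "]" = 33L,
  "e" = 34L, "n" = 35L, "f" = 38L, "(" = 39L, ")" = 40L, "r" = 41L
)
.WFDB_SYMBOLS <- stats::setNames(names(.WFDB_CODES), .WFDB_CODES)

#' Write an ECG record in WFDB-compatible files
#'
#' Writes `<record>.hea` (text header), `<record>.dat` (format 16, 16-bit
#' little-endian samples with gain 1000 ADC units/mV) and, if the record
#' carries annotations, `<record>.atr` in the MIT annotation format.
#'
#' @param rec An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param record_name Base name of the record files.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(rec, dir, record_name = "rec") {
  stopifnot(inherits(rec, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gain <- 1000
  adc <- as.integer(round(clip(rec$signal * gain, -32768, 32767)))
  dat <- file.path(dir, paste0(record_name, ".dat"))
  con <- file(dat, "wb")
  writeBin(adc, con, size = 2, endian = "little")
  close(con)
  hea <- file.path(dir, paste0(record_name, ".hea"))
  writeLines(c(
    sprintf("%s 1 %g %d", record_name, rec$fs, length(rec$signal)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", record_name, gain,
            adc[1])
  ), hea)
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0)
    write_wfdb_annotations(rec$annotations,
                           file.path(dir, paste0(record_name, ".atr")))
  invisible(hea)
}

# write one unsigned 16-bit little-endian word as raw bytes
w16 <- function(con, val) {
  val <- as.integer(val)
  writeBin(as.raw(c(val %% 256L, (val %/% 256L) %% 256L)), con)
}

write_wfdb_annotations <- function(annotations, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  for (i in seq_len(nrow(annotations))) {
    # annotation times are stored as 0-based sample numbers
    delta <- (annotations$sample[i] - 1L) - prev
    prev <- annotations$sample[i] - 1L
    code <- .WFDB_CODES[annotations$symbol[i]]
    if (is.na(code)) code <- .WFDB_CODES["Q"]
    if (delta > 1023L) {
      # SKIP: type 59, zero increment, followed by a 32-bit interval
      # stored high 16 bits first
      w16(con, bitwShiftL(59L, 10L))
      w16(con, bitwAnd(bitwShiftR(delta, 16L), 0xFFFFL))
      w16(con, bitwAnd(delta, 0xFFFFL))
      delta <- 0L
    }
    w16(con, bitwShiftL(code, 10L) + delta)
  }
  w16(con, 0L)  # terminator
  invisible(path)
}

read_wfdb_annotations <- function(path, n_samples = Inf) {
  raw <- readBin(path, "integer", n = file.size(path) / 2, size = 2,
                 signed = FALSE, endian = "little")
  samples <- integer(0)
  symbols <- character(0)
  time <- 0L
  i <- 1L
  while (i <= length(raw)) {
    word <- raw[i]
    code <- bitwShiftR(word, 10L)
    incr <- bitwAnd(word, 1023L)
    if (word == 0L) break
    if (code == 59L) {            # SKIP: 4-byte interval, high word first
      time <- time + bitwShiftL(raw[i + 1L], 16L) + raw[i + 2L]
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }  # NUM/SUB/CHAN
    if (code == 63L) {            # AUX: incr = byte count, padded to even
      i <- i + 1L + ceiling(incr / 2)
      next
    }
    time <- time + incr
    sym <- .WFDB_SYMBOLS[as.character(code)]
    if (!is.na(sym)) {
      samples <- c(samples, time + 1L)  # back to 1-based
      symbols <- c(symbols, unname(sym))
    }
    i <- i + 1L
  }
  keep <- samples <= n_samples
  data.frame(sample = samples[keep], symbol = symbols[keep],
             stringsAsFactors = FALSE)
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3) as.numeric(head_f[3]) else 250
  n_samp <- if (length(head_f) >= 4) as.integer(head_f[4]) else NA_integer_
  sigs <- lapply(lines[1 + seq_len(n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[3]
    baseline <- 0
    gain <- suppressWarnings(as.numeric(sub("\\(.*", "", gain_spec)))
    if (grepl("\\(", gain_spec))
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) suppressWarnings(as.integer(f[5])) else 0L
    if (is.na(adc_zero)) adc_zero <- 0L
    list(file = f[1], format = as.integer(f[2]), gain = gain,
         baseline = baseline, adc_zero = adc_zero)
  })
  list(record = head_f[1], n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = sigs)
}

read_dat_16 <- function(path, n_sig, n_samp) {
  expected <- 2 * n_sig * n_samp
  if (!is.na(expected) && file.size(path) < expected)
    abort_io(sprintf(
      "signal file %s holds %d bytes but the header declares %d",
      path, file.size(path), expected))
  v <- readBin(path, "integer", n = file.size(path) / 2, size = 2,
               signed = TRUE, endian = "little")
  matrix(v, ncol = n_sig, byrow = TRUE)
}

read_dat_212 <- function(path, n_sig, n_samp) {
  bytes <- readBin(path, "integer", n = file.size(path), size = 1,
                   signed = FALSE)
  n_pairs <- length(bytes) %/% 3
  b1 <- bytes[seq(1, by = 3, length.out = n_pairs)]
  b2 <- bytes[seq(2, by = 3, length.out = n_pairs)]
  b3 <- bytes[seq(3, by = 3, length.out = n_pairs)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  total <- n_sig * n_samp
  if (!is.na(total)) {
    if (length(v) < total)
      abort_io(sprintf(
        "signal file %s holds %d samples but the header declares %d",
        path, length(v), total))
    v <- v[seq_len(total)]
  }
  matrix(v, ncol = n_sig, byrow = TRUE)
}

#' Read a WFDB record
#'
#' Reads `<record>.hea` plus the signal file it names (formats 16 and 212)
#' and, when present, `<record>.atr` beat annotations. Physical units are
#' restored as `(adc - baseline) / gain`. The first lead is returned unless
#' `lead` says otherwise.
#'
#' @param record_path Path to the record without extension (or to the
#'   `.hea` file).
#' @param lead 1-based channel to extract (default 1).
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(record_path, lead = 1L) {
  base <- sub("\\.hea$", "", record_path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) abort_io(paste0("missing header file: ", hea))
  hdr <- parse_hea(hea)
  if (lead < 1 || lead > hdr$n_sig)
    abort_validation(sprintf("lead %d not in 1..%d", lead, hdr$n_sig))
  dat <- file.path(dirname(base), hdr$signals[[lead]]$file)
  if (!file.exists(dat)) abort_io(paste0("missing signal file: ", dat))
  fmt <- hdr$signals[[lead]]$format
  m <- switch(as.character(fmt),
              "16" = read_dat_16(dat, hdr$n_sig, hdr$n_samp),
              "212" = read_dat_212(dat, hdr$n_sig, hdr$n_samp),
              abort_io(paste0("unsupported WFDB signal format: ", fmt)))
  if (!is.na(hdr$n_samp) && nrow(m) != hdr$n_samp)
    abort_io(sprintf(
      "signal file %s holds %d frames but the header declares %d",
      dat, nrow(m), hdr$n_samp))
  sg <- hdr$signals[[lead]]
  phys <- (m[, lead] - sg$baseline) / sg$gain
  atr <- paste0(base, ".atr")
  ann <- if (file.exists(atr)) read_wfdb_annotations(atr, nrow(m)) else NULL
  ecg_record(phys, fs = hdr$fs, annotations = ann)
}

#' Read an annotated ECG record from disk
#'
#' Thin wrapper over [read_wfdb()] kept as the ingest entry point; `path`
#' is the WFDB record path without extension.
#'
#' @inheritParams read_wfdb
#' @param path Record path without extension.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, lead = 1L) read_wfdb(path, lead = lead)
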