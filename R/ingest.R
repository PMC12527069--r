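# Record/dataset containers, AAMI symbol consolidation, stratified split.

#' Annotated single-lead ECG record
#'
#' @param signal Numeric vector of amplitudes (mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param annotations Data frame with columns `sample` (1-based, strictly
#'   increasing, within the signal) and `symbol` (annotation characters),
#'   or NULL.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs = 360, annotations = NULL) {
  if (!is.numeric(signal) || length(signal) == 0)
    abort_validation("signal must be a nonempty numeric vector")
  if (!is.numeric(fs) || fs <= 0) abort_validation("fs must be > 0")
  if (!is.null(annotations)) {
    stopifnot(all(c("sample", "symbol") %in% names(annotations)))
    s <- annotations$sample
    if (any(s < 1 | s > length(signal)))
      abort_validation("annotation indices must lie within the signal")
    if (is.unsorted(s, strictly = TRUE))
      abort_validation("annotation indices must be strictly increasing")
  }
  structure(list(signal = as.numeric(signal), fs = fs,
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), %d annotations\n",
              length(x$signal), x$fs, length(x$signal) / x$fs,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' Labeled fixed-length heartbeat dataset
#'
#' @param segments Numeric matrix, one row per beat.
#' @param labels Integer class labels in 0:4 (0=N, 1=S, 2=V, 3=F, 4=Q).
#' @return Object of class `beat_dataset` with fields `segments`, `labels`
#'   and `class_counts` (named counts over the five classes).
#' @export
beat_dataset <- function(segments, labels) {
  segments <- as.matrix(segments)
  labels <- as.integer(labels)
  if (nrow(segments) != length(labels))
    abort_validation("row count of segments must equal label count")
  if (length(labels) && (min(labels) < 0 || max(labels) > 4))
    abort_validation("labels must lie in 0:4")
  counts <- as.integer(table(factor(labels, levels = 0:4)))
  names(counts) <- AAMI_CLASSES
  structure(list(segments = unname(segments), labels = labels,
                 class_counts = counts),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples\n",
              nrow(x$segments), ncol(x$segments)))
  print(x$class_counts)
  invisible(x)
}

# Native beat annotation symbol -> AAMI class, the standard consolidation:
# N <- {N,L,R,e,j}; S <- {A,a,J,S}; V <- {V,E}; F <- {F}; Q <- {/,f,Q}.
.AAMI_MAP <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' Consolidate native annotation symbols into the five AAMI classes
#'
#' Beat symbols are mapped by the standard consolidation
#' (N: N,L,R,e,j; S: A,a,J,S; V: V,E; F: F; Q: /,f,Q). Every other symbol
#' (rhythm markers, noise, non-beat annotations, unknowns) maps to the
#' sentinel `"excluded"`.
#'
#' @param symbol Character vector of annotation symbols.
#' @return Character vector over {"N","S","V","F","Q","excluded"}.
#' @examples
#' map_to_aami(c("V", "F", "+", "L"))
#' @export
map_to_aami <- function(symbol) {
  out <- unname(.AAMI_MAP[symbol])
  if (anyNA(out)) {
    unk <- unique(symbol[is.na(out)])
    log_msg("excluding non-beat annotation symbol(s): ",
            paste(unk, collapse = " "))
    out[is.na(out)] <- "excluded"
  }
  out
}

#' Integer label codes for AAMI class symbols
#' @param class_label Character vector over {"N","S","V","F","Q"}.
#' @return Integer codes 0:4 (NA for "excluded").
#' @export
aami_code <- function(class_label) {
  match(class_label, AAMI_CLASSES) - 1L
}

#' Stratified train/test split
#'
#' Splits a beat dataset class by class. Each class with `n_c` members
#' contributes `floor(n_c * train_fraction)` beats to training; the
#' remaining training slots (to reach `round(N * train_fraction)` in total)
#' are assigned by largest fractional remainder (ties broken by class
#' order). Membership within each class is a seeded uniform draw, so the
#' same seed reproduces the same split while different seeds give the same
#' per-class counts with different membership.
#'
#' @param ds A [beat_dataset()].
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both beat datasets that
#'   partition `ds`.
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "beat_dataset"))
  n <- nrow(ds$segments)
  if (n == 0) abort_validation("cannot split an empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort_validation("train_fraction must lie strictly between 0 and 1")
  alloc <- split_allocation(ds$class_counts, train_fraction)
  with_seed(seed, {
    train_idx <- integer(0)
    for (k in seq_along(AAMI_CLASSES)) {
      idx_k <- which(ds$labels == k - 1L)
      if (length(idx_k) == 0) next
      take <- alloc[k]
      chosen <- if (take > 0) sort(sample(idx_k, take)) else integer(0)
      train_idx <- c(train_idx, chosen)
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    list(train = beat_dataset(ds$segments[train_idx, , drop = FALSE],
                              ds$labels[train_idx]),
         test = beat_dataset(ds$segments[test_idx, , drop = FALSE],
                             ds$labels[test_idx]))
  })
}

# Floor + largest-remainder allocation of per-class training counts.
split_allocation <- function(class_counts, train_fraction) {
  counts <- as.numeric(class_counts)
  exact <- counts * train_fraction
  base <- floor(exact)
  target <- round(sum(counts) * train_fraction)
  short <- target - sum(base)
  alloc <- base
  if (short > 0) {
    rem <- exact - base
    ord <- order(-rem, seq_along(rem))
    # never allocate more than the class holds
    for (k in ord) {
      if (short == 0) break
      if (alloc[k] < counts[k]) { alloc[k] <- alloc[k] + 1; short <- short - 1 }
    }
  }
  as.integer(alloc)
}

#' Write a beat dataset as a delimited-text container
#'
#' One row per beat, sample columns first, final column `label` holding the
#' integer class code. A JSON sidecar manifest (`<path>.manifest.json`)
#' records per-class counts and any metadata supplied.
#'
#' @param ds A [beat_dataset()].
#' @param path Output CSV path.
#' @param meta Optional named list stored in the manifest.
#' @return `path`, invisibly.
#' @export
write_beat_dataset <- function(ds, path, meta = list()) {
  stopifnot(inherits(ds, "beat_dataset"))
  df <- data.table::as.data.table(ds$segments)
  data.table::setnames(df, paste0("x", seq_len(ncol(ds$segments))))
  df[["label"]] <- ds$labels
  data.table::fwrite(df, path)
  manifest <- c(list(n_beats = nrow(ds$segments),
                     segment_len = ncol(ds$segments),
                     class_counts = as.list(ds$class_counts)), meta)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a beat dataset written by [write_beat_dataset()]
#' @param path CSV path (last column = integer label).
#' @return A [beat_dataset()].
#' @export
read_beat_dataset <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such dataset file: ", path))
  df <- data.table::fread(path)
  if (!"label" %in% names(df))
    abort_io(paste0("dataset file lacks a 'label' column: ", path))
  labels <- df[["label"]]
  df[["label"]] <- NULL
  beat_dataset(as.matrix(df), labels)
}
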