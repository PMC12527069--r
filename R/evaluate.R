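# Confusion matrix construction, per-class metrics, report rendering.

#' Confusion matrix (rows = true class, columns = predicted)
#'
#' @param true_labels,predicted_labels Integer labels 0-4 (or class
#'   symbols, which are converted).
#' @return 5 x 5 integer matrix of class `confusion_matrix` with AAMI
#'   dimnames.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (is.character(true_labels)) true_labels <- aami_code(true_labels)
  if (is.character(predicted_labels))
    predicted_labels <- aami_code(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    abort_validation("label vectors must have equal length")
  cm <- table(factor(true_labels, levels = 0:4),
              factor(predicted_labels, levels = 0:4))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(true = AAMI_CLASSES,
                               predicted = AAMI_CLASSES))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class and averaged classification metrics
#'
#' One-vs-rest precision, recall and F1 per class, plus unweighted macro
#' averages, support-weighted averages and overall accuracy
#' (`trace / total`, which coincides with the binary
#' `(TP + TN) / (TP + TN + FP + FN)` formula applied per class). A class
#' with no predicted (or no true) members gets precision (or recall) 0
#' with a warning; F1 is 0 whenever precision + recall is 0.
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `eval_report`: list with `per_class` (data
#'   frame class/precision/recall/f1/support), `macro`, `weighted` (lists
#'   with precision/recall/f1) and `accuracy` (fraction in [0, 1]).
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) abort_validation("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  if (any(predicted == 0))
    warning("class(es) never predicted; precision reported as 0: ",
            paste(AAMI_CLASSES[predicted == 0], collapse = " "))
  if (any(support == 0))
    warning("class(es) absent from the truth; recall reported as 0: ",
            paste(AAMI_CLASSES[support == 0], collapse = " "))
  pr <- precision + recall
  f1 <- ifelse(pr > 0, 2 * precision * recall / pr, 0)
  wts <- support / total
  structure(list(
    per_class = data.frame(class = AAMI_CLASSES, precision = precision,
                           recall = recall, f1 = f1,
                           support = as.integer(support),
                           row.names = NULL),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = sum(wts * precision),
                    recall = sum(wts * recall), f1 = sum(wts * f1)),
    accuracy = sum(tp) / total,
    confusion = cm
  ), class = "eval_report")
}

# round half up to integer percent, as conventional in reported tables
percent_round <- function(x) floor(x * 100 + 0.5)

#' Render an evaluation report
#'
#' Produces a human-readable table (per-class rows N, S, V, F, Q, an
#' unweighted average row, and overall accuracy; percentages rounded half
#' up to integers) and a machine-readable list mirroring the report.
#'
#' @param r An [eval_metrics()] report.
#' @return List with `text` (character vector of table lines) and
#'   `record` (nested list suitable for JSON serialization).
#' @export
render_report <- function(r) {
  stopifnot(inherits(r, "eval_report"))
  pc <- r$per_class
  header <- sprintf("%-12s %5s %5s %5s %5s %5s %8s", "Metric",
                    "N", "S", "V", "F", "Q", "Average")
  row_line <- function(label, vals, avg) {
    sprintf("%-12s %5d %5d %5d %5d %5d %8d", label,
            vals[1], vals[2], vals[3], vals[4], vals[5], avg)
  }
  text <- c(header,
            row_line("Precision(%)", percent_round(pc$precision),
                     percent_round(r$macro$precision)),
            row_line("Recall(%)", percent_round(pc$recall),
                     percent_round(r$macro$recall)),
            row_line("F1(%)", percent_round(pc$f1),
                     percent_round(r$macro$f1)),
            sprintf("Overall accuracy: %d%%", percent_round(r$accuracy)))
  record <- list(
    per_class = lapply(seq_len(nrow(pc)), function(i) list(
      class = pc$class[i], precision = pc$precision[i],
      recall = pc$recall[i], f1 = pc$f1[i], support = pc$support[i])),
    macro = r$macro, weighted = r$weighted, accuracy = r$accuracy,
    confusion = apply(r$confusion, 1, as.integer, simplify = FALSE))
  list(text = text, record = record)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(render_report(x)$text, sep = "\n")
  invisible(x)
}

#' Evaluate a trained model on a test dataset
#'
#' @param model A trained `ecg_model`.
#' @param test A [beat_dataset()].
#' @return An [eval_metrics()] report.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict_classes(model, test$segments)
  eval_metrics(confusion(test$labels, pred))
}
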