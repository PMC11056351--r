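## One-vs-rest classification metrics and the per-class + macro report
## layout: rows are true classes, columns predicted classes; per-class
## accuracy/precision/recall/F1 are percentages computed from the class's
## TP/FP/FN/TN; the macro row is the unweighted mean over classes, taken on
## unrounded values and rounded (half-up, 2 decimals) only for display.

## round half-up to 2 decimals (reports print percentages like 95.66)
round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Confusion matrix of true vs. predicted labels
#'
#' @param true_labels,predicted_labels integer codes in `1:c` (or factors /
#'   character vectors sharing the same levels).
#' @param class_names optional ordered class labels; inferred from factors
#'   when absent.
#' @return a `c x c` integer matrix, rows = true class, columns = predicted
#'   class, with `dimnames` set to the class names.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_names = NULL) {
  if (is.factor(true_labels) && is.null(class_names))
    class_names <- levels(true_labels)
  if (is.character(true_labels)) {
    class_names <- class_names %||% sort(unique(c(true_labels, predicted_labels)))
    true_labels <- match(true_labels, class_names)
    predicted_labels <- match(predicted_labels, class_names)
  }
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length", call. = FALSE)
  c_n <- length(class_names %||% seq_len(max(true_labels, predicted_labels)))
  bad <- c(true_labels, predicted_labels)
  bad <- bad[is.na(bad) | bad < 1 | bad > c_n]
  if (length(bad))
    stop(sprintf("label out of range [1, %d]: %s", c_n, bad[1]), call. = FALSE)
  cm <- matrix(0L, c_n, c_n)
  for (i in seq_along(true_labels))
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  nms <- class_names %||% as.character(seq_len(c_n))
  dimnames(cm) <- list(true = nms, predicted = nms)
  class(cm) <- c("scmix_confusion", class(cm))
  cm
}

#' @export
print.scmix_confusion <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' One-vs-rest counts for a single class
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param class_index class position in `1:c`.
#' @return a one-row tibble with columns `TP`, `FP`, `FN`, `TN`.
#' @export
one_vs_rest_counts <- function(cm, class_index) {
  cm <- unclass(cm)
  i <- as.integer(class_index)
  if (i < 1 || i > nrow(cm)) stop("class_index out of range", call. = FALSE)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  tibble::tibble(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Per-class metrics from one-vs-rest counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 (harmonic mean of precision and recall), all as percentages in
#' `[0, 100]`. A zero denominator yields 0 with a warning.
#'
#' @param counts a row with `TP`, `FP`, `FN`, `TN` (see
#'   [one_vs_rest_counts()]).
#' @return a one-row tibble with columns `acc`, `pr`, `re`, `f1` (unrounded).
#' @export
class_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; reporting 0", what), call. = FALSE)
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / total * 100
  pr <- safe_div(tp, tp + fp, "precision") * 100
  re <- safe_div(tp, tp + fn, "recall") * 100
  f1 <- if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
  tibble::tibble(acc = acc, pr = pr, re = re, f1 = f1)
}

#' Macro (unweighted) average of per-class metric rows
#'
#' Computed on unrounded per-class values; rounding is applied only when the
#' report is printed or written.
#'
#' @param rows tibble of per-class rows with columns `acc`, `pr`, `re`, `f1`.
#' @return a one-row tibble of the column means.
#' @export
macro_summary <- function(rows) {
  if (is.null(nrow(rows)) || nrow(rows) == 0)
    stop("macro_summary needs at least one class row", call. = FALSE)
  tibble::tibble(acc = mean(rows$acc), pr = mean(rows$pr),
                 re = mean(rows$re), f1 = mean(rows$f1))
}

#' Per-class + macro metrics report from a confusion matrix
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @param class_names optional class labels (default: `rownames(cm)`).
#' @return a tibble with columns `class`, `acc`, `pr`, `re`, `f1`; one row per
#'   class plus a final `MACRO` row. Values are unrounded percentages; use
#'   [write_report()] for the rounded on-disk form.
#' @export
metrics_report <- function(cm, class_names = NULL) {
  cmu <- unclass(cm)
  class_names <- class_names %||% rownames(cmu) %||% as.character(seq_len(nrow(cmu)))
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(cmu)), function(i)
    class_metrics(one_vs_rest_counts(cmu, i))))
  macro <- macro_summary(rows)
  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(class = class_names), rows),
    dplyr::bind_cols(tibble::tibble(class = "MACRO"), macro))
  class(out) <- c("scmix_report", class(out))
  out
}

#' Write a metrics report and its confusion matrix to disk
#'
#' Emits `metrics.csv` (columns class, acc, pr, re, f1, rounded half-up to 2
#' decimals, final MACRO row), `metrics.json` (same fields), and
#' `confusion.csv` (class names as header row and column).
#'
#' @param report tibble from [metrics_report()].
#' @param cm the confusion matrix the report was computed from.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_report <- function(report, cm, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  rounded <- dplyr::mutate(report, dplyr::across(c("acc", "pr", "re", "f1"), round2))
  paths <- c(metrics_csv = file.path(dir, "metrics.csv"),
             metrics_json = file.path(dir, "metrics.json"),
             confusion_csv = file.path(dir, "confusion.csv"))
  tryCatch({
    utils::write.csv(rounded, paths["metrics_csv"], row.names = FALSE)
    jsonlite::write_json(rounded, paths["metrics_json"], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(unclass(cm)), paths["confusion_csv"],
                     row.names = TRUE)
  }, error = function(e) {
    stop(sprintf("failed writing report under '%s': %s", dir, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(paths)
}

#' Pooled (micro) multi-class accuracy of a confusion matrix
#'
#' `sum(diag(cm)) / sum(cm)` as a percentage; the quantity usually quoted as
#' plain "accuracy", distinct from the per-class one-vs-rest accuracy.
#'
#' @param cm confusion matrix.
#' @return scalar percentage.
#' @export
pooled_accuracy <- function(cm) {
  cmu <- unclass(cm)
  sum(diag(cmu)) / sum(cmu) * 100
}
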