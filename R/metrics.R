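# Performance metrics: class-balanced accuracy (macro-averaged per-class
# recall), Cohen's kappa, confusion matrices and per-subject summaries.

#' Confusion matrix from true and predicted labels
#'
#' @param true,pred Integer label vectors (0-based, same length).
#' @param n_classes Number of classes; inferred when `NULL`.
#' @return n x n count matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, n_classes = NULL) {
  if (length(true) != length(pred)) stop("length mismatch")
  if (is.null(n_classes)) n_classes <- max(true, pred) + 1L
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true)) {
    cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

#' Class-balanced accuracy
#'
#' The mean over classes of per-class recall, `(1/n) sum_i TP_i / H_i`
#' where `H_i` is the number of trials whose true class is `i`. Equals
#' plain (micro) accuracy whenever all classes have the same size.
#'
#' @param confusion Square count matrix (rows = true class).
#' @return Accuracy in `[0, 1]`.
#' @export
macro_accuracy <- function(confusion) {
  check_confusion(confusion)
  H <- rowSums(confusion)
  if (any(H == 0)) stop("undefined metric: some class has no trials")
  mean(diag(confusion) / H)
}

#' Micro (overall) accuracy
#'
#' @param confusion Square count matrix.
#' @return Fraction of correctly classified trials.
#' @export
micro_accuracy <- function(confusion) {
  check_confusion(confusion)
  sum(diag(confusion)) / sum(confusion)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(P_a - P_e) / (1 - P_e)` with observed
#' agreement `P_a = sum(diag) / N` and expected agreement
#' `P_e = sum_i row_i * col_i / N^2` from the marginals.
#'
#' @param confusion Square count matrix (rows = true class).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  check_confusion(confusion)
  n <- sum(confusion)
  if (n == 0) stop("undefined metric: empty confusion matrix")
  pa <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) stop("undefined metric: degenerate single-class data")
  (pa - pe) / (1 - pe)
}

check_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("confusion must be a square matrix")
  }
  if (any(cm < 0)) stop("confusion entries must be nonnegative counts")
  invisible(cm)
}

#' Full metrics report
#'
#' @param true,pred Integer label vectors (0-based).
#' @param n_classes Number of classes; inferred when `NULL`.
#' @return Object of class `mi_metrics`: confusion matrix, class-balanced
#'   accuracy, micro accuracy, Cohen's kappa, per-class recall and trial
#'   count.
#' @export
metrics_report <- function(true, pred, n_classes = NULL) {
  cm <- confusion_matrix(true, pred, n_classes)
  structure(list(confusion = cm,
                 acc = macro_accuracy(cm),
                 micro_acc = micro_accuracy(cm),
                 kappa = cohen_kappa(cm),
                 per_class_recall = diag(cm) / rowSums(cm),
                 n_trials = sum(cm)),
            class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  cat(sprintf("MI-EEG metrics over %d trials\n", x$n_trials))
  cat(sprintf("  accuracy (class-balanced): %.4f\n", x$acc))
  cat(sprintf("  accuracy (micro)         : %.4f\n", x$micro_acc))
  cat(sprintf("  Cohen's kappa            : %.4f\n", x$kappa))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a fitted classifier on labeled trials
#'
#' @param object A fitted `bfatcnet` object.
#' @param x An `epoched_eeg` dataset or array (trials, channels, time).
#' @param labels Integer labels (taken from `x` when it is a dataset).
#' @return An `mi_metrics` report.
#' @export
evaluate_model <- function(object, x, labels = NULL) {
  if (inherits(x, "epoched_eeg")) {
    labels <- x$labels
    x <- x$data
  }
  pred <- predict(object, x, type = "class")
  metrics_report(labels, pred, n_classes = object$config$n_classes)
}

#' Per-subject summary table
#'
#' One accuracy/kappa row per subject plus summary rows with the mean,
#' the population (divide-by-n) standard deviation of accuracy, and the
#' mean kappa.
#'
#' @param reports Named list of `mi_metrics`, one per subject.
#' @return A `data.frame` with columns `subject`, `acc` and `kappa`;
#'   summary rows are labeled `MEAN` and `STD`.
#' @export
subject_summary <- function(reports) {
  if (length(reports) == 0) stop("at least one subject is required")
  subj <- names(reports)
  if (is.null(subj)) subj <- paste0("S", seq_along(reports))
  acc <- vapply(reports, function(r) r$acc, numeric(1))
  kap <- vapply(reports, function(r) r$kappa, numeric(1))
  pop_sd <- sqrt(mean((acc - mean(acc))^2))
  data.frame(
    subject = c(subj, "MEAN", "STD"),
    acc = c(acc, mean(acc), pop_sd),
    kappa = c(kap, mean(kap), NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write / read a subject summary as CSV
#'
#' @param summary A data frame from [subject_summary()].
#' @param path CSV file path.
#' @export
write_subject_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_csv
#' @export
read_subject_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a metrics report as JSON
#'
#' @param report An `mi_metrics` object.
#' @param path JSON file path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(list(
    acc = report$acc, micro_acc = report$micro_acc, kappa = report$kappa,
    per_class_recall = report$per_class_recall,
    confusion = report$confusion, n_trials = report$n_trials
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
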