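#' Classification agreement metrics
#'
#' Overall accuracy (OA), average accuracy (AA) and the Kappa
#' coefficient, computed from an S x S confusion matrix with rows = true
#' class and columns = predicted class. Writing `n_i` for the diagonal
#' count of class i and `m_i` for its row total:
#'
#' * `OA  = sum(n_i) / sum(m_i)` — the trace over the total count.
#' * `AA  = mean(n_i / m_i)` — the mean per-class recall.
#' * `Kappa` comes in two modes. The `"printed"` mode evaluates the
#'   source formula literally, with expected agreement
#'   `P_e = sum(n_i * m_i) / S^2` over raw counts; note this quantity is
#'   not scale-invariant and can exceed 1 for large counts. The
#'   `"standard"` mode is Cohen's kappa with
#'   `P_e = sum(row_i * col_i) / N^2`.
#'
#' @name metrics
NULL

#' Build a confusion matrix from label vectors
#'
#' @param truth,pred integer class labels in `1..n_classes`.
#' @param n_classes number of classes S (default: max label seen).
#' @return S x S integer matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(c(truth, pred))) {
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  dimnames(cm) <- list(truth = seq_len(n_classes), pred = seq_len(n_classes))
  cm
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix has negative counts")
  if (sum(cm) <= 0) stop("confusion matrix is empty")
  cm
}

#' Overall accuracy
#' @param cm confusion matrix (rows = true, cols = predicted).
#' @return trace / total, in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Average accuracy (mean per-class recall)
#' @param cm confusion matrix.
#' @return mean of `n_i / m_i` over classes; errors if any class has no
#'   samples.
#' @export
average_accuracy <- function(cm) {
  check_cm(cm)
  m <- rowSums(cm)
  if (any(m == 0)) stop("undefined-class error: a class has zero samples")
  mean(diag(cm) / m)
}

#' Kappa coefficient
#'
#' @param cm confusion matrix.
#' @param mode `"printed"` (literal count-based expected agreement over
#'   `S^2`, the default) or `"standard"` (Cohen's kappa).
#' @return Kappa value; errors when the expected agreement equals 1.
#' @export
kappa_coefficient <- function(cm, mode = c("printed", "standard")) {
  mode <- match.arg(mode)
  check_cm(cm)
  oa <- overall_accuracy(cm)
  s <- nrow(cm)
  pe <- if (mode == "printed") {
    sum(diag(cm) * rowSums(cm)) / (s * s)
  } else {
    sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  }
  if (pe == 1) stop("degenerate error: expected agreement equals 1")
  (oa - pe) / (1 - pe)
}

#' Metrics report (OA, AA, both Kappa modes)
#'
#' A degenerate kappa (expected agreement exactly 1, e.g. an untrained
#' model predicting a single class everywhere) is reported as `NA`
#' rather than aborting a whole evaluation run.
#'
#' @param cm confusion matrix.
#' @return list with `OA`, `AA`, `kappa_printed`, `kappa_standard`.
#' @export
metrics_report <- function(cm) {
  safe_kappa <- function(mode) {
    tryCatch(kappa_coefficient(cm, mode),
             error = function(e) {
               if (grepl("degenerate", conditionMessage(e))) NA_real_ else stop(e)
             })
  }
  list(
    OA = overall_accuracy(cm),
    AA = average_accuracy(cm),
    kappa_printed = safe_kappa("printed"),
    kappa_standard = safe_kappa("standard")
  )
}
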