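#' Binary classification metrics for fit detection
#'
#' The positive class is `poor_fit`: a missed leak (false negative) is the
#' safety-critical error, so F1, the false-negative rate and the ROC curve
#' are all oriented around detecting poor fit. The confusion matrix is
#' fixed as rows = true `{poor_fit, fit}`, columns = predicted
#' `{poor_fit, fit}`.
#'
#' @param y_true,y_pred Character/factor vectors over `{fit, poor_fit}` of
#'   equal length.
#' @param scores Optional numeric scores, larger meaning more poor-fit-like;
#'   required for ROC-AUC.
#' @return List with `f1`, `roc_auc` (`NA` when undefined), `confusion`
#'   (2x2 integer matrix), `fn_rate` and `n`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) ||
      (!is.null(scores) && length(scores) != length(y_true)))
    bf_stop("y_true, y_pred and scores must have equal length",
            "bf_input_error")
  lv <- c("poor_fit", "fit")
  if (!all(c(y_true, y_pred) %in% lv))
    bf_stop("labels must be 'fit' or 'poor_fit'", "bf_vocab_error")
  cm <- table(factor(y_true, lv), factor(y_pred, lv))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(true = lv, predicted = lv))
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]
  # vacuous case (no true or predicted positives): no positive-class
  # errors were made, so F1 is reported as 1 rather than left undefined
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  fn_rate <- if (tp + fn == 0) NA_real_ else fn / (tp + fn)
  auc <- NA_real_
  if (!is.null(scores) && length(unique(y_true)) == 2L) {
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y_true, predictor = as.numeric(scores),
      levels = c("fit", "poor_fit"), direction = "<", quiet = TRUE)))
  }
  list(f1 = f1, roc_auc = auc, confusion = cm, fn_rate = fn_rate,
       n = length(y_true))
}
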