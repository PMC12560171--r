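#' Regression metrics
#'
#' Closed forms on residuals `e = y_true - y_pred`:
#' `mae = mean(|e|)`, `mse = mean(e^2)`,
#' `r2 = 1 - sum(e^2) / sum((y - mean(y))^2)` and explained variance
#' `ev = 1 - var(e) / var(y)`. EV ignores a constant residual bias, so
#' `r2 <= ev` always. A constant `y_true` makes r2/ev undefined (`NA`);
#' mae/mse are still reported.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return data.frame row with mae, mse, ev, r2.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  e <- y_true - y_pred
  mae <- mean(abs(e))
  mse <- mean(e^2)
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) {
    r2 <- NA_real_; ev <- NA_real_
  } else {
    r2 <- 1 - sum(e^2) / sst
    ev <- 1 - var(e) / var(y_true)
  }
  data.frame(mae = mae, mse = mse, ev = ev, r2 = r2)
}

#' Classification metrics at a score threshold
#'
#' Accuracy, sensitivity, specificity and F1 at `threshold` (a score at or
#' above the threshold predicts the positive class), plus a threshold-free
#' AUC computed as the rank (Mann-Whitney) statistic with ties counted 1/2 —
#' constant scores therefore give AUC 0.5.
#'
#' @param labels binary vector (0/1 or logical), 1 = positive class.
#' @param scores numeric scores, higher = more positive.
#' @param threshold decision threshold (default 0.5, suitable for posterior
#'   probabilities).
#' @return data.frame row with acc, sens, spec, auc, f1 (proportions).
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n_pos <- tp + fn; n_neg <- tn + fp
  acc <- (tp + tn) / length(labels)
  sens <- if (n_pos > 0) tp / n_pos else NA_real_
  spec <- if (n_neg > 0) tn / n_neg else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  auc <- if (n_pos > 0 && n_neg > 0) {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NA_real_
  data.frame(acc = acc, sens = sens, spec = spec, auc = auc, f1 = f1)
}
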