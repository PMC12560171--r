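# CSF-only baselines: constant-prediction regression baselines, fixed
# published cutoffs (abeta 977 pg/mL; ptau and tau derived from it by the
# ptau/abeta = 0.025 and tau/abeta = 0.27 ratios), and the deliberately
# overfit exhaustive threshold sweep.

#' Derive a marker cutoff from the abeta cutoff and a ratio
#'
#' `977 * 0.025 = 24.425` pg/mL (ptau), `977 * 0.27 = 263.79` pg/mL (tau).
#'
#' @param abeta_cutoff abeta cutoff in pg/mL.
#' @param ratio marker/abeta ratio.
#' @return cutoff in pg/mL.
#' @export
ratio_cutoff <- function(abeta_cutoff = 977, ratio) {
  stopifnot(abeta_cutoff >= 0, ratio >= 0)
  abeta_cutoff * ratio
}

#' Cutoff specification for a marker
#'
#' Orientation is fixed by the marker's pathology direction: low abeta is
#' abnormal (`below_positive`), high ptau/tau are abnormal (`above_positive`).
#'
#' @param marker "abeta", "ptau" or "tau".
#' @param value cutoff in pg/mL (> 0); defaults: abeta 977,
#'   ptau `977 * 0.025`, tau `977 * 0.27`.
#' @return list of class `cutoff_spec`.
#' @export
cutoff_spec <- function(marker = c("abeta", "ptau", "tau"), value = NULL) {
  marker <- match.arg(marker)
  if (is.null(value)) {
    value <- switch(marker, abeta = 977,
                    ptau = ratio_cutoff(977, 0.025),
                    tau = ratio_cutoff(977, 0.27))
  }
  stopifnot(value > 0)
  structure(list(marker = marker, value = value,
                 orientation = if (marker == "abeta") "below_positive"
                               else "above_positive"),
            class = "cutoff_spec")
}

predict_by_cutoff <- function(values, cutoff, orientation) {
  # ties at the cutoff count positive, matching the "<= cutoff abnormal"
  # convention of published abeta cutoffs
  if (orientation == "below_positive") as.integer(values <= cutoff)
  else as.integer(values >= cutoff)
}

#' Naive cutoff classifier on one CSF marker
#'
#' @param values marker concentrations (pg/mL).
#' @param labels binary labels (1 = disease-positive class).
#' @param spec a [cutoff_spec()].
#' @return [classification_metrics()] row (AUC oriented so that the
#'   pathology direction scores higher).
#' @export
cutoff_classifier <- function(values, labels, spec) {
  stopifnot(inherits(spec, "cutoff_spec"), length(values) == length(labels))
  # orient scores so the pathology direction is high; the >= threshold rule
  # then reproduces the ties-at-cutoff-positive convention for both markers
  flip <- spec$orientation == "below_positive"
  scores <- if (flip) -values else values
  classification_metrics(as.integer(labels), scores,
                         threshold = if (flip) -spec$value else spec$value)
}

#' Exhaustive accuracy sweep over decision thresholds
#'
#' Candidate thresholds are the midpoints of consecutive sorted distinct
#' values plus `-Inf`/`+Inf` sentinels — a superset of every possible
#' dichotomy, so the best accuracy is the true maximum over all thresholds.
#' Ties in accuracy resolve to the smallest threshold. This baseline is
#' evaluated on the same data it is optimized on and is intentionally
#' overfit ("best-case" baseline).
#'
#' @param values marker concentrations.
#' @param labels binary labels (1 = positive).
#' @param orientation `"above_positive"` or `"below_positive"`.
#' @return list with `curve` (data.frame threshold/accuracy), `best_threshold`,
#'   `best_accuracy`, and `overfit = TRUE` metadata.
#' @export
threshold_sweep <- function(values, labels, orientation = c("above_positive",
                                                            "below_positive")) {
  orientation <- match.arg(orientation)
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), all(labels %in% c(0L, 1L)))
  sv <- sort(unique(values))
  candidates <- c(-Inf, if (length(sv) > 1L) (sv[-1L] + sv[-length(sv)]) / 2, Inf)
  acc <- vapply(candidates, function(t) {
    mean(predict_by_cutoff(values, t, orientation) == labels)
  }, numeric(1L))
  best <- which(acc == max(acc))[1L]
  list(curve = data.frame(threshold = candidates, accuracy = acc),
       best_threshold = candidates[best], best_accuracy = acc[best],
       overfit = TRUE)
}

#' Naive regression baselines: mean prediction and cutoff prediction
#'
#' The mean model predicts `mean(y_train)` for every case; the cutoff model
#' predicts the constant cutoff. Both are scored with [regression_metrics()]
#' on `y_eval`. On its own fitting data the mean model has R2 and EV exactly
#' 0.
#'
#' @param y_train training targets defining the mean.
#' @param y_eval evaluation targets.
#' @param cutoff constant cutoff prediction (pg/mL).
#' @return data.frame with rows `mean_prediction` and `cutoff_prediction`.
#' @export
naive_regression_baselines <- function(y_train, y_eval = y_train, cutoff) {
  stopifnot(length(y_train) >= 1L, length(y_eval) >= 2L)
  mean_m <- regression_metrics(y_eval, rep(mean(y_train), length(y_eval)))
  cut_m <- regression_metrics(y_eval, rep(cutoff, length(y_eval)))
  out <- rbind(mean_m, cut_m)
  out$model <- c("mean_prediction", "cutoff_prediction")
  out[, c("model", "mae", "mse", "ev", "r2")]
}
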