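# Shared fixtures, built in code and memoised per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# Small cohort: 10 subjects/group, 10% corrupted volumes, 32^3 grid.
small_dataset <- function() {
  memo("small_dataset",
       generate_dataset(10, qc_fail_fraction = 0.1, seed = 401))
}

# Tiny network config that trains in seconds on a 16^3 grid.
tiny_config <- function(n_heads = 1L, markers = if (n_heads == 1L) "abeta" else c("abeta", "ptau", "tau")) {
  mrinet_config(conv_channels = c(4L, 8L), head_hidden = 64L,
                n_heads = n_heads, input_dims = c(16L, 16L, 16L),
                markers = markers)
}

random_volume <- function(dims = c(16L, 16L, 16L), seed = 1) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

# Independent brute-force metric oracles (pair counting for AUC, explicit
# confusion tallies, definition-level regression formulas).
oracle_regression <- function(y, p) {
  e <- y - p
  ybar <- sum(y) / length(y)
  n <- length(y)
  ebar <- sum(e) / n
  list(mae = sum(abs(e)) / n,
       mse = sum(e^2) / n,
       r2 = 1 - sum(e^2) / sum((y - ybar)^2),
       ev = 1 - (sum((e - ebar)^2) / (n - 1)) / (sum((y - ybar)^2) / (n - 1)))
}

oracle_classification <- function(labels, scores, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    pos <- scores[i] >= threshold
    if (labels[i] == 1 && pos) tp <- tp + 1
    if (labels[i] == 0 && pos) fp <- fp + 1
    if (labels[i] == 0 && !pos) tn <- tn + 1
    if (labels[i] == 1 && !pos) fn <- fn + 1
  }
  auc_num <- 0
  for (i in which(labels == 1)) {
    for (j in which(labels == 0)) {
      auc_num <- auc_num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  list(acc = (tp + tn) / length(labels),
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       f1 = 2 * tp / (2 * tp + fp + fn),
       auc = auc_num / (sum(labels == 1) * sum(labels == 0)))
}

# Exhaustive best accuracy over every dichotomy of the value axis.
oracle_best_accuracy <- function(values, labels, orientation) {
  cands <- c(-Inf, sort(unique(values)), Inf)
  best <- 0
  for (t in cands) {
    pred <- if (orientation == "above_positive") as.integer(values >= t)
            else as.integer(values <= t)
    best <- max(best, mean(pred == labels))
  }
  best
}
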