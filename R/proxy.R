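# Transfer of MRI-derived CSF proxy-markers (latent embeddings from trained
# regressors) to classification: AD-vs-CN diagnosis and sMCI-vs-pMCI
# progression prediction, plus an age-prediction context-specificity check.

#' Extract latent embeddings from a trained regressor
#'
#' One embedding per session: the hidden-layer activations of the regression
#' head (length `head_hidden`, 64 by default) for single-output models, and
#' the concatenation of the three head latents (length `3 * head_hidden`)
#' for multi-output models. Deterministic (evaluation mode).
#'
#' @param model a trained [mrinet()].
#' @param volumes list of [gm_volume()] (or arrays).
#' @return numeric matrix (n sessions x embedding length) with a `source`
#'   attribute (`"SO_<marker>"` or `"MO"`) and subject ids as rownames when
#'   available.
#' @export
extract_embeddings <- function(model, volumes) {
  stopifnot(inherits(model, "mrinet"))
  out <- mrinet_predict(model, volumes)
  emb <- do.call(cbind, out$latents)
  ids <- vapply(volumes_to_arrays(volumes), function(x) NA_character_, character(1L))
  if (all(vapply(volumes, inherits, logical(1L), "gm_volume"))) {
    ids <- vapply(volumes, function(v) v$subject_id, character(1L))
  }
  rownames(emb) <- ids
  attr(emb, "source") <- if (model$config$n_heads == 1L) {
    paste0("SO_", model$config$markers)
  } else "MO"
  emb
}

standardize_by_train <- function(x, train_idx) {
  mu <- colMeans(x[train_idx, , drop = FALSE])
  sdv <- apply(x[train_idx, , drop = FALSE], 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdv, "/"), mean = mu, sd = sdv)
}

#' Fit the logistic proxy classifier
#'
#' L2-regularized (ridge) logistic regression on embeddings standardized
#' per dimension with training-partition statistics only; no test-partition
#' information enters the fit. The default penalty corresponds to unit
#' inverse regularization strength at the training size.
#'
#' @param embeddings numeric matrix (sessions x dims).
#' @param labels binary vector (0/1 or logical), one per session.
#' @param train_idx,test_idx row indices of the training and held-out test
#'   partitions.
#' @param lambda ridge penalty; default `1 / length(train_idx)`.
#' @return list with `weights`, `intercept`, `scores` (posterior
#'   probabilities on the test partition), `test_idx`, and the scaler.
#' @export
fit_proxy_classifier <- function(embeddings, labels, train_idx, test_idx,
                                 lambda = NULL) {
  labels <- as.integer(labels)
  stopifnot(nrow(embeddings) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels[train_idx])) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- 1 / length(train_idx)
  sc <- standardize_by_train(embeddings, train_idx)
  fit <- glmnet::glmnet(sc$x[train_idx, , drop = FALSE], labels[train_idx],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  scores <- as.numeric(predict(fit, sc$x[test_idx, , drop = FALSE],
                               type = "response"))
  list(weights = as.numeric(coef(fit))[-1L],
       intercept = as.numeric(coef(fit))[1L],
       scores = scores, test_idx = test_idx,
       scaler = sc[c("mean", "sd")], lambda = lambda)
}

#' Age-prediction context-specificity check
#'
#' Regresses subject age on the CSF-optimized latent embeddings (ridge linear
#' model, train-partition standardization) and reports test-partition
#' regression metrics. Embeddings optimized for CSF pathology should predict
#' age markedly worse than they predict the CSF markers themselves.
#'
#' @param embeddings numeric matrix (sessions x dims).
#' @param ages numeric vector of ages.
#' @param train_idx,test_idx partition row indices.
#' @param lambda ridge penalty; default `1 / length(train_idx)`.
#' @return data.frame of [regression_metrics()] on the test partition.
#' @export
context_specificity_check <- function(embeddings, ages, train_idx, test_idx,
                                      lambda = NULL) {
  stopifnot(nrow(embeddings) == length(ages))
  if (is.null(lambda)) lambda <- 1 / length(train_idx)
  sc <- standardize_by_train(embeddings, train_idx)
  fit <- glmnet::glmnet(sc$x[train_idx, , drop = FALSE], ages[train_idx],
                        family = "gaussian", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  pred <- as.numeric(predict(fit, sc$x[test_idx, , drop = FALSE]))
  regression_metrics(ages[test_idx], pred)
}
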