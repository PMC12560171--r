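# Stratified Monte-Carlo cross-validation, the training loop (Adam, MSE /
# AL / WNL losses, reduce-on-plateau scheduling and early stopping on the
# validation R2), and best-epoch checkpointing.

#' Stratified Monte-Carlo splits at the subject level
#'
#' Repeated random subsampling into train/validation/test partitions,
#' stratified by diagnostic group and split by subject: every session of a
#' subject lands in the same partition, and each group's proportion in every
#' partition matches the cohort proportion within rounding.
#'
#' @param records data.frame with `subject_id` and `group` columns (sessions
#'   may repeat subjects).
#' @param n_repetitions number of repetitions (default 10).
#' @param fractions named numeric `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @return list of length `n_repetitions`; each element has `train`, `val`,
#'   `test` character vectors of subject ids.
#' @export
monte_carlo_splits <- function(records, n_repetitions = 10L,
                               fractions = c(train = 0.7, val = 0.1, test = 0.2),
                               seed = 1L) {
  stopifnot(n_repetitions >= 1L, length(fractions) == 3L,
            all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  assert_group(records$group)
  subj <- unique(records[, c("subject_id", "group")])
  if (anyDuplicated(subj$subject_id)) {
    stop("a subject appears with more than one diagnostic group", call. = FALSE)
  }
  strata <- split(subj$subject_id, subj$group)
  strata <- strata[lengths(strata) > 0L]

  counts <- lapply(strata, function(ids) {
    n_g <- length(ids)
    n_test <- round(fractions[["test"]] * n_g)
    n_val <- round(fractions[["val"]] * n_g)
    n_train <- n_g - n_test - n_val
    c(train = n_train, val = n_val, test = n_test)
  })
  for (g in names(counts)) {
    if (any(counts[[g]] < 1L)) {
      stop("stratum ", g, " (n = ", length(strata[[g]]),
           ") too small to populate train/val/test under fractions ",
           paste(fractions, collapse = "/"), call. = FALSE)
    }
  }

  with_seed(seed, {
    lapply(seq_len(n_repetitions), function(rep) {
      parts <- list(train = character(), val = character(), test = character())
      for (g in names(strata)) {
        ids <- sample(strata[[g]])
        k <- counts[[g]]
        parts$train <- c(parts$train, ids[seq_len(k[["train"]])])
        parts$val <- c(parts$val, ids[k[["train"]] + seq_len(k[["val"]])])
        parts$test <- c(parts$test, ids[k[["train"]] + k[["val"]] + seq_len(k[["test"]])])
      }
      parts
    })
  })
}

#' Training configuration
#'
#' @param optimizer "adam" or "sgd".
#' @param learning_rate initial learning rate (default 0.001).
#' @param scheduler_factor multiplicative learning-rate decay on plateau.
#' @param scheduler_patience epochs without validation-R2 improvement before
#'   the learning rate is decayed (default 7).
#' @param early_stop_patience epochs without improvement before training
#'   stops (default 20).
#' @param max_epochs epoch budget.
#' @param batch_size minibatch size.
#' @param loss "mse" (single-output), "al" or "wnl" (multi-output).
#' @param weights [loss_weights()] for the WNL strategy.
#' @param wnl_reset_per_epoch reset the WNL running maxima at each epoch
#'   start (default FALSE: run-global maxima).
#' @param standardize_targets z-score targets with train-partition statistics
#'   before computing the loss (default TRUE; predictions are always returned
#'   on the raw scale). Turning this off trains on raw pg/mL, which needs far
#'   more epochs to converge.
#' @param min_delta absolute improvement tolerance on validation R2.
#' @param seed integer seed for shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                         scheduler_factor = 0.5, scheduler_patience = 7L,
                         early_stop_patience = 20L, max_epochs = 60L,
                         batch_size = 8L, loss = c("mse", "al", "wnl"),
                         weights = loss_weights(), wnl_reset_per_epoch = FALSE,
                         standardize_targets = TRUE, min_delta = 1e-4,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, scheduler_factor > 0, scheduler_factor < 1,
            scheduler_patience >= 1L, early_stop_patience >= 1L,
            max_epochs >= 1L, batch_size >= 1L)
  structure(as.list(environment()), class = "train_config")
}

# ---- plateau scheduler / early stopping state machine ---------------------

scheduler_init <- function(lr, factor, patience, early_stop_patience,
                           min_delta = 1e-4) {
  list(lr = lr, factor = factor, patience = patience,
       early_stop_patience = early_stop_patience, min_delta = min_delta,
       best = -Inf, best_epoch = 0L, epoch = 0L,
       bad_epochs = 0L, stall_epochs = 0L, stop = FALSE, reduced = FALSE)
}

scheduler_step <- function(state, metric) {
  state$epoch <- state$epoch + 1L
  state$reduced <- FALSE
  if (is.finite(metric) && metric > state$best + state$min_delta) {
    state$best <- metric
    state$best_epoch <- state$epoch
    state$bad_epochs <- 0L
    state$stall_epochs <- 0L
  } else {
    state$bad_epochs <- state$bad_epochs + 1L
    state$stall_epochs <- state$stall_epochs + 1L
    if (state$bad_epochs >= state$patience) {
      state$lr <- state$lr * state$factor
      state$bad_epochs <- 0L
      state$reduced <- TRUE
    }
    if (state$stall_epochs >= state$early_stop_patience) state$stop <- TRUE
  }
  state
}

#' Replay the plateau scheduler on a scripted metric sequence
#'
#' Utility exposing the exact scheduler/early-stopping state machine the
#' training loop uses, for audit: given a sequence of validation metrics it
#' returns the learning rate in force at each epoch, the epochs at which the
#' rate was decayed, the best epoch, and where training would stop.
#'
#' @param metrics numeric vector of per-epoch validation metrics (higher is
#'   better).
#' @param config a [train_config()].
#' @return data.frame with epoch, metric, lr, reduced, stopped.
#' @export
simulate_plateau_schedule <- function(metrics, config = train_config()) {
  st <- scheduler_init(config$learning_rate, config$scheduler_factor,
                       config$scheduler_patience, config$early_stop_patience,
                       config$min_delta)
  rows <- vector("list", length(metrics))
  for (i in seq_along(metrics)) {
    st <- scheduler_step(st, metrics[i])
    rows[[i]] <- data.frame(epoch = i, metric = metrics[i], lr = st$lr,
                            reduced = st$reduced, stopped = st$stop)
    if (st$stop) { rows <- rows[seq_len(i)]; break }
  }
  do.call(rbind, rows)
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(m = list(conv = lapply(model$conv, function(l) zero_like(l[c("W", "gamma", "beta")])),
                heads = lapply(model$heads, function(h) zero_like(h[c("W1", "b1", "W2", "b2")]))),
       v = list(conv = lapply(model$conv, function(l) zero_like(l[c("W", "gamma", "beta")])),
                heads = lapply(model$heads, function(h) zero_like(h[c("W1", "b1", "W2", "b2")]))),
       t = 0L)
}

apply_update <- function(model, grads, opt, lr, optimizer = "adam",
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(param, grad, m, v) {
    if (optimizer == "sgd") {
      return(list(param = param - lr * grad, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad * grad
    step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(param = param - step, m = m, v = v)
  }
  for (l in seq_along(model$conv)) {
    for (f in c("W", "gamma", "beta")) {
      u <- upd(model$conv[[l]][[f]], grads$conv[[l]][[f]],
               opt$m$conv[[l]][[f]], opt$v$conv[[l]][[f]])
      model$conv[[l]][[f]] <- u$param
      opt$m$conv[[l]][[f]] <- u$m
      opt$v$conv[[l]][[f]] <- u$v
    }
  }
  for (j in seq_along(model$heads)) {
    for (f in c("W1", "b1", "W2", "b2")) {
      u <- upd(model$heads[[j]][[f]], grads$heads[[j]][[f]],
               opt$m$heads[[j]][[f]], opt$v$heads[[j]][[f]])
      model$heads[[j]][[f]] <- u$param
      opt$m$heads[[j]][[f]] <- u$m
      opt$v$heads[[j]][[f]] <- u$v
    }
  }
  list(model = model, opt = opt)
}

# ---- training loop --------------------------------------------------------

#' Train an MRINet regressor
#'
#' Optimizes the per-head batch MSE (single-output), its average (AL) or the
#' weighted running-maximum-normalized combination (WNL) with Adam (or SGD).
#' The validation coefficient of determination drives both the
#' reduce-on-plateau scheduler and early stopping; the parameters of the best
#' validation-R2 epoch are returned.
#'
#' @param model an [mrinet()].
#' @param volumes list of [gm_volume()]/arrays, one per session.
#' @param targets numeric matrix (n x n_heads) of raw pg/mL targets with
#'   columns in the model's marker order, or a vector for single-output.
#' @param train_idx,val_idx integer indices into `volumes` for the train and
#'   validation partitions.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch parameters, target statistics
#'   embedded), `history` (epoch, train_loss, val_r2, lr), `best_epoch`,
#'   `best_val_r2`, `stopped_early`.
#' @export
train_regressor <- function(model, volumes, targets, train_idx, val_idx,
                            config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "mrinet"), inherits(config, "train_config"),
            length(train_idx) >= 1L, length(val_idx) >= 1L)
  xs <- volumes_to_arrays(volumes)
  Y <- as.matrix(targets)
  stopifnot(nrow(Y) == length(xs), ncol(Y) == model$config$n_heads)
  if (model$config$n_heads > 1L && config$loss == "mse") {
    stop('multi-output models need loss = "al" or "wnl"', call. = FALSE)
  }
  if (model$config$n_heads == 1L && config$loss != "mse") {
    stop('single-output models use loss = "mse"', call. = FALSE)
  }

  mu <- colMeans(Y[train_idx, , drop = FALSE])
  sdv <- apply(Y[train_idx, , drop = FALSE], 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  if (!config$standardize_targets) { mu[] <- 0; sdv[] <- 1 }
  Yz <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
  model$target_stats <- list(mean = mu, sd = sdv)

  opt <- adam_init(model)
  sched <- scheduler_init(config$learning_rate, config$scheduler_factor,
                          config$scheduler_patience, config$early_stop_patience,
                          config$min_delta)
  wstate <- wnl_state()
  best_model <- model
  history <- vector("list", config$max_epochs)
  stopped_early <- FALSE

  for (epoch in seq_len(config$max_epochs)) {
    if (config$loss == "wnl" && config$wnl_reset_per_epoch) wstate <- wnl_state()
    order_idx <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)),
                           sample(train_idx))
    epoch_losses <- c()
    for (start in seq(1L, length(order_idx), by = config$batch_size)) {
      bidx <- order_idx[start:min(start + config$batch_size - 1L, length(order_idx))]
      fw <- net_forward(model, xs[bidx], train = TRUE, keep_cache = TRUE)
      model <- fw$model  # running BN statistics
      err <- fw$pred - Yz[bidx, , drop = FALSE]
      per_head_mse <- colMeans(err * err)
      if (any(!is.finite(per_head_mse))) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      nb <- length(bidx)
      if (config$loss == "mse") {
        batch_loss <- per_head_mse[1L]
        dpred <- 2 * err / nb
      } else if (config$loss == "al") {
        batch_loss <- al_loss(per_head_mse)
        dpred <- (2 * err / nb) / 3
      } else {
        names(per_head_mse) <- model$config$markers
        wl <- wnl_loss(per_head_mse, wstate, config$weights)
        wstate <- wl$state
        batch_loss <- wl$loss
        scale <- config$weights[model$config$markers] /
          pmax(wstate$running_max[model$config$markers], 1e-12)
        dpred <- (2 * err / nb) * rep(scale, each = nb)
      }
      bw <- net_backward(model, fw$cache, dpred, train = TRUE)
      u <- apply_update(model, bw$grads, opt, sched$lr, config$optimizer)
      model <- u$model
      opt <- u$opt
      epoch_losses <- c(epoch_losses, batch_loss)
    }

    val_fw <- mrinet_predict_raw(model, xs[val_idx])
    val_r2 <- mean(vapply(seq_len(ncol(Yz)), function(j) {
      regression_metrics(Yz[val_idx, j], val_fw[, j])$r2
    }, numeric(1L)))
    sched <- scheduler_step(sched, val_r2)
    if (sched$best_epoch == epoch) best_model <- model
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = mean(epoch_losses),
                                   val_r2 = val_r2, lr = sched$lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val R2 %.4f  lr %.2g",
                      epoch, mean(epoch_losses), val_r2, sched$lr))
    }
    if (sched$stop) { stopped_early <- TRUE; break }
  }

  list(model = best_model,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1L))]),
       best_epoch = sched$best_epoch, best_val_r2 = sched$best,
       stopped_early = stopped_early)
}

# Raw-scale standardized head outputs without de-standardization (internal,
# used for validation R2 where scale does not matter).
mrinet_predict_raw <- function(model, xs, batch_size = 16L) {
  preds <- NULL
  for (start in seq(1L, length(xs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(xs))
    fw <- net_forward(model, xs[idx], train = FALSE)
    preds <- rbind(preds, fw$pred)
  }
  preds
}
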