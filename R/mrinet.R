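# Compact 3D CNN regressor for gray-matter volumes ("MRINet").
#
# Architecture: a shared backbone of conv blocks (3x3x3 convolution -> batch
# normalization -> ReLU -> 2x max-pool), one block per entry of
# conv_channels, followed by global average pooling to a feature vector.
# Regression heads are two fully connected layers (hidden width 64 by
# default); the hidden ReLU activations of a head are the "latent embedding"
# transferred to classification. A single-output net (SO) has one head; the
# multi-output net (MO) has three, one per CSF marker, on the shared
# backbone.
#
# Everything is implemented here (no DL framework in the supported
# toolchain): forward, full backprop including gradients with respect to the
# input volume (needed for integrated gradients), and Adam. Convolution is
# im2col + BLAS matrix products with compiled gather/scatter kernels.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Network configuration
#'
#' @param conv_channels integer vector of conv-block output channels; the
#'   reference architecture is `c(64, 128, 192, 192, 128)`. Each block halves
#'   every grid axis, so all `input_dims` must be divisible by
#'   `2^length(conv_channels)`.
#' @param head_hidden width of the first fully connected head layer (the
#'   latent embedding length; default 64).
#' @param n_heads 1 (single-output) or 3 (multi-output).
#' @param input_dims integer length-3 input grid.
#' @param markers marker name(s) the head(s) predict; length must equal
#'   `n_heads`.
#' @return list of class `mrinet_config`.
#' @export
mrinet_config <- function(conv_channels = c(64L, 128L, 192L, 192L, 128L),
                          head_hidden = 64L, n_heads = 1L,
                          input_dims = c(32L, 32L, 32L),
                          markers = if (n_heads == 1L) "abeta" else MARKERS) {
  stopifnot(length(conv_channels) >= 1L, all(conv_channels >= 1L),
            head_hidden >= 1L, n_heads %in% c(1L, 3L),
            length(input_dims) == 3L, length(markers) == n_heads)
  pool_factor <- 2L^length(conv_channels)
  if (any(input_dims %% pool_factor != 0L)) {
    stop("input_dims ", paste(input_dims, collapse = "x"),
         " must be divisible by 2^n_blocks = ", pool_factor, call. = FALSE)
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 head_hidden = as.integer(head_hidden),
                 n_heads = as.integer(n_heads),
                 input_dims = as.integer(input_dims),
                 markers = markers),
            class = "mrinet_config")
}

#' Create an MRINet model
#'
#' He-initialized weights; batch-norm scale 1 / shift 0; running statistics
#' start at mean 0 / variance 1.
#'
#' @param config an [mrinet_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `mrinet`.
#' @export
mrinet <- function(config = mrinet_config(), seed = 1L) {
  stopifnot(inherits(config, "mrinet_config"))
  n_layers <- length(config$conv_channels)
  with_seed(seed, {
    conv <- vector("list", n_layers)
    cin <- 1L
    for (l in seq_len(n_layers)) {
      cout <- config$conv_channels[l]
      fan_in <- 27L * cin
      # no conv bias: batch normalization directly after the convolution
      # makes it exactly redundant (its gradient is identically zero)
      conv[[l]] <- list(
        W = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
        gamma = rep(1, cout), beta = numeric(cout),
        running_mean = numeric(cout), running_var = rep(1, cout)
      )
      cin <- cout
    }
    feat_dim <- config$conv_channels[n_layers]
    heads <- lapply(seq_len(config$n_heads), function(j) {
      list(W1 = matrix(rnorm(feat_dim * config$head_hidden,
                             sd = sqrt(2 / feat_dim)),
                       feat_dim, config$head_hidden),
           b1 = numeric(config$head_hidden),
           W2 = matrix(rnorm(config$head_hidden, sd = sqrt(1 / config$head_hidden)),
                       config$head_hidden, 1L),
           b2 = 0)
    })
    names(heads) <- config$markers
    structure(list(config = config, conv = conv, heads = heads,
                   target_stats = NULL),
              class = "mrinet")
  })
}

#' @export
print.mrinet <- function(x, ...) {
  cat(sprintf("<mrinet %s: %d conv blocks (%s), %d head(s) [%s], latent %d, input %s>\n",
              if (x$config$n_heads == 1L) "SO" else "MO",
              length(x$conv), paste(x$config$conv_channels, collapse = "-"),
              x$config$n_heads, paste(x$config$markers, collapse = ","),
              x$config$head_hidden,
              paste(x$config$input_dims, collapse = "x")))
  invisible(x)
}

# ---- forward --------------------------------------------------------------

# xlist: list of B input arrays (D,H,W). Returns predictions (B x n_heads,
# raw head scale), latents (per head, B x head_hidden), and, when keep_cache,
# everything backprop needs. Activations flow as one (B*nvox) x channels
# matrix whose rows are B contiguous sample blocks in column-major voxel
# order; the compiled kernels (im2col/col2im, fused BN+ReLU, batched
# max-pool) all share that layout. In train mode batch-norm uses batch
# statistics and updates the running ones (returned in $model).
net_forward <- function(model, xlist, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  B <- length(xlist)
  stopifnot(B >= 1L)
  for (x in xlist) {
    if (!identical(dim(x), cfg$input_dims)) {
      stop("input dims ", paste(dim(x), collapse = "x"),
           " do not match network input_dims ",
           paste(cfg$input_dims, collapse = "x"), call. = FALSE)
    }
  }
  n_layers <- length(model$conv)
  dims <- cfg$input_dims
  cin <- 1L
  cur <- matrix(unlist(xlist, use.names = FALSE), ncol = 1L)
  caches <- if (keep_cache) vector("list", n_layers) else NULL

  for (l in seq_len(n_layers)) {
    layer <- model$conv[[l]]
    cout <- ncol(layer$W)
    nvox <- prod(dims)
    P <- im2col3d_batch(cur, dims[1], dims[2], dims[3], B)
    Z <- P %*% layer$W
    if (train) {
      st <- bn_stats(Z)
      mu <- st$mean
      inv_sd <- 1 / sqrt(st$var + BN_EPS)
      model$conv[[l]]$running_mean <-
        (1 - BN_MOMENTUM) * layer$running_mean + BN_MOMENTUM * mu
      model$conv[[l]]$running_var <-
        (1 - BN_MOMENTUM) * layer$running_var + BN_MOMENTUM * st$var
    } else {
      mu <- layer$running_mean
      inv_sd <- 1 / sqrt(layer$running_var + BN_EPS)
    }
    fr <- bn_relu_fwd(Z, mu, inv_sd, layer$gamma, layer$beta)
    pool <- maxpool3d_fwd(fr$act, dims[1], dims[2], dims[3], B)
    if (keep_cache) {
      caches[[l]] <- list(P = P, zhat = fr$zhat, act = fr$act,
                          inv_sd = inv_sd, sel = pool$sel,
                          dims = dims, cin = cin, nvox = nvox, cout = cout)
    }
    cur <- pool$pooled
    dims <- dims %/% 2L
    cin <- cout
  }

  # global average pool over the residual spatial grid
  nvox_last <- prod(dims)
  feats <- matrix(0, B, cin)
  for (i in seq_len(B)) {
    rows <- ((i - 1L) * nvox_last + 1L):(i * nvox_last)
    feats[i, ] <- colMeans(cur[rows, , drop = FALSE])
  }

  preds <- matrix(0, B, cfg$n_heads, dimnames = list(NULL, cfg$markers))
  latents <- vector("list", cfg$n_heads)
  head_cache <- if (keep_cache) vector("list", cfg$n_heads) else NULL
  for (j in seq_len(cfg$n_heads)) {
    hd <- model$heads[[j]]
    H1 <- feats %*% hd$W1 + rep(hd$b1, each = B)
    L <- H1 * (H1 > 0)
    preds[, j] <- L %*% hd$W2 + hd$b2
    latents[[j]] <- L
    if (keep_cache) head_cache[[j]] <- list(H1 = H1, L = L)
  }
  names(latents) <- cfg$markers

  list(pred = preds, latents = latents, model = model,
       cache = if (keep_cache) list(conv = caches, feats = feats,
                                    heads = head_cache,
                                    nvox_last = nvox_last, B = B) else NULL)
}

# ---- backward -------------------------------------------------------------

# dpred: B x n_heads gradient of the loss w.r.t. raw head outputs.
# Returns parameter gradients (same structure as the model's conv/heads) and,
# when want_input_grad, the per-sample gradient w.r.t. the input volume.
# `train` must match the mode the cache was built in (batch-norm path).
net_backward <- function(model, cache, dpred, train = TRUE,
                         want_input_grad = FALSE) {
  cfg <- model$config
  B <- cache$B
  feats <- cache$feats
  grads <- list(conv = vector("list", length(model$conv)),
                heads = vector("list", cfg$n_heads))
  dfeats <- matrix(0, B, ncol(feats))
  for (j in seq_len(cfg$n_heads)) {
    hd <- model$heads[[j]]
    hc <- cache$heads[[j]]
    dp <- dpred[, j, drop = FALSE]
    dW2 <- t(hc$L) %*% dp
    db2 <- sum(dp)
    dL <- dp %*% t(hd$W2)
    dH1 <- dL * (hc$H1 > 0)
    dW1 <- t(feats) %*% dH1
    db1 <- colSums(dH1)
    dfeats <- dfeats + dH1 %*% t(hd$W1)
    grads$heads[[j]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  }

  # GAP backward: spread each feature gradient uniformly over last-grid voxels
  nvox_last <- cache$nvox_last
  dcur <- dfeats[rep(seq_len(B), each = nvox_last), , drop = FALSE] / nvox_last

  for (l in rev(seq_along(model$conv))) {
    cc <- cache$conv[[l]]
    layer <- model$conv[[l]]
    dR <- maxpool3d_bwd(dcur, cc$sel, B * cc$nvox)
    bb <- bn_relu_bwd(dR, cc$act, cc$zhat, layer$gamma, cc$inv_sd, train)
    grads$conv[[l]] <- list(W = crossprod(cc$P, bb$dZ),
                            gamma = bb$dgamma, beta = bb$dbeta)
    if (l > 1L || want_input_grad) {
      dP <- bb$dZ %*% t(layer$W)
      dcur <- col2im3d_batch(dP, cc$dims[1], cc$dims[2], cc$dims[3], B)
    }
  }

  input_grads <- if (want_input_grad) {
    d0 <- model$config$input_dims
    nvox0 <- prod(d0)
    lapply(seq_len(B), function(i) {
      array(dcur[((i - 1L) * nvox0 + 1L):(i * nvox0), 1L], dim = d0)
    })
  } else NULL
  list(grads = grads, input_grads = input_grads)
}

# ---- user-facing forward wrappers ----------------------------------------

volumes_to_arrays <- function(volumes) {
  if (inherits(volumes, "gm_volume")) volumes <- list(volumes)
  lapply(volumes, as_volume_array)
}

#' Predict CSF concentrations for a set of volumes
#'
#' Evaluation-mode forward pass (deterministic). When the model carries
#' target standardization statistics from training, predictions are returned
#' on the raw pg/mL scale.
#'
#' @param model a trained or fresh [mrinet()].
#' @param volumes list of [gm_volume()] (or 3D arrays).
#' @param batch_size forward-pass batch size.
#' @return list with `pred` (n x n_heads matrix, columns named by marker) and
#'   `latents` (per head, n x head_hidden matrix).
#' @export
mrinet_predict <- function(model, volumes, batch_size = 16L) {
  xs <- volumes_to_arrays(volumes)
  n <- length(xs)
  preds <- NULL; latents <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- net_forward(model, xs[idx], train = FALSE)
    preds <- rbind(preds, fw$pred)
    if (is.null(latents)) latents <- fw$latents
    else latents <- Map(rbind, latents, fw$latents)
  }
  if (!is.null(model$target_stats)) {
    for (j in seq_len(ncol(preds))) {
      preds[, j] <- preds[, j] * model$target_stats$sd[j] + model$target_stats$mean[j]
    }
  }
  list(pred = preds, latents = latents)
}

#' Single-output forward pass
#'
#' @param volume a [gm_volume()] or 3D array matching the model input dims.
#' @param model a single-output [mrinet()].
#' @return list with `prediction` (scalar, pg/mL when the model carries
#'   training target statistics) and `latent` (length `head_hidden`).
#' @export
forward_single <- function(model, volume) {
  stopifnot(inherits(model, "mrinet"), model$config$n_heads == 1L)
  out <- mrinet_predict(model, list(volume))
  list(prediction = unname(out$pred[1L, 1L]),
       latent = as.numeric(out$latents[[1L]][1L, ]))
}

#' Multi-output forward pass
#'
#' @param volume a [gm_volume()] or 3D array.
#' @param model a three-head [mrinet()].
#' @return list with `predictions` (named length-3: abeta, ptau, tau) and
#'   `latents` (list of three length-`head_hidden` vectors).
#' @export
forward_multi <- function(model, volume) {
  stopifnot(inherits(model, "mrinet"), model$config$n_heads == 3L)
  out <- mrinet_predict(model, list(volume))
  list(predictions = out$pred[1L, ],
       latents = lapply(out$latents, function(m) as.numeric(m[1L, ])))
}

#' Save / load an MRINet checkpoint (parameters with embedded config)
#'
#' @param model an [mrinet()].
#' @param path checkpoint path.
#' @return `path` invisibly; `load_mrinet` returns the model.
#' @export
save_mrinet <- function(model, path) {
  stopifnot(inherits(model, "mrinet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mrinet
#' @export
load_mrinet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mrinet"))
  model
}
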