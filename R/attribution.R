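# Integrated-gradients attribution on the input voxel grid, post-processing
# (Gaussian filter, [0,1] scaling), group-level mean and difference maps,
# and per-ROI summaries. Raw signed maps are kept alongside scaled maps:
# sign analyses (pathology direction) use the raw maps, group-level
# visual/summary analyses the scaled ones.

GROUP_PAIRS <- list(c("CN", "sMCI"), c("CN", "pMCI"), c("CN", "AD"),
                    c("sMCI", "pMCI"), c("sMCI", "AD"), c("pMCI", "AD"))

attribution_volume <- function(data, subject_id = NA_character_,
                               target = NA_character_, stage = "raw") {
  structure(list(data = data, subject_id = subject_id,
                 target = target, stage = stage),
            class = "attribution_volume")
}

#' @export
print.attribution_volume <- function(x, ...) {
  cat(sprintf("<attribution_volume %s target=%s stage=%s range [%.3g, %.3g]>\n",
              x$subject_id, x$target, x$stage, min(x$data), max(x$data)))
  invisible(x)
}

# Gradient of one scalar model output w.r.t. the input, batched over inputs.
input_gradients <- function(model, xlist, target_head) UseMethod("input_gradients")

#' @export
input_gradients.mrinet <- function(model, xlist, target_head) {
  fw <- net_forward(model, xlist, train = FALSE, keep_cache = TRUE)
  dpred <- matrix(0, length(xlist), model$config$n_heads)
  dpred[, target_head] <- 1
  bw <- net_backward(model, fw$cache, dpred, train = FALSE,
                     want_input_grad = TRUE)
  for (g in bw$input_grads) {
    if (any(!is.finite(g))) stop("non-finite input gradient", call. = FALSE)
  }
  bw$input_grads
}

#' Exact linear scorer (reference model for attribution checks)
#'
#' A model computing `f(x) = sum(w * x) + b`; its integrated-gradients
#' attribution has the closed form `w * x` (zero baseline) for any number of
#' path steps.
#'
#' @param w 3D array of voxel weights.
#' @param b intercept.
#' @return object of class `linear_scorer`.
#' @export
linear_scorer <- function(w, b = 0) {
  structure(list(w = w, b = b, config = list(input_dims = dim(w), n_heads = 1L)),
            class = "linear_scorer")
}

#' @export
input_gradients.linear_scorer <- function(model, xlist, target_head) {
  lapply(xlist, function(x) model$w)
}

model_scores <- function(model, xlist, target_head) {
  if (inherits(model, "linear_scorer")) {
    vapply(xlist, function(x) sum(model$w * x) + model$b, numeric(1L))
  } else {
    mrinet_predict_raw(model, xlist)[, target_head]
  }
}

#' Integrated-gradients attribution for one volume
#'
#' Path integral of the model gradient from a zero-input baseline to the
#' volume, approximated with a midpoint Riemann sum:
#' `attr_v = (x_v - b_v) * mean_k  d f / d x_v  at  b + ((k - 0.5)/n)(x - b)`.
#' For multi-output models the attribution is computed per head. The sum of
#' attributions converges to `f(x) - f(baseline)` (completeness) as `n_steps`
#' grows, and is exact for linear models at any `n_steps`.
#'
#' @param model an [mrinet()] (evaluation mode is used) or [linear_scorer()].
#' @param volume a [gm_volume()] or 3D array.
#' @param target_head head index or marker name (for multi-output models).
#' @param n_steps number of path steps (default 64).
#' @param chunk_size path steps evaluated per forward/backward batch.
#' @return An `attribution_volume` (stage `"raw"`, signed).
#' @export
integrated_gradients <- function(model, volume, target_head = 1L,
                                 n_steps = 64L, chunk_size = 16L) {
  stopifnot(n_steps >= 1L)
  x <- as_volume_array(volume)
  if (is.character(target_head)) {
    target_head <- match(target_head, model$config$markers)
    stopifnot(!is.na(target_head))
  }
  grad_sum <- array(0, dim = dim(x))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  for (start in seq(1L, n_steps, by = chunk_size)) {
    a <- alphas[start:min(start + chunk_size - 1L, n_steps)]
    xs <- lapply(a, function(al) al * x)
    gs <- input_gradients(model, xs, target_head)
    for (g in gs) grad_sum <- grad_sum + g
  }
  attribution_volume(x * grad_sum / n_steps,
                     subject_id = if (inherits(volume, "gm_volume"))
                       volume$subject_id else NA_character_,
                     target = if (!is.null(model$config$markers))
                       model$config$markers[target_head] else NA_character_,
                     stage = "raw")
}

#' Post-process a raw attribution map
#'
#' 3D Gaussian filtering (default sd 2 voxels truncated at 1.75 sd, i.e. a
#' 9 x 9 x 9 kernel) followed by per-subject min-max scaling to `[0, 1]`.
#' A constant (degenerate-range) map scales to all zeros.
#'
#' @param raw an `attribution_volume` at stage `"raw"`.
#' @param smoothing_sd Gaussian sd in voxels.
#' @param truncate kernel support in sd multiples.
#' @return An `attribution_volume` at stage `"scaled"`, values in `[0, 1]`.
#' @export
postprocess_attribution <- function(raw, smoothing_sd = 2, truncate = 1.75) {
  stopifnot(inherits(raw, "attribution_volume"), raw$stage == "raw",
            smoothing_sd >= 0)
  d <- raw$data
  if (smoothing_sd > 0) d <- smooth_array3d(d, smoothing_sd, truncate)
  rng <- range(d)
  d <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else array(0, dim(d))
  attribution_volume(d, raw$subject_id, raw$target, stage = "scaled")
}

as_attribution_array <- function(x) {
  if (inherits(x, "attribution_volume")) x$data else x
}

#' Group mean and paired-difference attribution maps
#'
#' @param maps list of `attribution_volume`s (or arrays) on a common grid.
#' @param groups diagnostic group per map (CN/sMCI/pMCI/AD).
#' @return list with `group_means` (one array per group present) and
#'   `pair_diffs` (array per unordered pair, named `"A-B"`, value
#'   `mean_A - mean_B`).
#' @export
group_difference_maps <- function(maps, groups) {
  stopifnot(length(maps) == length(groups))
  assert_group(groups)
  arrays <- lapply(maps, as_attribution_array)
  check_same_grid(arrays)
  present <- DIAGNOSTIC_GROUPS[DIAGNOSTIC_GROUPS %in% groups]
  missing <- setdiff(DIAGNOSTIC_GROUPS, present)
  if (length(missing) > 0L) {
    stop("empty group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  group_means <- lapply(DIAGNOSTIC_GROUPS, function(g) {
    idx <- which(groups == g)
    acc <- arrays[[idx[1L]]]
    if (length(idx) > 1L) for (i in idx[-1L]) acc <- acc + arrays[[i]]
    acc / length(idx)
  })
  names(group_means) <- DIAGNOSTIC_GROUPS
  pair_diffs <- lapply(GROUP_PAIRS, function(p) {
    group_means[[p[1L]]] - group_means[[p[2L]]]
  })
  names(pair_diffs) <- vapply(GROUP_PAIRS, paste, character(1L), collapse = "-")
  list(group_means = group_means, pair_diffs = pair_diffs)
}

#' Per-region sum and mean of an attribution map
#'
#' @param map an `attribution_volume` or 3D array.
#' @param atlas a [make_atlas()] atlas on the same grid (background label 0
#'   is excluded).
#' @return data.frame with region, name, n_voxels, sum, mean (`NA` mean for
#'   empty regions).
#' @export
regional_summary <- function(map, atlas) {
  arr <- as_attribution_array(map)
  stopifnot(inherits(atlas, "roi_atlas"), identical(dim(arr), dim(atlas$labels)))
  k <- length(atlas$names)
  sums <- vapply(seq_len(k), function(r) sum(arr[atlas$labels == r]), numeric(1L))
  nvox <- vapply(seq_len(k), function(r) sum(atlas$labels == r), numeric(1L))
  data.frame(region = seq_len(k), name = atlas$names, n_voxels = nvox,
             sum = sums, mean = ifelse(nvox > 0, sums / nvox, NA_real_))
}

#' Rank group pairs by attribution-difference magnitude in signal regions
#'
#' Orders the six diagnostic-group pairs by the mean absolute pair-difference
#' attribution within the atlas signal regions, descending; exact ties break
#' alphabetically by pair name. On cohorts generated by this package the
#' ranking should follow the generator severity gaps, with (CN, AD) first
#' and (CN, sMCI) last.
#'
#' @param pair_diffs named list of six pair-difference arrays, as produced
#'   by [group_difference_maps()].
#' @param atlas a [make_atlas()] atlas with at least one signal region.
#' @return data.frame (pair, magnitude) sorted descending.
#' @export
rank_pair_magnitudes <- function(pair_diffs, atlas) {
  stopifnot(length(pair_diffs) == 6L, inherits(atlas, "roi_atlas"),
            any(atlas$signal_flags))
  mask <- atlas$labels > 0 &
    array(atlas$signal_flags[pmax(atlas$labels, 1L)], dim = dim(atlas$labels))
  mags <- vapply(pair_diffs, function(d) mean(abs(d[mask])), numeric(1L))
  out <- data.frame(pair = names(pair_diffs), magnitude = unname(mags))
  out[order(-out$magnitude, out$pair), , drop = FALSE]
}

#' Dominant attribution sign within signal regions
#'
#' Sign of the mean raw attribution inside signal ROIs, pooled over a list
#' of raw maps. Heads predicting abeta (which falls with atrophy) and
#' ptau/tau (which rise) should have opposite dominant signs.
#'
#' @param maps list of raw `attribution_volume`s or arrays.
#' @param atlas atlas with signal regions.
#' @return `+1`, `-1` or `0`.
#' @export
dominant_sign <- function(maps, atlas) {
  mask <- atlas$labels > 0 &
    array(atlas$signal_flags[pmax(atlas$labels, 1L)], dim = dim(atlas$labels))
  m <- mean(vapply(maps, function(x) mean(as_attribution_array(x)[mask]),
                   numeric(1L)))
  sign(m)
}
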