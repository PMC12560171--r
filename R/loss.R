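# Multi-task loss strategies for the three-head regressor: the plain average
# loss (AL) and the weighted normalized loss (WNL), which keeps a running
# maximum of each marker's batch loss and combines the maximum-normalized
# losses with fixed weights favouring abeta (the most predictive marker).

#' Average loss over the three marker heads
#'
#' @param per_marker_mse named or unnamed numeric length-3 of non-negative
#'   per-marker batch MSEs.
#' @return their arithmetic mean.
#' @export
al_loss <- function(per_marker_mse) {
  stopifnot(length(per_marker_mse) == 3L)
  if (any(per_marker_mse < 0)) stop("losses must be non-negative", call. = FALSE)
  mean(as.numeric(per_marker_mse))
}

#' Loss weights for the WNL strategy
#'
#' Non-negative weights summing to 1; the default gives abeta 50% and tau and
#' ptau 25% each.
#'
#' @param w_abeta,w_tau,w_ptau weights.
#' @return named numeric in marker order (abeta, ptau, tau).
#' @export
loss_weights <- function(w_abeta = 0.50, w_tau = 0.25, w_ptau = 0.25) {
  w <- c(abeta = w_abeta, ptau = w_ptau, tau = w_tau)
  if (any(w < 0)) stop("loss weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12) stop("loss weights must sum to 1", call. = FALSE)
  w
}

#' Fresh running-maximum state for the WNL loss
#'
#' @return list of class `wnl_state` with per-marker running maxima (starting
#'   at 0, i.e. no loss observed yet) and a step counter.
#' @export
wnl_state <- function() {
  structure(list(running_max = c(abeta = 0, ptau = 0, tau = 0),
                 step_count = 0L),
            class = "wnl_state")
}

#' Weighted normalized loss update
#'
#' For each marker `k`: the running maximum is raised to
#' `max(running_max_k, loss_k)`, the normalized loss is
#' `n_k = loss_k / running_max_k` (0 when both are 0), and the combined loss
#' is the weighted sum of the `n_k`. On the first batch every observed
#' positive loss is its own maximum, so the combined loss is 1.
#'
#' @param per_marker_mse named numeric length-3 (abeta, ptau, tau) of
#'   non-negative batch MSEs.
#' @param state a [wnl_state()].
#' @param weights a [loss_weights()] vector.
#' @return list with `loss` (scalar in `[0, 1]`) and `state` (updated).
#' @export
wnl_loss <- function(per_marker_mse, state = wnl_state(), weights = loss_weights()) {
  stopifnot(inherits(state, "wnl_state"), length(per_marker_mse) == 3L)
  if (any(per_marker_mse < 0)) stop("losses must be non-negative", call. = FALSE)
  losses <- as.numeric(per_marker_mse)
  if (!is.null(names(per_marker_mse))) {
    stopifnot(setequal(names(per_marker_mse), MARKERS))
    losses <- as.numeric(per_marker_mse[MARKERS])
  }
  names(losses) <- MARKERS
  state$running_max <- pmax(state$running_max, losses)
  normalized <- ifelse(state$running_max > 0, losses / state$running_max, 0)
  state$step_count <- state$step_count + 1L
  list(loss = sum(weights[MARKERS] * normalized[MARKERS]), state = state)
}
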