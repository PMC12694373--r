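#' @title Adaptive focal loss
#' @description
#' An IoU-aware classification loss for imbalanced detection. It extends
#' varifocal loss with two adaptive mechanisms: a training-step decay
#' factor `D_i = delta * (1 - exp(-i / lambda))` that smooths a dynamic
#' IoU threshold, and a piecewise modulating weight driven by that
#' threshold. The threshold `auto_iou` is an exponential moving average of
#' the mean IoU of positive matches in each batch, floored at 0.2:
#' `auto_iou = max(D_i * auto_iou_pre + (1 - D_i) * iou_batch, 0.2)`.
#' Samples whose ground-truth quality sits just below the threshold are
#' amplified, easy high-quality samples are damped, and low-quality
#' samples keep weight 1, which steers learning toward the informative
#' medium-quality band — the band where rare-class samples typically live.
#' The decay factor enters only the threshold update; it never scales the
#' loss itself. The modulating weight depends only on ground-truth
#' quantities, so it contributes no gradient with respect to predictions.
#' @name afl
NULL

#' Create the mutable state of the adaptive focal loss
#'
#' @param delta decay coefficient of the threshold EMA (default 0.999).
#' @param lambda decay-rate constant in optimizer steps (default 2000).
#' @param alpha negative-sample scaling of the varifocal base (default 0.75).
#' @param gamma focusing exponent of the varifocal base (default 2.0).
#' @param iou_floor lower bound of the dynamic threshold (default 0.2).
#' @param auto_iou initial threshold; defaults to the floor, so the first
#'   update is dominated by the first batch IoU (`D_0 = 0`).
#' @return an object of class `afl_state` with fields `i` (update count),
#'   `auto_iou`, `auto_iou_pre` and the constants above.
#' @examples
#' st <- afl_state()
#' st <- update_auto_iou(st, iou_batch = 0.55)
#' st$auto_iou
#' @export
afl_state <- function(delta = 0.999, lambda = 2000, alpha = 0.75,
                      gamma = 2.0, iou_floor = 0.2, auto_iou = iou_floor) {
  stopifnot(delta > 0, delta < 1, lambda > 0, iou_floor >= 0,
            auto_iou >= iou_floor, auto_iou <= 1)
  structure(list(i = 0L, auto_iou = auto_iou, auto_iou_pre = auto_iou,
                 delta = delta, lambda = lambda, alpha = alpha,
                 gamma = gamma, iou_floor = iou_floor),
            class = "afl_state")
}

#' Training-step decay factor
#'
#' `D_i = delta * (1 - exp(-i / lambda))`: near 0 early in training and
#' approaching `delta` as the update count grows. The exponent uses
#' `i / lambda`; `lambda` is the number of steps over which the factor
#' saturates.
#'
#' @param i non-negative update count (vectorized).
#' @param delta decay coefficient in (0, 1).
#' @param lambda positive decay-rate constant (steps).
#' @return decay factor in `[0, delta)`.
#' @export
decay_factor <- function(i, delta = 0.999, lambda = 2000) {
  if (any(i < 0)) stop("update count i must be non-negative")
  if (lambda <= 0) stop("lambda must be positive")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  delta * (1 - exp(-i / lambda))
}

#' Update the dynamic IoU threshold
#'
#' Applies one EMA step
#' `auto_iou <- max(D_i * auto_iou_pre + (1 - D_i) * iou_batch, floor)`
#' where `auto_iou_pre` is the threshold before this update, then
#' increments the update counter. Call once per optimizer step with the
#' mean IoU of the step's positive matches; if a batch has no positives,
#' re-use the previous step's `iou_batch`.
#'
#' @param state an [afl_state()].
#' @param iou_batch mean IoU of positive matches in the batch, in `[0, 1]`.
#' @return the updated state.
#' @export
update_auto_iou <- function(state, iou_batch) {
  stopifnot(inherits(state, "afl_state"))
  if (!is.finite(iou_batch) || iou_batch < 0 || iou_batch > 1)
    stop("iou_batch must lie in [0, 1]")
  d_i <- decay_factor(state$i, state$delta, state$lambda)
  state$auto_iou_pre <- state$auto_iou
  state$auto_iou <- max(d_i * state$auto_iou_pre + (1 - d_i) * iou_batch,
                        state$iou_floor)
  state$i <- state$i + 1L
  state
}

#' Piecewise modulating weight
#'
#' Three intervals of the ground-truth quality relative to the dynamic
#' threshold:
#' weight 1 for `true_quality <= auto_iou - 0.1`;
#' `exp(1 - auto_iou)` for `auto_iou - 0.1 < true_quality < auto_iou`;
#' `exp(1 - true_quality)` for `true_quality >= auto_iou`.
#' The weight is a pure function of ground-truth quantities and is treated
#' as a constant when differentiating the loss.
#'
#' @param true_quality ground-truth quality targets in `[0, 1]` (vectorized).
#' @param auto_iou current dynamic threshold in `[0.2, 1]`.
#' @return weights in `[1, exp(0.8)]`.
#' @export
modulating_weight <- function(true_quality, auto_iou) {
  if (any(true_quality < 0 | true_quality > 1))
    stop("true_quality must lie in [0, 1]")
  if (auto_iou < 0.2 || auto_iou > 1)
    stop("auto_iou must lie in [0.2, 1]")
  w <- rep(1, length(true_quality))
  mid <- true_quality > auto_iou - 0.1 & true_quality < auto_iou
  hi <- true_quality >= auto_iou
  w[mid] <- exp(1 - auto_iou)
  w[hi] <- exp(1 - true_quality[hi])
  w
}

# stable binary cross-entropy with logits:
# max(x,0) - x*t + log(1 + exp(-|x|))
bce_with_logits <- function(x, t) {
  pmax(x, 0) - x * t + log1p(exp(-abs(x)))
}

#' Varifocal base loss (per element)
#'
#' `[alpha * sigmoid(pred)^gamma * (1 - q) + q] * BCE_with_logits(pred, q)`
#' where `q` is the IoU-aware target: the match IoU in the assigned class
#' channel for positives, 0 elsewhere. Negatives are down-weighted by the
#' predicted confidence raised to `gamma`; positives are weighted by their
#' target quality.
#'
#' @param pred_logit predicted score(s), pre-sigmoid (vectorized).
#' @param true_quality target quality in `[0, 1]`.
#' @param alpha negative-sample scaling (default 0.75).
#' @param gamma focusing exponent (default 2.0).
#' @return non-negative per-element loss in nats.
#' @export
varifocal_loss <- function(pred_logit, true_quality, alpha = 0.75,
                           gamma = 2.0) {
  if (any(!is.finite(pred_logit))) stop("pred_logit must be finite")
  if (any(true_quality < 0 | true_quality > 1))
    stop("true_quality must lie in [0, 1]")
  p <- sigmoid(pred_logit)
  wt <- alpha * p^gamma * (1 - true_quality) + true_quality
  wt * bce_with_logits(pred_logit, true_quality)
}

#' Analytic gradient of the weighted varifocal loss w.r.t. the logit
#'
#' Derivative of `modulating_weight * varifocal_loss` with the modulating
#' weight held constant (it carries no gradient). Used by the desk-scale
#' trainer and by the gradient-purity tests.
#'
#' @inheritParams varifocal_loss
#' @param mod_weight modulating weight treated as a constant (default 1).
#' @return per-element derivative.
#' @export
varifocal_grad <- function(pred_logit, true_quality, alpha = 0.75,
                           gamma = 2.0, mod_weight = 1) {
  p <- sigmoid(pred_logit)
  bce <- bce_with_logits(pred_logit, true_quality)
  wt <- alpha * p^gamma * (1 - true_quality) + true_quality
  dwt <- alpha * gamma * p^(gamma - 1) * p * (1 - p) * (1 - true_quality)
  mod_weight * (dwt * bce + wt * (p - true_quality))
}

#' Batch adaptive focal loss
#'
#' Mean over elements of `varifocal_loss * modulating_weight`, evaluated at
#' the state's current threshold. The decay factor does not scale this
#' value; it only smooths the threshold, which the caller advances
#' separately with [update_auto_iou()] once per optimizer step.
#'
#' @param pred_logits vector of predicted logits.
#' @param true_quality vector of ground-truth quality targets in `[0, 1]`.
#' @param state an [afl_state()].
#' @return scalar loss (nats).
#' @export
afl_batch_loss <- function(pred_logits, true_quality, state) {
  stopifnot(inherits(state, "afl_state"))
  if (length(pred_logits) == 0L) stop("batch must be non-empty")
  if (length(pred_logits) != length(true_quality))
    stop("pred_logits and true_quality lengths differ")
  w <- modulating_weight(true_quality, state$auto_iou)
  mean(varifocal_loss(pred_logits, true_quality,
                      alpha = state$alpha, gamma = state$gamma) * w)
}
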