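# Multi-layer Tversky supervision.
#
# Each supervised head contributes 1 - TI where
#   TI = TP / (TP + alpha*FP + beta*FN)
# over *soft* voxel counts (probabilities, not thresholded masks), which
# keeps the loss differentiable. alpha = 0.3 and beta = 0.7 weight false
# negatives more heavily than false positives, trading precision for recall
# so thin structures are not dropped. The printed form of the objective is
# the sum of the indices themselves (large when predictions are good); it is
# implemented as sum(1 - TI) so that gradient-descent minimization matches.

#' Loss configuration
#'
#' @param alpha False-positive weight (published value 0.3).
#' @param beta False-negative weight (published value 0.7); `beta > alpha`
#'   emphasizes recall over precision.
#' @param smooth Non-negative denominator stabilizer; also resolves the
#'   empty-foreground case (an all-background prediction of an all-background
#'   patch scores TI = 1).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.3, beta = 0.7, smooth = 1e-6) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop("loss config: need alpha, beta >= 0 and alpha + beta > 0")
  if (smooth < 0) stop("loss config: smooth must be >= 0")
  structure(list(alpha = alpha, beta = beta, smooth = smooth),
            class = "loss_config")
}

#' Soft confusion counts
#'
#' Accumulates probabilistic true/false positive/negative voxel counts of a
#' soft prediction against a binary reference:
#' `tp = sum(G*P)`, `fp = sum((1-G)*P)`, `fn = sum(G*(1-P))`,
#' `tn = sum((1-G)*(1-P))`.
#'
#' @param p Probability array in `[0, 1]`.
#' @param g Binary reference array of the same shape.
#' @return List with fields `tp`, `fp`, `fn`, `tn`.
#' @export
soft_confusion <- function(p, g) {
  if (!identical(dim(p), dim(g)) && length(p) != length(g))
    stop("soft_confusion: shapes differ")
  if (any(p < 0 | p > 1)) stop("soft_confusion: probabilities outside [0, 1]")
  if (!all(g %in% c(0, 1))) stop("soft_confusion: reference must be binary")
  tp <- sum(g * p)
  fp <- sum((1 - g) * p)
  fn <- sum(g * (1 - p))
  list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
}

#' Tversky index of soft confusion counts
#'
#' `TI = (tp + smooth) / (tp + alpha*fp + beta*fn + smooth)`. With
#' `alpha = beta = 0.5` the index reduces to the soft Dice coefficient (up to
#' its habitual rescaling). An all-zero denominator (empty foreground, empty
#' prediction, `smooth = 0`) returns 1 by the empty-foreground convention.
#'
#' @param confusion List from [soft_confusion()].
#' @param config A [loss_config()].
#' @return Scalar in `[0, 1]`.
#' @export
tversky_index <- function(confusion, config = loss_config()) {
  den <- confusion$tp + config$alpha * confusion$fp +
    config$beta * confusion$fn + config$smooth
  if (den <= 0) return(1)
  (confusion$tp + config$smooth) / den
}

#' Deep-supervision loss
#'
#' Sums `1 - TI` over all supervised prediction heads. Every head must be at
#' the reference resolution. In multi-supervision mode the loss of a
#' perfectly wrong prediction is therefore the number of heads.
#'
#' @param preds Named list of probability arrays (one per head), as returned
#'   by [forward()].
#' @param g Binary reference mask at the prediction resolution.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
deep_supervision_loss <- function(preds, g, config = loss_config()) {
  if (length(preds) == 0) stop("deep_supervision_loss: no prediction heads")
  g <- as_tensor(g)
  sum(vapply(preds, function(p) {
    p <- as_tensor(p)
    if (!all(dim(p)[1:3] == dim(g)[1:3]))
      stop("deep_supervision_loss: head resolution differs from the reference")
    1 - tversky_index(soft_confusion(p, g), config)
  }, numeric(1)))
}

# node-level version used by the training loop
loss_nodes <- function(pred_nodes, g, config) {
  terms <- lapply(pred_nodes, function(p)
    ag_tversky_term(p, g, config$alpha, config$beta, config$smooth))
  ag_sum_nodes(terms)
}
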