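#' Detection loss weights
#'
#' Constant weights of the four-term detection loss. Cells that contain no
#' particle center must be penalized less than missed particles, so
#' `lambda_noobj` is required to be smaller than `lambda_obj`: this is what
#' lets training tolerate sparsely labeled micrographs, where unlabeled true
#' particles sit in "no-object" cells.
#'
#' @param lambda_coord Weight of the two coordinate-regression terms.
#' @param lambda_obj Weight of the confidence term at object cells.
#' @param lambda_noobj Weight of the confidence term at no-object cells.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_coord = 5, lambda_obj = 5,
                         lambda_noobj = 0.5) {
  if (min(lambda_coord, lambda_obj, lambda_noobj) < 0)
    stop_cfg("loss weights must be nonnegative")
  if (lambda_noobj >= lambda_obj)
    stop_cfg("lambda_noobj must be smaller than lambda_obj")
  structure(list(lambda_coord = lambda_coord, lambda_obj = lambda_obj,
                 lambda_noobj = lambda_noobj), class = "loss_weights")
}

#' Four-term detection loss
#'
#' For an S-by-S grid with object indicator `1_obj`, the loss is
#' \deqn{L = \lambda_{coord} \sum_{obj} [(x-\hat x)^2 + (y-\hat y)^2]
#'     + \lambda_{coord} \sum_{obj} [(\sqrt w-\sqrt{\hat w})^2
#'                                  + (\sqrt h-\sqrt{\hat h})^2]
#'     + \lambda_{obj} \sum_{obj} (C-\hat C)^2
#'     + \lambda_{noobj} \sum_{noobj} (C-\hat C)^2}
#' summed over all cells. The sixth predicted channel (the class score,
#' redundant with a single particle class) is trained toward 1 at object
#' cells and 0 elsewhere with the same confidence weights, and is ignored
#' when decoding.
#'
#' @param pred Prediction array, S-by-S-by-6, channels
#'   (x, y, w, h, confidence, class score), after output activations
#'   (offsets and confidences in (0,1), sizes positive).
#' @param target A `target_tensor` from [encode_boxes()].
#' @param w A [loss_weights()] object.
#' @return Nonnegative scalar loss.
#' @export
detection_loss <- function(pred, target, w = loss_weights()) {
  stopifnot(inherits(target, "target_tensor"), length(dim(pred)) == 3)
  if (!all(dim(pred)[1:2] == dim(target$obj)))
    stop_cfg("prediction and target grids differ in shape")
  if (any(pred[, , 3:4] < 0))
    stop_cfg("predicted box sizes must be nonnegative")
  obj <- target$obj
  noobj <- 1 - obj
  l_xy <- sum(obj * ((target$x - pred[, , 1])^2 + (target$y - pred[, , 2])^2))
  l_wh <- sum(obj * ((sqrt(target$w) - sqrt(pred[, , 3]))^2 +
                     (sqrt(target$h) - sqrt(pred[, , 4]))^2))
  l_obj <- sum(obj * (target$C - pred[, , 5])^2) +
           sum(obj * (1 - pred[, , 6])^2)
  l_noobj <- sum(noobj * (target$C - pred[, , 5])^2) +
             sum(noobj * (0 - pred[, , 6])^2)
  w$lambda_coord * (l_xy + l_wh) + w$lambda_obj * l_obj +
    w$lambda_noobj * l_noobj
}

#' Analytic gradient of the detection loss
#'
#' Gradient of [detection_loss()] with respect to the activated prediction
#' array, used by the training loop (and checked against finite differences
#' in the test suite).
#'
#' @inheritParams detection_loss
#' @return Array of the same shape as `pred`.
#' @export
detection_loss_grad <- function(pred, target, w = loss_weights()) {
  obj <- target$obj
  noobj <- 1 - obj
  g <- array(0, dim(pred))
  g[, , 1] <- -2 * w$lambda_coord * obj * (target$x - pred[, , 1])
  g[, , 2] <- -2 * w$lambda_coord * obj * (target$y - pred[, , 2])
  # d/dp (sqrt(t) - sqrt(p))^2 = -(sqrt(t) - sqrt(p)) / sqrt(p)
  sp_w <- sqrt(pmax(pred[, , 3], 1e-12))
  sp_h <- sqrt(pmax(pred[, , 4], 1e-12))
  g[, , 3] <- -w$lambda_coord * obj * (sqrt(target$w) - sp_w) / sp_w
  g[, , 4] <- -w$lambda_coord * obj * (sqrt(target$h) - sp_h) / sp_h
  wc <- w$lambda_obj * obj + w$lambda_noobj * noobj
  g[, , 5] <- -2 * wc * (target$C - pred[, , 5])
  g[, , 6] <- -2 * wc * (obj - pred[, , 6])
  g
}

# Perfect prediction array for a target (class channel = objectness);
# useful for oracle models and loss tests.
target_to_pred <- function(target) {
  S <- nrow(target$obj)
  arr <- array(0, c(S, S, 6))
  arr[, , 1] <- target$x; arr[, , 2] <- target$y
  arr[, , 3] <- target$w; arr[, , 4] <- target$h
  arr[, , 5] <- target$C; arr[, , 6] <- target$obj
  arr
}
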