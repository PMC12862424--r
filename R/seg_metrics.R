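#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. By convention two empty masks score 1
#' (perfect agreement on absence); a warning notes when that convention is
#' used. The maximum attainable score is 1, for identical masks.
#'
#' @param prediction,truth Logical (or 0/1) arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
#' dice_score(a, a)  # 1
dice_score <- function(prediction, truth) {
  if (!identical(dim(prediction), dim(truth)))
    stop_fp("masks must have identical shape", "fp_error_value")
  p <- as.logical(prediction); t <- as.logical(truth)
  denom <- sum(p) + sum(t)
  if (denom == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(p & t) / denom
}

#' Per-class Dice report for multi-label volumes
#'
#' Binary Dice per listed class plus the macro mean across classes. A
#' pooled (micro) Dice over all listed classes together is also reported,
#' since summaries over cases can be formed either way.
#'
#' @param prediction,truth [label_volume()]s on the same grid.
#' @param classes Label codes or names to evaluate (default the three
#'   foreground structures).
#' @return Object of class `metric_report` with fields `per_class_dice`,
#'   `mean_dice`, `pooled_dice` and `classes`.
#' @export
multiclass_dice <- function(prediction, truth, classes = c(1L, 2L, 3L)) {
  stopifnot(inherits(prediction, "label_volume"),
            inherits(truth, "label_volume"))
  if (!identical(dim(prediction$voxels), dim(truth$voxels)))
    stop_fp("volumes must share grid shape", "fp_error_value")
  if (!isTRUE(all.equal(prediction$spacing, truth$spacing)))
    stop_fp("volumes must share voxel spacing", "fp_error_value")
  codes <- vapply(classes, function(cl) resolve_label(truth, cl), integer(1))
  names(codes) <- names(truth$schema)[match(codes, truth$schema)]
  per <- vapply(codes, function(code) {
    p <- prediction$voxels == code
    t <- truth$voxels == code
    denom <- sum(p) + sum(t)
    if (denom == 0) 1 else 2 * sum(p & t) / denom
  }, numeric(1))
  pin <- prediction$voxels %in% codes
  tin <- truth$voxels %in% codes
  agree <- pin & tin & (prediction$voxels == truth$voxels)
  pooled <- if (sum(pin) + sum(tin) == 0) 1 else
    2 * sum(agree) / (sum(pin) + sum(tin))
  structure(list(per_class_dice = per, mean_dice = mean(per),
                 pooled_dice = pooled, classes = codes),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Dice report\n")
  for (i in seq_along(x$per_class_dice))
    cat(sprintf("  %-12s (%d): %.4f\n", names(x$classes)[i], x$classes[i],
                x$per_class_dice[i]))
  cat(sprintf("  macro mean: %.4f   pooled: %.4f\n", x$mean_dice,
              x$pooled_dice))
  invisible(x)
}

#' Differentiable Soft IoU loss
#'
#' `1 - sum(y * yhat) / (sum(y + yhat - y * yhat) + eta)` for a single
#' foreground class, where `yhat` are per-voxel foreground probabilities
#' and `eta >= 0` is a smoothing coefficient. With binary `yhat` and
#' `eta = 0` this equals `1 - IoU`.
#'
#' @param prediction Numeric array of probabilities in \[0, 1\].
#' @param truth Logical (or 0/1) array of the same shape.
#' @param eta Smoothing coefficient, >= 0 (default 1).
#' @return Scalar loss in \[0, 1\].
#' @export
soft_iou_loss <- function(prediction, truth, eta = 1) {
  if (!identical(dim(prediction), dim(truth)))
    stop_fp("prediction and truth must have identical shape",
            "fp_error_value")
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0)
    stop_fp("eta must be a single value >= 0", "fp_error_value")
  p <- as.numeric(prediction)
  if (any(p < 0 | p > 1))
    stop_fp("prediction probabilities must lie in [0, 1]", "fp_error_value")
  y <- as.numeric(as.logical(truth))
  num <- sum(y * p)
  den <- sum(y + p - y * p) + eta
  if (den == 0) return(0)   # both empty, eta = 0: no disagreement mass
  1 - num / den
}
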