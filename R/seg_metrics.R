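#' Pixel confusion counts between a prediction and a reference
#'
#' @param pred,gt 2D 0/1 matrices of identical dimensions.
#' @return List with `tp`, `fp`, `fn`, `tn`; the four counts partition the
#'   slice exhaustively.
#' @export
confusion_counts <- function(pred, gt) {
  cg_assert(identical(dim(pred), dim(gt)), "cg_error_dim_mismatch",
            "prediction and reference dims differ")
  pred <- as_binary_mask(pred)
  gt <- as_binary_mask(gt)
  tp <- sum(pred == 1L & gt == 1L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  list(tp = tp, fp = fp, fn = fn, tn = length(pred) - tp - fp - fn)
}

#' Lesion detection flag
#'
#' 1 if the prediction overlaps the reference lesion in at least one pixel,
#' else 0. A prediction disjoint from the lesion has not segmented it, so
#' mere non-emptiness does not count as detection.
#'
#' @param pred,gt 2D 0/1 matrices; `gt` non-empty (lesion-free slices are
#'   removed during preprocessing).
#' @return 0 or 1.
#' @export
detection <- function(pred, gt) {
  cg_assert(sum(gt) > 0, "cg_error_empty_lesion", "reference mask is empty")
  cg_assert(identical(dim(pred), dim(gt)), "cg_error_dim_mismatch",
            "prediction and reference dims differ")
  as.integer(any(pred == 1 & gt == 1))
}

#' Dice similarity coefficient from confusion counts
#'
#' \eqn{DSC = 2 TP / (FN + FP + 2 TP)}, in \[0, 1\]; 1 for identical masks.
#' Undefined (raises) when both masks are empty.
#'
#' @param counts List from [confusion_counts()].
#' @return DSC in \[0, 1\].
#' @export
dice <- function(counts) {
  s <- counts$tp + counts$fp + counts$fn
  cg_assert(s >= 1, "cg_error_undefined_metric",
            "DSC undefined: both masks are empty")
  2 * counts$tp / (counts$fn + counts$fp + 2 * counts$tp)
}

#' Symmetric Hausdorff distance between two masks
#'
#' Exact Euclidean Hausdorff distance between the two foreground pixel
#' sets (all foreground pixels, not boundaries):
#' \eqn{HD = \max(h(A,B), h(B,A))} with
#' \eqn{h(A,B) = \max_{a \in A} \min_{b \in B} \lVert a-b \rVert}.
#' An empty prediction leaves the distance undefined; the acceptability
#' cap is assigned instead and the result carries a `degenerate`
#' attribute. Values above the cap are returned as computed — the cap only
#' drives the acceptability flag downstream.
#'
#' @param pred,gt 2D 0/1 matrices; `gt` non-empty.
#' @param cap Acceptability cap in pixels, assigned to empty predictions.
#' @return Nonnegative distance in pixels.
#' @export
hausdorff <- function(pred, gt, cap = 60) {
  cg_assert(sum(gt) > 0, "cg_error_empty_lesion", "reference mask is empty")
  cg_assert(identical(dim(pred), dim(gt)), "cg_error_dim_mismatch",
            "prediction and reference dims differ")
  if (sum(pred) == 0) {
    return(structure(as.numeric(cap), degenerate = TRUE))
  }
  a <- which(pred == 1, arr.ind = TRUE)
  b <- which(gt == 1, arr.ind = TRUE)
  d2 <- cross_dist2(a, b)
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

# Squared Euclidean cross-distance matrix between two coordinate sets,
# chunked so that huge masks do not allocate one giant matrix.
cross_dist2 <- function(a, b, chunk = 2048L) {
  nb2 <- rowSums(b^2)
  out <- matrix(0, nrow(a), nrow(b))
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    ai <- a[idx, , drop = FALSE]
    out[idx, ] <- outer(rowSums(ai^2), nb2, "+") - 2 * tcrossprod(ai, b)
  }
  pmax(out, 0)
}

#' Relative absolute area difference
#'
#' \eqn{RAAD = ((TP+FP) - (TP+FN)) / (TP+FN)}: the signed relative
#' difference between predicted and reference lesion area. 0 is optimal;
#' negative values signal underestimation (-1 for an empty prediction),
#' positive values overestimation.
#'
#' @param counts List from [confusion_counts()].
#' @return Real number \eqn{\ge -1}.
#' @export
raad <- function(counts) {
  ref_area <- counts$tp + counts$fn
  cg_assert(ref_area >= 1, "cg_error_empty_lesion",
            "RAAD undefined: reference mask is empty")
  ((counts$tp + counts$fp) - ref_area) / ref_area
}

#' Combined Dice + binary cross-entropy training loss
#'
#' The segmentation training objective: the Dice loss (one minus the soft
#' Dice coefficient) plus the mean binary cross-entropy,
#' \deqn{L = 1 - \frac{2\sum y p}{\sum y + \sum p}
#'       + \mathrm{mean}(-(y \log p + (1-y)\log(1-p)))}
#' Predictions are clipped to \[`epsilon`, 1-`epsilon`\] so the logarithms
#' stay finite; the loss tends to 0 at a perfect prediction.
#'
#' @param y 2D 0/1 reference matrix.
#' @param p 2D matrix of predicted probabilities (same dimensions).
#' @param epsilon Clipping bound for `p`.
#' @return Nonnegative loss value.
#' @export
combined_loss <- function(y, p, epsilon = 1e-7) {
  cg_assert(identical(dim(y), dim(p)), "cg_error_dim_mismatch",
            "reference and prediction dims differ")
  cg_assert(all(is.finite(p)), "cg_error_nonfinite_prediction",
            "prediction contains non-finite values")
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  soft_dice <- 2 * sum(y * p) / (sum(y) + sum(p))
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  (1 - soft_dice) + bce
}

#' Evaluate one predicted mask against its reference
#'
#' Computes the four per-slice metrics and their acceptability flags:
#' DSC at least `dsc_min` (default 0.1, i.e. 10% overlap), Hausdorff
#' distance at most `hd_max` pixels (default 60), |RAAD| at most
#' `raad_max` (default 0.5).
#'
#' @param pred,gt 2D 0/1 matrices; `gt` non-empty.
#' @param slice_id Slice reference string.
#' @param dsc_min,hd_max,raad_max Acceptability thresholds.
#' @return One-row data.frame: `slice_id`, `detection`, `dsc`, `hd`,
#'   `hd_degenerate`, `raad`, `dsc_ok`, `hd_ok`, `raad_ok`.
#' @export
evaluate_slice <- function(pred, gt, slice_id = "slice",
                           dsc_min = 0.1, hd_max = 60, raad_max = 0.5) {
  counts <- confusion_counts(pred, gt)
  hd <- hausdorff(pred, gt, cap = hd_max)
  data.frame(
    slice_id = slice_id,
    detection = detection(pred, gt),
    dsc = dice(counts),
    hd = as.numeric(hd),
    hd_degenerate = isTRUE(attr(hd, "degenerate")),
    raad = raad(counts),
    dsc_ok = dice(counts) >= dsc_min,
    hd_ok = as.numeric(hd) <= hd_max,
    raad_ok = abs(raad(counts)) <= raad_max,
    stringsAsFactors = FALSE)
}

#' Evaluate a set of predictions
#'
#' @param samples List of [cg_slice()] references.
#' @param predictions List of 0/1 matrices, parallel to `samples`.
#' @param ... Thresholds passed to [evaluate_slice()].
#' @return data.frame with one row per slice.
#' @export
evaluate_dataset <- function(samples, predictions, ...) {
  cg_assert(length(samples) == length(predictions), "cg_error_dim_mismatch",
            "samples and predictions differ in length")
  do.call(rbind, Map(function(s, p) {
    evaluate_slice(p, s$lesion_mask, slice_id = slice_id(s), ...)
  }, samples, predictions))
}
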