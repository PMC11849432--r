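#' Desk-scale trainable baseline segmenter
#'
#' A deliberately simple segmenter that responds to training-set
#' composition and trains in seconds: hypodense lesions are darker than
#' healthy tissue, so the model fits a single global cutoff on the
#' windowed, per-slice min-max-normalized intensity. Training evaluates a
#' uniform grid of candidate cutoffs and keeps the one maximizing mean
#' training DSC (ties to the smaller cutoff); prediction thresholds the
#' normalized slice at the fitted cutoff within the retained brain mask
#' and keeps the largest connected component. Deterministic given its
#' training data; the `seed` argument exists for interface compatibility
#' with stochastic segmenters.
#'
#' @param cutoff_grid_size Number of candidate cutoffs on (0, 1).
#' @param low_hu,high_hu HU window used for normalization.
#' @return A segmenter interface: list with `fit(samples, seed)` and
#'   `predict(model, sample)`.
#' @export
baseline_segmenter <- function(cutoff_grid_size = 64, low_hu = 15,
                               high_hu = 80) {
  grid <- seq_len(cutoff_grid_size) / (cutoff_grid_size + 1)
  normalize <- function(sample) {
    tryCatch(
      window_and_normalize(sample$image, sample$brain_mask, low_hu,
                           high_hu)$normalized,
      cg_error = function(e) NULL)
  }
  segment_normalized <- function(norm, dims, cutoff) {
    empty <- matrix(0L, dims[1], dims[2])
    if (is.null(norm)) return(empty)
    cand <- (!is.na(norm) & norm <= cutoff) + 0L
    if (sum(cand) == 0) return(empty)
    labels <- EBImage::bwlabel(cand)
    sizes <- tabulate(labels[labels > 0])
    matrix(as.integer(labels == which.max(sizes)), dims[1])
  }
  list(
    fit = function(samples, seed = 1L) {
      cg_assert(length(samples) > 0, "cg_error_empty_dataset",
                "cannot fit on an empty training set")
      norms <- lapply(samples, normalize)
      mean_dsc <- vapply(grid, function(cutoff) {
        mean(vapply(seq_along(samples), function(i) {
          pred <- segment_normalized(norms[[i]], dim(samples[[i]]$image),
                                     cutoff)
          dice(confusion_counts(pred, samples[[i]]$lesion_mask))
        }, numeric(1)))
      }, numeric(1))
      list(cutoff = grid[which.max(mean_dsc)],
           mean_train_dsc = max(mean_dsc))
    },
    predict = function(model, sample) {
      segment_normalized(normalize(sample), dim(sample$image), model$cutoff)
    })
}
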