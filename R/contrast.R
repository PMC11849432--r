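#' HU windowing and per-slice normalization
#'
#' Restricts the brain to the diagnostic soft-tissue window before contrast
#' scoring: HU above `high_hu` are eliminated (skull), HU below `low_hu`
#' are discarded (cerebrospinal fluid, calcifications); the bounds
#' themselves are retained. Surviving intensities are min-max mapped to
#' \[0, 1\] over the retained set; non-retained positions are set to `NA`
#' and excluded from every downstream statistic.
#'
#' @param image 2D HU matrix.
#' @param brain_mask 2D 0/1 matrix, non-empty.
#' @param low_hu,high_hu Window bounds in HU (inclusive).
#' @return List with `normalized` (matrix, `NA` outside the retained set)
#'   and `retained_mask` (0/1 matrix).
#' @export
window_and_normalize <- function(image, brain_mask, low_hu = 15,
                                 high_hu = 80) {
  brain_mask <- as_binary_mask(brain_mask)
  cg_assert(sum(brain_mask) > 0, "cg_error_empty_brain",
            "brain mask is empty")
  retained <- brain_mask == 1L & is.finite(image) &
    image >= low_hu & image <= high_hu
  cg_assert(any(retained), "cg_error_empty_window",
            "no brain pixel survives the [%g, %g] HU window", low_hu, high_hu)
  vals <- image[retained]
  lo <- min(vals)
  hi <- max(vals)
  cg_assert(hi > lo, "cg_error_degenerate_slice",
            "retained intensities are constant (HU = %g)", lo)
  normalized <- matrix(NA_real_, nrow(image), ncol(image))
  normalized[retained] <- (vals - lo) / (hi - lo)
  list(normalized = normalized, retained_mask = retained + 0L)
}

#' Ipsilateral healthy-tissue background mask
#'
#' The Fisher's-ratio background is the healthy tissue in the hemisphere
#' containing the lesion: retained brain pixels on the lesion-centroid side
#' of the vertical midline, minus the lesion itself. The contralateral
#' hemisphere is excluded entirely.
#'
#' @param brain_mask,lesion_mask,retained_mask 2D 0/1 matrices of equal
#'   dimensions; `lesion_mask` non-empty.
#' @return 0/1 background mask.
#' @export
ipsilateral_background <- function(brain_mask, lesion_mask, retained_mask) {
  lesion_mask <- as_binary_mask(lesion_mask)
  cg_assert(sum(lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  nc <- ncol(lesion_mask)
  midline <- (nc + 1) / 2
  centroid_col <- lesion_centroid_col(lesion_mask)
  cols <- matrix(rep(seq_len(nc), each = nrow(lesion_mask)),
                 nrow(lesion_mask))
  side <- if (centroid_col <= midline) cols < midline else cols > midline
  background <- (retained_mask == 1L) & side & (lesion_mask == 0L)
  cg_assert(any(background), "cg_error_empty_background",
            "no retained ipsilateral background pixel")
  background + 0L
}

#' Region statistics for Fisher's ratio
#'
#' Mean, population variance (divisor N) and pixel count of a value
#' vector; the same estimator is used for the lesion and the background so
#' the ratio is symmetric in its two regions.
#'
#' @param values Numeric vector of (normalized) intensities.
#' @return List with `mean`, `variance`, `n`.
#' @export
region_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) return(list(mean = NA_real_, variance = NA_real_, n = 0L))
  m <- mean(values)
  list(mean = m, variance = mean((values - m)^2), n = n)
}

#' Fisher's ratio between two regions
#'
#' The squared difference of the region means divided by the sum of the
#' region variances:
#' \deqn{F = (\mu_{obj} - \mu_{bg})^2 / (\sigma^2_{obj} + \sigma^2_{bg})}
#' A scalar, scale-free contrast score: invariant under any shared affine
#' intensity map, zero when the regions are indistinguishable in mean.
#'
#' @param object_stats,background_stats Lists as returned by
#'   [region_stats()]; both regions need at least 2 pixels and a strictly
#'   positive variance sum.
#' @return Nonnegative Fisher's ratio.
#' @export
fisher_ratio <- function(object_stats, background_stats) {
  cg_assert(object_stats$n >= 2 && background_stats$n >= 2,
            "cg_error_region_too_small",
            "both regions need >= 2 pixels (got %d and %d)",
            object_stats$n, background_stats$n)
  denom <- object_stats$variance + background_stats$variance
  cg_assert(denom > 0, "cg_error_degenerate_contrast",
            "both regions are constant: variance sum is zero")
  (object_stats$mean - background_stats$mean)^2 / denom
}

#' Fisher's-ratio contrast of one slice
#'
#' Applies the HU window and per-slice normalization, builds the
#' ipsilateral background, and evaluates [fisher_ratio()] between the
#' lesion and the background on the normalized intensities. Because the
#' ratio is affine-invariant, the normalization does not alter its value;
#' it is kept so that reported region statistics live on a common scale.
#'
#' @param sample [cg_slice()].
#' @param low_hu,high_hu Window bounds (see [window_and_normalize()]).
#' @return List with `slice_id`, `fisher`, `lesion_stats`,
#'   `background_stats`, `retained_fraction`.
#' @export
slice_contrast <- function(sample, low_hu = 15, high_hu = 80) {
  wn <- window_and_normalize(sample$image, sample$brain_mask, low_hu, high_hu)
  bg <- ipsilateral_background(sample$brain_mask, sample$lesion_mask,
                               wn$retained_mask)
  lesion_vals <- wn$normalized[sample$lesion_mask == 1L &
                               wn$retained_mask == 1L]
  bg_vals <- wn$normalized[bg == 1L]
  ls <- region_stats(lesion_vals)
  bs <- region_stats(bg_vals)
  list(slice_id = slice_id(sample),
       fisher = fisher_ratio(ls, bs),
       lesion_stats = ls, background_stats = bs,
       retained_fraction = sum(wn$retained_mask) / sum(sample$brain_mask))
}

#' Contrast profile of a slice dataset
#'
#' Scores every slice with [slice_contrast()]; slices that fail windowing
#' or background construction are reported as degenerate with their
#' reason, never raised. A histogram of the Fisher's-ratio distribution is
#' returned for dataset-imbalance inspection (clinical CT datasets are
#' typically right-skewed, dominated by low-contrast slices).
#'
#' @param samples List of [cg_slice()].
#' @param low_hu,high_hu Window bounds.
#' @param bin_width Histogram bin width in Fisher's-ratio units.
#' @return List with `records` (data.frame: slice_id, fisher, region means,
#'   variances, counts, retained_fraction), `degenerate` (data.frame:
#'   slice_id, reason) and `histogram` (list: breaks, counts).
#' @export
contrast_profile <- function(samples, low_hu = 15, high_hu = 80,
                             bin_width = 0.025) {
  rec <- list()
  bad <- list()
  for (s in samples) {
    r <- tryCatch(slice_contrast(s, low_hu, high_hu),
                  cg_error = function(e) e)
    if (inherits(r, "cg_error")) {
      bad[[length(bad) + 1L]] <- data.frame(
        slice_id = slice_id(s), reason = conditionMessage(r),
        stringsAsFactors = FALSE)
    } else {
      rec[[length(rec) + 1L]] <- data.frame(
        slice_id = r$slice_id, fisher = r$fisher,
        lesion_mean = r$lesion_stats$mean,
        lesion_var = r$lesion_stats$variance,
        lesion_n = r$lesion_stats$n,
        background_mean = r$background_stats$mean,
        background_var = r$background_stats$variance,
        background_n = r$background_stats$n,
        retained_fraction = r$retained_fraction,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(slice_id = character(), fisher = numeric())
  degenerate <- if (length(bad)) do.call(rbind, bad) else
    data.frame(slice_id = character(), reason = character())
  histogram <- fisher_histogram(records$fisher, bin_width)
  list(records = records, degenerate = degenerate, histogram = histogram)
}

#' Histogram of a Fisher's-ratio distribution
#'
#' Fixed-width bins from zero to just past the observed maximum.
#'
#' @param fisher Numeric vector of Fisher's ratios.
#' @param bin_width Bin width.
#' @return List with `breaks` and `counts`.
#' @export
fisher_histogram <- function(fisher, bin_width = 0.025) {
  if (length(fisher) == 0) {
    return(list(breaks = numeric(), counts = integer()))
  }
  top <- max(bin_width, ceiling(max(fisher) / bin_width) * bin_width)
  breaks <- seq(0, top, by = bin_width)
  h <- graphics::hist(fisher, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}
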