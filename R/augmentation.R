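# Lesion interior under 8-adjacency: lesion pixels none of whose 8
# neighbours (image border counts as outside) leave the lesion.
lesion_interior <- function(lesion_mask) {
  padded <- matrix(0L, nrow(lesion_mask) + 2L, ncol(lesion_mask) + 2L)
  padded[2:(nrow(lesion_mask) + 1L), 2:(ncol(lesion_mask) + 1L)] <- lesion_mask
  interior <- EBImage::erode(padded, matrix(1L, 3L, 3L))
  matrix(as.integer(interior[2:(nrow(lesion_mask) + 1L),
                             2:(ncol(lesion_mask) + 1L)]),
         nrow(lesion_mask))
}

#' Iterative lesion darkening
#'
#' First augmentation step: the lesion interior is darkened by `step_hu`
#' HU per round, cumulatively over `rounds` rounds, while the one-pixel
#' border ring of the lesion (lesion pixels 8-adjacent to non-lesion)
#' stays unchanged in every round — a smooth gradient that avoids a sharp
#' step at the lesion edge. Masks and all non-lesion pixels are untouched.
#'
#' @param sample [cg_slice()] with a non-empty lesion.
#' @param step_hu HU reduction per round.
#' @param rounds Number of cumulative rounds; 0 yields an empty list.
#' @return List of [cg_slice()], one per round (round k darkened by
#'   `k * step_hu`); an empty list with attribute `reason` when the lesion
#'   has no interior (all pixels on the border ring).
#' @export
darken_lesion <- function(sample, step_hu = 2, rounds = 3) {
  cg_assert(sum(sample$lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  if (rounds < 1) return(list())
  interior <- lesion_interior(sample$lesion_mask)
  if (sum(interior) == 0) {
    return(structure(list(), reason = "lesion has no interior"))
  }
  lapply(seq_len(rounds), function(k) {
    img <- sample$image
    img[interior == 1L] <- img[interior == 1L] - k * step_hu
    cg_slice(img, sample$brain_mask, sample$lesion_mask,
             sample$patient_id, sample$slice_index, sample$spacing,
             tag = paste0(sub("^$", "aug", sample$tag), "d", k))
  })
}

#' Lesion homogenization
#'
#' Second augmentation step, applied selectively to slices whose lesion
#' intensity spreads more than the healthy tissue (population SD of lesion
#' HU strictly greater than that of the non-lesion brain): lesion pixels
#' strictly below the lesion HU median are raised by `delta_hu`, pixels
#' strictly above it lowered by `delta_hu`, median-valued pixels left
#' unchanged — equalizing the appearance of inhomogeneous lesions without
#' ever increasing lesion variance.
#'
#' @param sample [cg_slice()] with a non-empty lesion.
#' @param delta_hu HU shift toward the median.
#' @return List with `sample` (modified or original [cg_slice()]) and
#'   `applied` (logical: whether the selection gate passed).
#' @export
homogenize_lesion <- function(sample, delta_hu = 2) {
  cg_assert(sum(sample$lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  lesion_vals <- sample$image[sample$lesion_mask == 1L]
  bg_vals <- sample$image[sample$brain_mask == 1L & sample$lesion_mask == 0L]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (length(bg_vals) == 0 || pop_sd(lesion_vals) <= pop_sd(bg_vals)) {
    return(list(sample = sample, applied = FALSE))
  }
  med <- stats::median(lesion_vals)
  img <- sample$image
  les <- sample$lesion_mask == 1L
  img[les & img < med] <- img[les & img < med] + delta_hu
  img[les & img > med] <- img[les & img > med] - delta_hu
  out <- cg_slice(img, sample$brain_mask, sample$lesion_mask,
                  sample$patient_id, sample$slice_index, sample$spacing,
                  tag = paste0(sub("^$", "aug", sample$tag), "h"))
  list(sample = out, applied = TRUE)
}

#' Contrast-targeted dataset augmentation with Fisher-guided acceptance
#'
#' For every input slice, candidate augmentations are generated — the
#' cumulative darkening rounds, homogenization of the original (when its
#' gate passes), and optionally homogenization composed onto each darkened
#' round (darkening first, then homogenization) — and each candidate's
#' Fisher's ratio is recomputed through the contrast module. Only
#' candidates whose contrast lies within `[accept_min_f, accept_max_f]`
#' are retained, keeping augmented contrast inside the range observed in
#' the original dataset and excluding overly low-contrast products (those
#' slices are already well-represented). Originals are always kept.
#'
#' @param samples List of [cg_slice()].
#' @param contrast_records data.frame from [contrast_profile()]`$records`
#'   for `samples`; used for the default acceptance band.
#' @param accept_min_f Acceptance floor; defaults to the `floor_quantile`
#'   of the original Fisher distribution.
#' @param accept_max_f Acceptance ceiling; defaults to the observed
#'   maximum.
#' @param floor_quantile Quantile defining the default floor.
#' @param step_hu,rounds Darkening parameters ([darken_lesion()]).
#' @param delta_hu Homogenization shift ([homogenize_lesion()]).
#' @param compose Also emit homogenization composed onto darkened rounds.
#' @param low_hu,high_hu Window bounds for contrast recomputation.
#' @return List with `samples` (originals followed by accepted candidates),
#'   `fisher` (their Fisher's ratios, parallel), and `report` (data.frame
#'   per source slice: candidates generated / kept / rejected).
#' @export
augment_dataset <- function(samples, contrast_records,
                            accept_min_f = NULL, accept_max_f = NULL,
                            floor_quantile = 0.5,
                            step_hu = 2, rounds = 3, delta_hu = 2,
                            compose = TRUE, low_hu = 15, high_hu = 80) {
  cg_assert(length(samples) > 0, "cg_error_empty_dataset",
            "sample list is empty")
  if (is.null(accept_max_f)) accept_max_f <- max(contrast_records$fisher)
  if (is.null(accept_min_f)) {
    accept_min_f <- unname(stats::quantile(contrast_records$fisher,
                                           floor_quantile))
  }
  cg_assert(accept_min_f < accept_max_f, "cg_error_bad_acceptance_band",
            "accept_min_f (%g) must be below accept_max_f (%g)",
            accept_min_f, accept_max_f)
  fisher_of <- function(s) {
    tryCatch(slice_contrast(s, low_hu, high_hu)$fisher,
             cg_error = function(e) NA_real_)
  }
  out_samples <- list()
  out_fisher <- numeric()
  report <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    darkened <- darken_lesion(s, step_hu = step_hu, rounds = rounds)
    candidates <- darkened
    hom <- homogenize_lesion(s, delta_hu = delta_hu)
    if (hom$applied) candidates <- c(candidates, list(hom$sample))
    if (compose) {
      for (d in darkened) {
        hd <- homogenize_lesion(d, delta_hu = delta_hu)
        if (hd$applied) candidates <- c(candidates, list(hd$sample))
      }
    }
    f_cand <- vapply(candidates, fisher_of, numeric(1))
    keep <- !is.na(f_cand) & f_cand >= accept_min_f & f_cand <= accept_max_f
    out_samples <- c(out_samples, list(s), candidates[keep])
    f_orig <- contrast_records$fisher[match(slice_id(s),
                                            contrast_records$slice_id)]
    if (is.na(f_orig)) f_orig <- fisher_of(s)
    out_fisher <- c(out_fisher, f_orig, f_cand[keep])
    report[[i]] <- data.frame(
      slice_id = slice_id(s), generated = length(candidates),
      kept = sum(keep), rejected = sum(!keep), stringsAsFactors = FALSE)
  }
  list(samples = out_samples, fisher = out_fisher,
       report = do.call(rbind, report),
       accept_min_f = accept_min_f, accept_max_f = accept_max_f)
}
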