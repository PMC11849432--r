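#' Extract lesion-bearing axial slices from a volume pair
#'
#' Walks the volume along its last axis and keeps every slice whose lesion
#' area strictly exceeds `min_area_cm2` (small lesions cannot be reliably
#' segmented on CT). Lesion area is pixel count times the in-plane pixel
#' area at native resolution, before any resizing. The brain mask is taken
#' as the support of the skull-stripped image: pixels with finite, nonzero
#' HU (unioned with the lesion, which is brain tissue by definition).
#'
#' @param image,mask [cg_volume()] pair sharing dimensions and spacing;
#'   `mask` must be binary (see [read_volume_pair()]).
#' @param min_area_cm2 Minimum lesion area in cm2 (strict inequality).
#' @return List of [cg_slice()] objects, possibly empty.
#' @export
extract_lesion_slices <- function(image, mask, min_area_cm2 = 1.0) {
  cg_assert(identical(dim(image$intensities), dim(mask$intensities)),
            "cg_error_dim_mismatch", "image and mask dims differ")
  cg_assert(all(is.finite(image$spacing)) && all(image$spacing > 0),
            "cg_error_bad_spacing", "volume spacing missing or nonpositive")
  px_area_mm2 <- image$spacing[1] * image$spacing[2]
  out <- list()
  for (k in seq_len(dim(image$intensities)[3])) {
    lesion <- (mask$intensities[, , k] > 0) + 0L
    area_mm2 <- sum(lesion) * px_area_mm2
    if (area_mm2 <= min_area_cm2 * 100) next
    img <- image$intensities[, , k]
    brain <- ((is.finite(img) & img != 0) | lesion == 1L) + 0L
    out[[length(out) + 1L]] <- cg_slice(
      image = img, brain_mask = brain, lesion_mask = lesion,
      patient_id = image$identity, slice_index = k,
      spacing = image$spacing[1:2])
  }
  out
}

#' Harmonize lesion laterality and resize a slice
#'
#' If the lesion-mask centroid falls in the non-reference hemisphere
#' (relative to the image's vertical midline), the image and both masks are
#' mirrored horizontally so all lesions share one hemisphere — a consistent
#' position prior for training. All three grids are then resized to
#' `target_side` x `target_side`: the image by bilinear interpolation,
#' masks by nearest neighbour (preserving binarity), and the pixel spacing
#' is rescaled accordingly.
#'
#' @param sample [cg_slice()] with a non-empty lesion mask.
#' @param target_side Output side length in pixels.
#' @param reference_hemisphere `"left"` (low column indices) or `"right"`.
#' @return The harmonized, resized [cg_slice()].
#' @export
harmonize_and_resize <- function(sample, target_side = 192,
                                 reference_hemisphere = c("left", "right")) {
  reference_hemisphere <- match.arg(reference_hemisphere)
  cg_assert(sum(sample$lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  ncol_img <- ncol(sample$image)
  centroid_col <- mean(which(sample$lesion_mask == 1L, arr.ind = TRUE)[, 2])
  midline <- (ncol_img + 1) / 2
  on_left <- centroid_col <= midline
  flip <- (reference_hemisphere == "left") != on_left
  img <- sample$image
  brain <- sample$brain_mask
  lesion <- sample$lesion_mask
  if (flip) {
    img <- img[, ncol_img:1, drop = FALSE]
    brain <- brain[, ncol_img:1, drop = FALSE]
    lesion <- lesion[, ncol_img:1, drop = FALSE]
  }
  d0 <- dim(img)
  img <- EBImage::resize(img, w = target_side, h = target_side,
                         filter = "bilinear")
  brain <- EBImage::resize(brain, w = target_side, h = target_side,
                           filter = "none")
  lesion <- EBImage::resize(lesion, w = target_side, h = target_side,
                            filter = "none")
  # nearest-neighbour resampling can leave stray lesion pixels on resized
  # brain boundary positions; brain support follows the lesion by definition
  brain[lesion == 1] <- 1
  cg_slice(image = matrix(as.numeric(img), target_side),
           brain_mask = matrix(as.integer(brain), target_side),
           lesion_mask = matrix(as.integer(lesion), target_side),
           patient_id = sample$patient_id,
           slice_index = sample$slice_index,
           spacing = sample$spacing * d0 / target_side,
           tag = sample$tag)
}

# Column of the lesion centroid and the hemisphere it falls in.
lesion_centroid_col <- function(lesion_mask) {
  cg_assert(sum(lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  mean(which(lesion_mask == 1L, arr.ind = TRUE)[, 2])
}
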