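#' Construct a CT volume
#'
#' A minimal container for a 3D image: a numeric array of Hounsfield-unit
#' intensities, per-axis voxel spacing in millimetres, and a patient
#' identifier. Axial slices are taken along the third (last) axis
#' throughout the package.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing Numeric vector of length 3, voxel size in mm per axis;
#'   all entries must be strictly positive and finite.
#' @param identity Patient identifier string.
#' @return An object of class `cg_volume`.
#' @export
cg_volume <- function(intensities, spacing, identity = "unknown") {
  cg_assert(is.array(intensities) && length(dim(intensities)) == 3,
            "cg_error_not_3d", "intensities must be a 3D array")
  cg_assert(all(dim(intensities) >= 1), "cg_error_not_3d",
            "every axis must have length >= 1")
  spacing <- as.numeric(spacing)
  cg_assert(length(spacing) == 3 && all(is.finite(spacing)) && all(spacing > 0),
            "cg_error_bad_spacing",
            "spacing must be 3 strictly positive finite values")
  structure(list(intensities = intensities, spacing = spacing,
                 identity = as.character(identity)),
            class = "cg_volume")
}

#' Construct a 2D slice sample
#'
#' One axial slice: the HU image, a brain mask (support of brain tissue), a
#' lesion mask, identity metadata and in-plane pixel spacing. Invariants
#' enforced: all three grids share dimensions, masks are strictly 0/1, and
#' the lesion mask is a subset of the brain mask.
#'
#' @param image 2D numeric matrix of HU values.
#' @param brain_mask,lesion_mask 2D 0/1 matrices of the same dimensions as
#'   `image`.
#' @param patient_id Patient identifier string.
#' @param slice_index Integer index of the slice within its volume.
#' @param spacing Numeric length-2 in-plane pixel size in mm.
#' @param tag Optional suffix distinguishing derived slices (e.g.
#'   augmentation products) from their source; empty for originals.
#' @return An object of class `cg_slice`.
#' @export
cg_slice <- function(image, brain_mask, lesion_mask, patient_id,
                     slice_index, spacing, tag = "") {
  cg_assert(is.matrix(image), "cg_error_bad_slice", "image must be a matrix")
  cg_assert(identical(dim(image), dim(brain_mask)) &&
            identical(dim(image), dim(lesion_mask)),
            "cg_error_dim_mismatch",
            "image, brain_mask and lesion_mask must share dimensions")
  brain_mask <- as_binary_mask(brain_mask)
  lesion_mask <- as_binary_mask(lesion_mask)
  cg_assert(!any(lesion_mask == 1L & brain_mask == 0L),
            "cg_error_mask_subset", "lesion_mask must be a subset of brain_mask")
  spacing <- as.numeric(spacing)
  cg_assert(length(spacing) == 2 && all(is.finite(spacing)) && all(spacing > 0),
            "cg_error_bad_spacing",
            "spacing must be 2 strictly positive finite values")
  structure(list(image = image, brain_mask = brain_mask,
                 lesion_mask = lesion_mask,
                 patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index),
                 spacing = spacing, tag = as.character(tag)),
            class = "cg_slice")
}

# Coerce a matrix to an integer 0/1 mask; values must already be in {0,1}
# up to numeric fuzz (masks read from float containers are binarized
# upstream at 0.5).
as_binary_mask <- function(m) {
  cg_assert(is.matrix(m), "cg_error_bad_slice", "mask must be a matrix")
  v <- as.numeric(m)
  cg_assert(all(v %in% c(0, 1)), "cg_error_mask_not_binary",
            "mask values must be exactly 0 or 1")
  matrix(as.integer(v), nrow = nrow(m))
}

#' @export
print.cg_slice <- function(x, ...) {
  cat(sprintf("<cg_slice> %s #%d  %dx%d px  spacing %.3gx%.3g mm  lesion %d px\n",
              x$patient_id, x$slice_index, nrow(x$image), ncol(x$image),
              x$spacing[1], x$spacing[2], sum(x$lesion_mask)))
  invisible(x)
}

#' @export
print.cg_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<cg_volume> %s  %dx%dx%d  spacing %.3gx%.3gx%.3g mm\n",
              x$identity, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

slice_id <- function(sample) {
  base <- sprintf("%s_%04d", sample$patient_id, sample$slice_index)
  if (!is.null(sample$tag) && nzchar(sample$tag)) {
    base <- paste(base, sample$tag, sep = "_")
  }
  base
}
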