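#' Read a NIfTI image/mask pair
#'
#' Loads a 3D image volume and its binary lesion mask from NIfTI files,
#' checks that their grids match, and binarizes the mask at 0.5 (masks are
#' often stored as floats after resampling).
#'
#' @param image_path,mask_path Paths to `.nii` / `.nii.gz` files.
#' @param identity Patient identifier; defaults to the image file stem.
#' @return A list with elements `image` and `mask`, both [cg_volume()]
#'   objects with identical dimensions and spacing; the mask volume
#'   contains only 0/1.
#' @export
read_volume_pair <- function(image_path, mask_path, identity = NULL) {
  img <- read_nifti_volume(image_path, identity)
  msk <- read_nifti_volume(mask_path, identity)
  cg_assert(identical(dim(img$intensities), dim(msk$intensities)),
            "cg_error_dim_mismatch",
            "image dims (%s) != mask dims (%s)",
            paste(dim(img$intensities), collapse = "x"),
            paste(dim(msk$intensities), collapse = "x"))
  msk$intensities <- (msk$intensities > 0.5) + 0
  list(image = img, mask = msk)
}

read_nifti_volume <- function(path, identity = NULL) {
  cg_assert(file.exists(path), "cg_error_unreadable_file",
            "file does not exist: %s", path)
  arr <- tryCatch(RNifti::readNifti(path),
                  error = function(e) cg_abort("cg_error_unreadable_file",
                                               "cannot read %s: %s",
                                               path, conditionMessage(e)))
  cg_assert(length(dim(arr)) == 3, "cg_error_not_3d",
            "%s is not a 3D volume (dims: %s)", path,
            paste(dim(arr), collapse = "x"))
  spacing <- RNifti::pixdim(arr)[seq_len(3)]
  if (is.null(identity)) {
    identity <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  cg_volume(array(as.numeric(arr), dim = dim(arr)), spacing, identity)
}

#' Write a slice dataset with a CSV manifest
#'
#' Persists each slice (image + brain mask + lesion mask + metadata) as one
#' compressed RDS container and writes a single `manifest.csv` describing
#' the dataset, so every downstream stage is file-driven. Reloading with
#' [read_slice_dataset()] reproduces bit-identical arrays and metadata.
#'
#' @param samples Non-empty list of [cg_slice()] objects with unique ids.
#' @param directory Output directory (created if missing).
#' @param split Optional character vector (`"train"`/`"test"`), one per
#'   sample; checked for patient-level disjointness.
#' @param fisher Optional numeric vector of per-slice Fisher's ratios.
#' @return The manifest as a data.frame (invisibly written to
#'   `manifest.csv` in `directory`), with columns `slice_file`, `slice_id`,
#'   `patient_id`, `slice_index`, `area_cm2`, `fisher`, `split`.
#' @export
write_slice_dataset <- function(samples, directory, split = NULL,
                                fisher = NULL) {
  cg_assert(length(samples) > 0, "cg_error_empty_dataset",
            "sample list is empty")
  ids <- vapply(samples, slice_id, character(1))
  cg_assert(!anyDuplicated(ids), "cg_error_duplicate_slice",
            "duplicate slice references: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(split)) split <- rep(NA_character_, length(samples))
  cg_assert(all(is.na(split) | split %in% c("train", "test")),
            "cg_error_bad_split", "split labels must be train/test")
  if (is.null(fisher)) fisher <- rep(NA_real_, length(samples))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(ids, ".rds")
  for (i in seq_along(samples)) {
    saveRDS(samples[[i]], file.path(directory, files[i]))
  }
  manifest <- data.frame(
    slice_file = files,
    slice_id = ids,
    patient_id = vapply(samples, function(s) s$patient_id, character(1)),
    slice_index = vapply(samples, function(s) s$slice_index, integer(1)),
    area_cm2 = vapply(samples, function(s) {
      sum(s$lesion_mask) * prod(s$spacing) / 100
    }, numeric(1)),
    fisher = as.numeric(fisher),
    split = split,
    stringsAsFactors = FALSE)
  check_patient_split(manifest)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a slice dataset written by [write_slice_dataset()]
#'
#' @param directory Dataset directory containing `manifest.csv`.
#' @return A list with `samples` (list of [cg_slice()]) and `manifest`
#'   (data.frame).
#' @export
read_slice_dataset <- function(directory) {
  path <- file.path(directory, "manifest.csv")
  cg_assert(file.exists(path), "cg_error_unreadable_file",
            "no manifest.csv in %s", directory)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(split = "character"))
  cg_assert(!anyDuplicated(manifest$slice_file), "cg_error_duplicate_slice",
            "manifest contains duplicate slice references")
  samples <- lapply(manifest$slice_file, function(f) {
    readRDS(file.path(directory, f))
  })
  list(samples = samples, manifest = manifest)
}

# Patient-level split invariant: no patient id in both train and test.
check_patient_split <- function(manifest) {
  tr <- unique(manifest$patient_id[!is.na(manifest$split) &
                                   manifest$split == "train"])
  te <- unique(manifest$patient_id[!is.na(manifest$split) &
                                   manifest$split == "test"])
  bad <- intersect(tr, te)
  cg_assert(length(bad) == 0, "cg_error_patient_leak",
            "patients in both train and test: %s",
            paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Assign a patient-level train/test split
#'
#' Whole patients (never individual slices) are assigned to the test set,
#' preserving test-set independence. Patients are shuffled with the given
#' seed and moved to the test side until the requested fraction of patients
#' is reached (at least one patient on each side).
#'
#' @param manifest Manifest data.frame from [write_slice_dataset()].
#' @param test_fraction Fraction of patients assigned to the test split.
#' @param seed Integer seed controlling the shuffle.
#' @return The manifest with its `split` column filled.
#' @export
assign_patient_split <- function(manifest, test_fraction = 0.2, seed = 1) {
  patients <- sort(unique(manifest$patient_id))
  cg_assert(length(patients) >= 2, "cg_error_bad_split",
            "need at least 2 patients to split")
  n_test <- max(1L, min(length(patients) - 1L,
                        round(test_fraction * length(patients))))
  shuffled <- with_local_seed(seed, sample(patients))
  test_patients <- shuffled[seq_len(n_test)]
  manifest$split <- ifelse(manifest$patient_id %in% test_patients,
                           "test", "train")
  check_patient_split(manifest)
  manifest
}

# Run code under a local RNG state; the caller's RNG is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
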