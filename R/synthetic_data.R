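#' Phantom generator configuration
#'
#' Parameters of the CT-like 2D brain phantom: an elliptical brain filled
#' with Gaussian-distributed soft-tissue intensities (CT grey matter sits
#' around 35 HU with a few HU of noise) and a connected hypodense lesion
#' blob whose mean deficit is solved from the requested Fisher's ratio.
#' Lesion and background share the same variance by default, matching the
#' equal-variance assumption under which Fisher's ratio is used.
#'
#' @param side Image side in pixels.
#' @param brain_axes Ellipse semi-axes as fractions of `side` (rows, cols).
#' @param background_mean_hu,background_sd_hu Healthy-tissue HU
#'   distribution.
#' @param lesion_sd_hu Lesion HU standard deviation; defaults to the
#'   background SD.
#' @param lesion_radius_range Disk radius interval (pixels) for the lesion
#'   blob.
#' @param spacing In-plane pixel size in mm.
#' @return List of class `cg_phantom_config`.
#' @export
phantom_config <- function(side = 192, brain_axes = c(0.38, 0.44),
                           background_mean_hu = 35, background_sd_hu = 4,
                           lesion_sd_hu = background_sd_hu,
                           lesion_radius_range = c(6, 12),
                           spacing = c(1, 1)) {
  cg_assert(all(brain_axes > 0) && all(brain_axes < 0.5),
            "cg_error_bad_config", "brain axes must be in (0, 0.5)")
  cg_assert(background_sd_hu > 0 && lesion_sd_hu > 0, "cg_error_bad_config",
            "intensity SDs must be positive")
  cg_assert(lesion_radius_range[1] >= 2 &&
            lesion_radius_range[2] < side * min(brain_axes) / 2,
            "cg_error_bad_config", "lesion radius range must fit the brain")
  structure(list(side = side, brain_axes = brain_axes,
                 background_mean_hu = background_mean_hu,
                 background_sd_hu = background_sd_hu,
                 lesion_sd_hu = lesion_sd_hu,
                 lesion_radius_range = lesion_radius_range,
                 spacing = spacing),
            class = "cg_phantom_config")
}

# 0/1 ellipse mask centered in a side x side grid, semi-axes in pixels.
ellipse_mask <- function(side, semi_r, semi_c) {
  ctr <- (side + 1) / 2
  r <- matrix(seq_len(side), side, side)
  c <- t(r)
  ((r - ctr)^2 / semi_r^2 + (c - ctr)^2 / semi_c^2 <= 1) + 0L
}

disk_mask <- function(side, center_r, center_c, radius) {
  r <- matrix(seq_len(side), side, side)
  c <- t(r)
  ((r - center_r)^2 + (c - center_c)^2 <= radius^2) + 0L
}

#' Generate one phantom slice with a planted Fisher's-ratio contrast
#'
#' Builds an elliptical brain with background HU ~
#' Normal(`background_mean_hu`, `background_sd_hu`^2), plants a connected
#' hypodense lesion (union of random disks, confined to one randomly
#' chosen hemisphere) with mean deficit `delta = sqrt(target_f * (s_l^2 +
#' s_b^2))` solving the Fisher formula in expectation, then calibrates the
#' lesion mean so that the contrast measured through the real contrast
#' module ([slice_contrast()]) matches `target_f` — the generator is
#' audited by the scorer it feeds, not by its own internals.
#'
#' @param config [phantom_config()].
#' @param target_f Requested Fisher's ratio (>= 0).
#' @param seed Integer seed; a fixed seed reproduces the slice bit for
#'   bit.
#' @param patient_id,slice_index Identity metadata for the emitted slice.
#' @param low_hu,high_hu Window bounds used when measuring the achieved
#'   contrast.
#' @return List with `sample` ([cg_slice()]), `target_f` and `achieved_f`.
#' @export
generate_phantom_slice <- function(config, target_f, seed,
                                   patient_id = "SYN", slice_index = 1L,
                                   low_hu = 15, high_hu = 80) {
  cg_assert(target_f >= 0, "cg_error_infeasible_target",
            "target_f must be nonnegative")
  delta <- sqrt(target_f * (config$lesion_sd_hu^2 + config$background_sd_hu^2))
  cg_assert(config$background_mean_hu - delta >=
            low_hu + 2 * config$lesion_sd_hu / sqrt(200),
            "cg_error_infeasible_target",
            "target_f %.3g pushes the lesion mean below the HU window",
            target_f)
  side <- config$side
  with_local_seed(seed, {
    brain <- ellipse_mask(side, config$brain_axes[1] * side,
                          config$brain_axes[2] * side)
    # lesion blob: union of disks seeded inside one hemisphere, clipped to
    # an inner ellipse so the lesion stays strictly within the brain
    inner <- ellipse_mask(side, config$brain_axes[1] * side * 0.85,
                          config$brain_axes[2] * side * 0.85)
    hemi_sign <- sample(c(-1, 1), 1)
    ctr <- (side + 1) / 2
    r0 <- ctr + stats::runif(1, -0.4, 0.4) * config$brain_axes[1] * side
    c0 <- ctr + hemi_sign * stats::runif(1, 0.25, 0.7) *
      config$brain_axes[2] * side
    radii <- stats::runif(3, config$lesion_radius_range[1],
                          config$lesion_radius_range[2])
    lesion <- disk_mask(side, r0, c0, radii[1])
    for (j in 2:3) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0, radii[1])
      lesion <- lesion | disk_mask(side, r0 + off * cos(ang),
                                   c0 + off * sin(ang), radii[j])
    }
    # keep the blob in its hemisphere: clip at the midline
    cols <- t(matrix(seq_len(side), side, side))
    lesion <- lesion & inner == 1L &
      (if (hemi_sign > 0) cols > ctr else cols < ctr)
    lesion <- lesion + 0L
    image <- matrix(0, side, side)
    n_brain <- sum(brain)
    image[brain == 1L] <- stats::rnorm(n_brain, config$background_mean_hu,
                                       config$background_sd_hu)
    n_lesion <- sum(lesion)
    image[lesion == 1L] <- stats::rnorm(n_lesion,
                                        config$background_mean_hu - delta,
                                        config$lesion_sd_hu)
    sample <- cg_slice(image, brain, lesion, patient_id, slice_index,
                       config$spacing)
    # calibrate the lesion mean so the measured F hits the target exactly
    # (windowing can only perturb it at the distribution tails)
    for (iter in 1:2) {
      wn <- window_and_normalize(sample$image, sample$brain_mask,
                                 low_hu, high_hu)
      bg <- ipsilateral_background(sample$brain_mask, sample$lesion_mask,
                                   wn$retained_mask)
      les_idx <- sample$lesion_mask == 1L & wn$retained_mask == 1L
      ls <- region_stats(sample$image[les_idx])
      bs <- region_stats(sample$image[bg == 1L])
      target_mean <- bs$mean - sqrt(target_f * (ls$variance + bs$variance))
      img <- sample$image
      img[sample$lesion_mask == 1L] <-
        img[sample$lesion_mask == 1L] + (target_mean - ls$mean)
      sample <- cg_slice(img, sample$brain_mask, sample$lesion_mask,
                         sample$patient_id, sample$slice_index,
                         sample$spacing)
    }
    achieved <- slice_contrast(sample, low_hu, high_hu)$fisher
    list(sample = sample, target_f = target_f, achieved_f = achieved)
  })
}

#' Generate a synthetic slice dataset
#'
#' Draws per-slice Fisher's-ratio targets from a configurable
#' distribution, generates one phantom per target with a deterministic
#' per-slice seed, and assigns slices round-robin to synthetic patients.
#' The default `"skewed"` distribution is exponential-like (mean 0.06,
#' resampled above `f_cap`), mimicking the strong predominance of very
#' low-contrast slices in clinical CT datasets; `"uniform"` mimics a
#' contrast-balanced test split.
#'
#' @param config [phantom_config()].
#' @param n_slices,n_patients Dataset size; `n_slices >= n_patients >= 1`.
#' @param seed Integer base seed.
#' @param distribution `"skewed"`, `"uniform"` or `"fixed"`.
#' @param rate_mean Mean of the skewed (exponential) distribution.
#' @param uniform_range Range of the uniform distribution.
#' @param fixed_values Target values recycled over slices for `"fixed"`.
#' @param f_cap Upper truncation for drawn targets.
#' @return List with `samples` (list of [cg_slice()]) and `truth`
#'   (data.frame: `slice_id`, `patient_id`, `target_f`, `achieved_f`).
#' @export
generate_synthetic_dataset <- function(config, n_slices, n_patients, seed,
                                       distribution = c("skewed", "uniform",
                                                        "fixed"),
                                       rate_mean = 0.06,
                                       uniform_range = c(0.005, 0.3),
                                       fixed_values = NULL, f_cap = 0.5) {
  distribution <- match.arg(distribution)
  cg_assert(n_slices >= n_patients && n_patients >= 1, "cg_error_bad_config",
            "need n_slices >= n_patients >= 1")
  targets <- with_local_seed(seed, switch(distribution,
    skewed = {
      x <- stats::rexp(n_slices, rate = 1 / rate_mean)
      while (any(x > f_cap)) {
        x[x > f_cap] <- stats::rexp(sum(x > f_cap), rate = 1 / rate_mean)
      }
      x
    },
    uniform = stats::runif(n_slices, uniform_range[1], uniform_range[2]),
    fixed = {
      cg_assert(length(fixed_values) > 0, "cg_error_bad_config",
                "fixed distribution needs fixed_values")
      rep_len(fixed_values, n_slices)
    }))
  samples <- vector("list", n_slices)
  truth <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    patient <- sprintf("P%03d", ((i - 1L) %% n_patients) + 1L)
    idx <- ((i - 1L) %/% n_patients) + 1L
    g <- generate_phantom_slice(config, targets[i],
                                seed = derive_seed(seed, i),
                                patient_id = patient, slice_index = idx)
    samples[[i]] <- g$sample
    truth[[i]] <- data.frame(slice_id = slice_id(g$sample),
                             patient_id = patient,
                             target_f = g$target_f,
                             achieved_f = g$achieved_f,
                             stringsAsFactors = FALSE)
  }
  list(samples = samples, truth = do.call(rbind, truth))
}

# Deterministic stream of per-item seeds below 2^31.
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 7919 + i * 104729) %% 2147483647)
}

#' Surrogate segmenter configuration
#'
#' Parameters of the contrast-sensitive surrogate: a known
#' performance-vs-contrast law with a planted cliff at
#' `critical_contrast`. Target quality follows a logistic curve from
#' `dsc_floor` to `dsc_ceiling` centred on the cliff; detection
#' probability follows the same curve from `detection_floor` to 1. The
#' default steepness makes the transition width a few hundredths of a
#' Fisher's-ratio unit — a genuine cliff, so that threshold recovery is a
#' well-posed estimation problem.
#'
#' The default noise level, detection floor and area-bias slope are
#' calibrated so that the emitted predictions reproduce the magnitudes
#' reported for clinical stroke CT: per-bin DSC scatter of roughly 0.1,
#' detection failures concentrated but not exclusive below the cliff,
#' two-cluster silhouettes near 0.6 with purities near 0.8, and lesion
#' area drifting from underestimation at low contrast to overestimation
#' at high contrast (which is what makes the pixel false-positive rate
#' grow as the contrast threshold tightens).
#'
#' @param critical_contrast Planted critical contrast c*.
#' @param steepness Logistic steepness (per Fisher's-ratio unit) of the
#'   mean-quality cliff.
#' @param dsc_floor,dsc_ceiling DSC plateau below / above the cliff.
#' @param detection_floor Detection probability far below the cliff.
#' @param detection_steepness Logistic steepness of the detection curve;
#'   softer than the quality cliff by default, so occasional detection
#'   failures persist above the cliff as observed clinically.
#' @param noise_sd SD of the Gaussian jitter added to the DSC target
#'   (per-slice quality scatter).
#' @param area_bias Logistic slope (in F - c*) of the lesion-area bias
#'   trend from `raad_low` to `raad_high`.
#' @param area_bias_shift Optional leftward shift of the area-bias
#'   transition centre relative to the cliff (0 centres it on the
#'   cliff).
#' @param raad_low,raad_high Mean RAAD target far below / far above the
#'   cliff: low-contrast lesions are underestimated, high-contrast ones
#'   overestimated, which is what makes the pixel false-positive rate
#'   grow as the contrast threshold tightens.
#' @param raad_noise SD of the per-slice jitter on the RAAD target.
#' @param miss_blob_prob On detection failure, probability of emitting a
#'   disjoint false blob in another brain region instead of an empty
#'   mask (the failure mode that motivates the Hausdorff acceptability
#'   cap).
#' @return List of class `cg_surrogate_config`.
#' @export
surrogate_config <- function(critical_contrast = 0.05, steepness = 300,
                             dsc_floor = 0.05, dsc_ceiling = 0.75,
                             detection_floor = 0.4,
                             detection_steepness = steepness,
                             noise_sd = 0.3, area_bias = 60,
                             area_bias_shift = 0,
                             raad_low = -0.6, raad_high = 0.5,
                             raad_noise = 0.15, miss_blob_prob = 0.3) {
  cg_assert(critical_contrast > 0, "cg_error_bad_config",
            "critical_contrast must be positive")
  cg_assert(dsc_floor < dsc_ceiling, "cg_error_bad_config",
            "dsc_floor must be below dsc_ceiling")
  cg_assert(noise_sd >= 0 && steepness > 0, "cg_error_bad_config",
            "noise_sd must be >= 0 and steepness > 0")
  structure(list(critical_contrast = critical_contrast,
                 steepness = steepness, dsc_floor = dsc_floor,
                 dsc_ceiling = dsc_ceiling,
                 detection_floor = detection_floor,
                 detection_steepness = detection_steepness,
                 noise_sd = noise_sd, area_bias = area_bias,
                 area_bias_shift = area_bias_shift,
                 raad_low = raad_low, raad_high = raad_high,
                 raad_noise = raad_noise, miss_blob_prob = miss_blob_prob),
            class = "cg_surrogate_config")
}

# Shift a 0/1 matrix by (dr, dc), dropping pixels pushed off the grid.
shift_mask <- function(m, dr, dc) {
  out <- matrix(0L, nrow(m), ncol(m))
  if (abs(dr) >= nrow(m) || abs(dc) >= ncol(m)) return(out)
  src_r <- max(1L, 1L - dr):min(nrow(m), nrow(m) - dr)
  src_c <- max(1L, 1L - dc):min(ncol(m), ncol(m) - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

mask_dsc <- function(pred, gt) {
  2 * sum(pred == 1L & gt == 1L) / (sum(pred) + sum(gt))
}

#' Surrogate segmentation of one slice
#'
#' Emits a prediction whose quality follows the planted
#' performance-vs-contrast law of `config`. Detection failure is sampled
#' with probability rising below the planted cliff and yields either an
#' empty mask or, with probability `miss_blob_prob`, a disjoint false
#' blob in another brain region. On success, a target DSC q(F) and a
#' target area ratio (the RAAD trend) are drawn; the prediction is built
#' from the true lesion by eroding or dilating toward the target area
#' and then translating along a random direction, searching the offset
#' whose measured DSC is closest to q. If no candidate lands within 0.05
#' of q, the closest achievable is returned with a `quality_gap`
#' attribute. The surrogate reads only the ground-truth mask, never the
#' image: it imposes the law under test rather than estimating it.
#'
#' @param sample [cg_slice()] with a non-empty lesion.
#' @param true_f The slice's Fisher's ratio (measured or planted).
#' @param config [surrogate_config()].
#' @param seed Integer seed.
#' @return 0/1 prediction matrix; attributes `target_dsc` and possibly
#'   `quality_gap`.
#' @export
surrogate_segment <- function(sample, true_f, config, seed) {
  cg_assert(sum(sample$lesion_mask) > 0, "cg_error_empty_lesion",
            "lesion mask is empty")
  gt <- sample$lesion_mask
  side <- nrow(gt)
  with_local_seed(seed, {
    s <- stats::plogis(config$steepness *
                       (true_f - config$critical_contrast))
    s_det <- stats::plogis(config$detection_steepness *
                           (true_f - config$critical_contrast))
    p_detect <- config$detection_floor + (1 - config$detection_floor) * s_det
    if (stats::runif(1) > p_detect) {
      if (stats::runif(1) < config$miss_blob_prob) {
        return(structure(disjoint_blob(gt), target_dsc = 0))
      }
      return(structure(matrix(0L, side, ncol(gt)), target_dsc = 0))
    }
    q <- config$dsc_floor + (config$dsc_ceiling - config$dsc_floor) * s +
      stats::rnorm(1, 0, config$noise_sd)
    q <- min(max(q, 0.02), 0.98)
    raad_target <- config$raad_low +
      (config$raad_high - config$raad_low) *
        stats::plogis(config$area_bias *
                      (true_f - config$critical_contrast +
                       config$area_bias_shift)) +
      stats::rnorm(1, 0, config$raad_noise)
    # the DSC target is primary: cap overestimation so that a base of
    # area ratio r (max reachable DSC = 2 min(1,r)/(1+r)) can still hit q
    rho <- max(0.25, 1 + raad_target)
    if (rho > 1) rho <- min(rho, 2 / (q + 0.01) - 1)
    base <- resize_mask_area(gt, rho)
    area_ratio <- sum(base) / sum(gt)
    q <- min(q, 2 * min(1, area_ratio) / (1 + area_ratio) - 0.01)
    ang <- stats::runif(1, 0, 2 * pi)
    best <- NULL
    best_gap <- Inf
    for (off in 0:side) {
      cand <- shift_mask(base, as.integer(round(off * cos(ang))),
                         as.integer(round(off * sin(ang))))
      d <- mask_dsc(cand, gt)
      gap <- abs(d - q)
      if (gap < best_gap) {
        best <- cand
        best_gap <- gap
      }
      if (d == 0) break
    }
    attr(best, "target_dsc") <- q
    if (best_gap > 0.05) attr(best, "quality_gap") <- best_gap
    best
  })
}

# Grow or shrink a mask to `ratio` times its area, to the pixel: whole
# morphological rings (3x3 box) are added or removed while they fit, then
# the final ring is applied partially (random subset, caller controls the
# RNG state). The mask is never emptied.
resize_mask_area <- function(mask, ratio) {
  target <- max(1L, as.integer(round(ratio * sum(mask))))
  out <- mask
  brush <- matrix(1L, 3L, 3L)
  for (step in seq_len(8)) {
    current <- sum(out)
    if (current == target) break
    if (current < target) {
      grown <- matrix(as.integer(EBImage::dilate(out, brush)), nrow(mask))
      ring <- which(grown == 1L & out == 0L)
      if (length(ring) == 0) break
      need <- target - current
      if (length(ring) > need) ring <- ring[sample.int(length(ring), need)]
      out[ring] <- 1L
    } else {
      shrunk <- matrix(as.integer(EBImage::erode(out, brush)), nrow(mask))
      ring <- which(out == 1L & shrunk == 0L)
      excess <- current - target
      if (length(ring) >= current) {
        # eroding would empty the mask: drop just the excess pixels
        ring <- ring[sample.int(length(ring), min(excess, current - 1L))]
      } else if (length(ring) > excess) {
        ring <- ring[sample.int(length(ring), excess)]
      }
      if (length(ring) == 0) break
      out[ring] <- 0L
    }
  }
  out
}

# A false-positive blob disjoint from the reference: the (eroded)
# reference translated to another region along a random direction.
disjoint_blob <- function(gt) {
  base <- gt
  er <- matrix(as.integer(EBImage::erode(gt, matrix(1L, 3L, 3L))),
               nrow(gt))
  if (sum(er) > 0) base <- er
  ext <- apply(which(gt == 1L, arr.ind = TRUE), 2, function(v)
    diff(range(v))) + 1
  ang <- stats::runif(1, 0, 2 * pi)
  for (off in seq(from = ceiling(1.3 * max(ext)), to = nrow(gt), by = 1)) {
    cand <- shift_mask(base, as.integer(round(off * cos(ang))),
                       as.integer(round(off * sin(ang))))
    if (sum(cand) > 0 && sum(cand == 1L & gt == 1L) == 0) return(cand)
  }
  matrix(0L, nrow(gt), ncol(gt))
}

#' Surrogate predictions for a whole dataset
#'
#' @param samples List of [cg_slice()].
#' @param fisher Per-slice Fisher's ratios, parallel to `samples`.
#' @param config [surrogate_config()].
#' @param seed Integer base seed; per-slice seeds are derived
#'   deterministically.
#' @return List of 0/1 prediction matrices.
#' @export
surrogate_segment_dataset <- function(samples, fisher, config, seed) {
  cg_assert(length(samples) == length(fisher), "cg_error_dim_mismatch",
            "samples and fisher differ in length")
  lapply(seq_along(samples), function(i) {
    surrogate_segment(samples[[i]], fisher[i], config,
                      seed = derive_seed(seed, i))
  })
}
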