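#' Per-bin performance summary against contrast
#'
#' Aggregates per-slice evaluation metrics within Fisher's-ratio bins
#' (mean and SD of detection, DSC, HD, RAAD, plus acceptability-failure
#' counts). Empty bins are reported with `NA` aggregates, never raised.
#'
#' @param evals data.frame from [evaluate_dataset()].
#' @param contrasts data.frame with `slice_id`, `fisher`.
#' @param bin_edges Increasing numeric vector of bin edges.
#' @return data.frame with one row per bin.
#' @export
bin_performance <- function(evals, contrasts, bin_edges) {
  f <- contrasts$fisher[match(evals$slice_id, contrasts$slice_id)]
  cg_assert(all(is.finite(f)), "cg_error_unpaired",
            "missing contrast for some evaluated slices")
  bin <- cut(f, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  agg <- function(v, idx, fun) if (any(idx)) fun(v[idx]) else NA_real_
  out <- list()
  for (lev in seq_len(length(bin_edges) - 1L)) {
    idx <- !is.na(bin) & as.integer(bin) == lev
    out[[lev]] <- data.frame(
      bin_low = bin_edges[lev], bin_high = bin_edges[lev + 1L],
      n = sum(idx),
      detection_mean = agg(evals$detection, idx, mean),
      dsc_mean = agg(evals$dsc, idx, mean),
      dsc_sd = agg(evals$dsc, idx, stats::sd),
      hd_mean = agg(evals$hd, idx, mean),
      hd_sd = agg(evals$hd, idx, stats::sd),
      raad_mean = agg(evals$raad, idx, mean),
      raad_sd = agg(evals$raad, idx, stats::sd),
      n_undetected = sum(idx & evals$detection == 0),
      n_dsc_fail = sum(idx & !evals$dsc_ok),
      n_hd_fail = sum(idx & !evals$hd_ok),
      n_raad_fail = sum(idx & !evals$raad_ok))
  }
  do.call(rbind, out)
}

#' Fraction of metric failures below a contrast threshold
#'
#' For each acceptability criterion, the share of failing slices whose
#' Fisher's ratio lies strictly below `threshold` — the headline statistic
#' linking poor segmentation to low contrast.
#'
#' @inheritParams bin_performance
#' @param threshold Fisher's-ratio query threshold.
#' @return data.frame with columns `metric`, `n_fail`,
#'   `fraction_below` (`NA` when no slice fails that metric).
#' @export
failure_share_below <- function(evals, contrasts, threshold) {
  f <- contrasts$fisher[match(evals$slice_id, contrasts$slice_id)]
  cg_assert(all(is.finite(f)), "cg_error_unpaired",
            "missing contrast for some evaluated slices")
  fails <- list(detection = evals$detection == 0,
                dsc = !evals$dsc_ok,
                hd = !evals$hd_ok,
                raad = !evals$raad_ok)
  do.call(rbind, lapply(names(fails), function(metric) {
    idx <- fails[[metric]]
    data.frame(metric = metric, n_fail = sum(idx),
               fraction_below = if (any(idx)) mean(f[idx] < threshold)
                                else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' ROC sweep over contrast thresholds
#'
#' For each threshold t in the grid, pixel confusion counts are summed
#' over the slices with Fisher's ratio at least t, and the aggregate
#' true-positive rate TP/(TP+FN) and false-positive rate FP/(FP+TN) are
#' computed — tightening the contrast threshold progressively removes the
#' hardest slices. Thresholds leaving zero slices are omitted.
#'
#' @param confusions List of [confusion_counts()] results, one per slice.
#' @param fisher Per-slice Fisher's ratios, parallel to `confusions`.
#' @param threshold_grid Ascending numeric grid of contrast thresholds.
#' @return data.frame of ROC points: `contrast_threshold`, `tpr`, `fpr`,
#'   `n_slices`.
#' @export
roc_sweep <- function(confusions, fisher, threshold_grid) {
  cg_assert(length(threshold_grid) > 0, "cg_error_empty_grid",
            "threshold grid is empty")
  cg_assert(!is.unsorted(threshold_grid), "cg_error_empty_grid",
            "threshold grid must be ascending")
  cg_assert(length(confusions) == length(fisher), "cg_error_dim_mismatch",
            "confusions and fisher differ in length")
  tp <- vapply(confusions, `[[`, numeric(1), "tp")
  fp <- vapply(confusions, `[[`, numeric(1), "fp")
  fn <- vapply(confusions, `[[`, numeric(1), "fn")
  tn <- vapply(confusions, `[[`, numeric(1), "tn")
  out <- list()
  for (t in threshold_grid) {
    sel <- fisher >= t
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      contrast_threshold = t,
      tpr = sum(tp[sel]) / (sum(tp[sel]) + sum(fn[sel])),
      fpr = sum(fp[sel]) / (sum(fp[sel]) + sum(tn[sel])),
      n_slices = sum(sel))
  }
  do.call(rbind, out)
}

#' Elbow threshold of a ROC sweep
#'
#' Both axes are min-max normalized over the sweep (the FPR axis of a
#' contrast sweep is compressed by orders of magnitude relative to TPR, so
#' unnormalized distance would be degenerate; a constant axis contributes
#' zero). The selected threshold belongs to the point closest, in
#' normalized coordinates, to the ideal corner (FPR = 0, TPR = 1); ties go
#' to the smaller threshold.
#'
#' Aggregate rates computed over a handful of surviving slices are
#' dominated by sampling noise, and after normalization such tail points
#' can fluctuate onto the ideal corner; `min_slices` crops them before
#' the search (0 keeps the full curve). At least one point is always
#' retained.
#'
#' @param sweep data.frame from [roc_sweep()] with at least one row.
#' @param min_slices Drop sweep points supported by fewer slices than
#'   this before the elbow search.
#' @return The elbow contrast threshold.
#' @export
elbow_threshold <- function(sweep, min_slices = 0) {
  cg_assert(nrow(sweep) >= 1, "cg_error_empty_grid", "empty ROC sweep")
  if (min_slices > 0 && any(sweep$n_slices >= min_slices)) {
    sweep <- sweep[sweep$n_slices >= min_slices, ]
  }
  norm01 <- function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  }
  fpr_n <- norm01(sweep$fpr)
  tpr_n <- norm01(sweep$tpr)
  d <- sqrt(fpr_n^2 + (1 - tpr_n)^2)
  ord <- order(d, sweep$contrast_threshold)
  sweep$contrast_threshold[ord[1]]
}

#' Default clustering method x distance combinations
#'
#' The eight combinations benchmarked for the purity/silhouette analysis:
#' k-means under all five dissimilarities, hierarchical clustering under
#' euclidean, squared euclidean and canberra.
#'
#' @return data.frame with columns `algorithm`, `distance`.
#' @export
default_cluster_combos <- function() {
  rbind(
    data.frame(algorithm = "kmeans", distance = cg_distances,
               stringsAsFactors = FALSE),
    data.frame(algorithm = "hierarchical",
               distance = c("euclidean", "sq_euclidean", "canberra"),
               stringsAsFactors = FALSE))
}

#' Run clustering across method x distance combinations
#'
#' @param features Normalized feature matrix ([cluster_feature_matrix()]).
#' @param combos data.frame with `algorithm`, `distance` rows; defaults to
#'   [default_cluster_combos()].
#' @param restarts,seed Passed to [cluster_slices()].
#' @return List of `cg_cluster_result`.
#' @export
cluster_all_combos <- function(features, combos = default_cluster_combos(),
                               restarts = 10, seed = 1) {
  lapply(seq_len(nrow(combos)), function(i) {
    cluster_slices(features, algorithm = combos$algorithm[i],
                   distance = combos$distance[i], restarts = restarts,
                   seed = seed)
  })
}

#' R-squared sweep of purity vs silhouette over contrast thresholds
#'
#' The silhouette is unsupervised; the purity is supervised by a contrast
#' cutoff. Varying the cutoff over a grid, R-squared(t) is the squared
#' Pearson correlation, across the clustering combinations, between their
#' purities at t and their silhouettes. The cutoff that best correlates
#' the two scores is the selected critical contrast. Thresholds where
#' purity or silhouette is constant across combinations (or where purity
#' is undefined) are reported as missing and excluded from the argmax;
#' ties go to the smaller threshold.
#'
#' @param cluster_results List of `cg_cluster_result` (at least 3 distinct
#'   combinations).
#' @param fisher Per-slice Fisher's ratios, parallel to the clustered rows.
#' @param threshold_grid Ascending numeric grid of candidate cutoffs.
#' @return List with `r2_curve` (data.frame: `threshold`, `r2`,
#'   `n_defined`), `purity_table` (data.frame: `algorithm`, `distance`,
#'   `silhouette`, one purity column per threshold is summarised long as
#'   `threshold`, `purity`) and `selected_threshold`.
#' @export
r2_threshold_sweep <- function(cluster_results, fisher, threshold_grid) {
  cg_assert(length(cluster_results) >= 3, "cg_error_too_few_points",
            "need at least 3 clustering combinations")
  cg_assert(!is.unsorted(threshold_grid), "cg_error_empty_grid",
            "threshold grid must be ascending")
  sil <- vapply(cluster_results, `[[`, numeric(1), "silhouette")
  purity_rows <- list()
  r2 <- rep(NA_real_, length(threshold_grid))
  for (j in seq_along(threshold_grid)) {
    t <- threshold_grid[j]
    pur <- vapply(cluster_results, function(cr) {
      cluster_quality(cr, fisher, t)$purity
    }, numeric(1))
    purity_rows[[j]] <- data.frame(
      threshold = t,
      algorithm = vapply(cluster_results, `[[`, character(1), "algorithm"),
      distance = vapply(cluster_results, `[[`, character(1), "distance"),
      silhouette = sil, purity = pur, stringsAsFactors = FALSE)
    if (anyNA(pur) || stats::sd(pur) == 0 || stats::sd(sil) == 0) next
    r2[j] <- stats::cor(pur, sil)^2
  }
  selected <- if (all(is.na(r2))) NA_real_ else
    threshold_grid[which.max(replace(r2, is.na(r2), -Inf))]
  list(r2_curve = data.frame(threshold = threshold_grid, r2 = r2),
       purity_table = do.call(rbind, purity_rows),
       selected_threshold = selected)
}

#' Filter a dataset by minimum contrast
#'
#' @param samples List of [cg_slice()].
#' @param contrasts data.frame with `slice_id`, `fisher`.
#' @param min_f Minimum Fisher's ratio; slices with `fisher < min_f` are
#'   dropped.
#' @return List with `samples`, `kept` (logical vector) and
#'   `reduction_fraction` (share of slices removed).
#' @export
filter_by_contrast <- function(samples, contrasts, min_f) {
  ids <- vapply(samples, slice_id, character(1))
  f <- contrasts$fisher[match(ids, contrasts$slice_id)]
  cg_assert(all(is.finite(f)), "cg_error_unpaired",
            "missing contrast for some slices")
  kept <- f >= min_f
  list(samples = samples[kept], kept = kept,
       reduction_fraction = 1 - mean(kept))
}

#' Validate a contrast threshold by retraining
#'
#' Trains the segmenter twice per seed — on the full training set and on
#' the subset with Fisher's ratio at least `threshold` — and evaluates
#' both on the identical test set and on its high-contrast subset. If
#' performance is steady although data was removed, the removed slices
#' carried no learnable information and the threshold is validated.
#'
#' @param train_samples,test_samples Lists of [cg_slice()].
#' @param contrasts data.frame with `slice_id`, `fisher` covering both
#'   sets.
#' @param threshold Contrast threshold under test.
#' @param segmenter A trainable segmenter interface: list with
#'   `fit(samples, seed)` returning a model and `predict(model, sample)`
#'   returning a 0/1 mask (see [baseline_segmenter()]).
#' @param seeds Integer seeds; metrics are reported mean +/- sd across
#'   them.
#' @return List with `comparison` (data.frame: training set x test set x
#'   metric, mean and sd over seeds), `per_seed` (data.frame of raw
#'   means) and `reduction_fraction`.
#' @export
validate_threshold <- function(train_samples, test_samples, contrasts,
                               threshold, segmenter = baseline_segmenter(),
                               seeds = c(1L, 2L, 3L)) {
  filt <- filter_by_contrast(train_samples, contrasts, threshold)
  cg_assert(length(filt$samples) > 0, "cg_error_empty_dataset",
            "no training slice survives the threshold")
  test_ids <- vapply(test_samples, slice_id, character(1))
  f_test <- contrasts$fisher[match(test_ids, contrasts$slice_id)]
  cg_assert(all(is.finite(f_test)), "cg_error_unpaired",
            "missing contrast for some test slices")
  high_idx <- f_test >= threshold
  training_sets <- list(full = train_samples, filtered = filt$samples)
  rows <- list()
  for (seed in seeds) {
    for (tr_name in names(training_sets)) {
      model <- segmenter$fit(training_sets[[tr_name]], seed = seed)
      preds <- lapply(test_samples, function(s) segmenter$predict(model, s))
      ev <- evaluate_dataset(test_samples, preds)
      for (te_name in c("all", "high_contrast")) {
        idx <- if (te_name == "all") rep(TRUE, nrow(ev)) else high_idx
        if (!any(idx)) next
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, training = tr_name, test = te_name,
          n_test = sum(idx),
          detection = mean(ev$detection[idx]), dsc = mean(ev$dsc[idx]),
          hd = mean(ev$hd[idx]), raad = mean(ev$raad[idx]))
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  comparison <- do.call(rbind, lapply(
    split(per_seed, list(per_seed$training, per_seed$test), drop = TRUE),
    function(g) {
      data.frame(training = g$training[1], test = g$test[1],
                 n_test = g$n_test[1],
                 detection_mean = mean(g$detection),
                 detection_sd = stats::sd(g$detection),
                 dsc_mean = mean(g$dsc), dsc_sd = stats::sd(g$dsc),
                 hd_mean = mean(g$hd), hd_sd = stats::sd(g$hd),
                 raad_mean = mean(g$raad), raad_sd = stats::sd(g$raad))
    }))
  rownames(comparison) <- NULL
  list(comparison = comparison, per_seed = per_seed,
       reduction_fraction = filt$reduction_fraction)
}
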