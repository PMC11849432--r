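mk_conf <- function(tp, fp, fn, tn) list(tp = tp, fp = fp, fn = fn, tn = tn)

test_that("roc sweep aggregates pixel counts over surviving slices", {
  confs <- list(mk_conf(10, 2, 5, 83), mk_conf(30, 1, 10, 59))
  fisher <- c(0.02, 0.10)
  sw <- roc_sweep(confs, fisher, c(0.01, 0.05, 0.2))
  # below min F: whole-set rates
  expect_equal(sw$tpr[1], 40 / 55)
  expect_equal(sw$fpr[1], 3 / 145)
  expect_equal(sw$n_slices[1], 2)
  # between the two F values: surviving slice alone
  expect_equal(sw$tpr[2], 30 / 40)
  expect_equal(sw$fpr[2], 1 / 60)
  # beyond max F: threshold omitted
  expect_equal(nrow(sw), 2)
  expect_error(roc_sweep(confs, fisher, numeric()),
               class = "cg_error_empty_grid")
})

test_that("roc rates stay within [0, 1] on random inputs", {
  set.seed(103)
  confs <- lapply(1:30, function(i) {
    v <- as.list(sample(0:50, 4, replace = TRUE))
    names(v) <- c("tp", "fp", "fn", "tn")
    v$fn <- v$fn + 1  # gt non-empty
    v
  })
  sw <- roc_sweep(confs, runif(30), seq(0, 1, 0.1))
  expect_true(all(sw$tpr >= 0 & sw$tpr <= 1))
  expect_true(all(sw$fpr >= 0 & sw$fpr <= 1))
})

test_that("elbow picks the normalized point closest to the ideal corner", {
  one <- data.frame(contrast_threshold = 0.07, tpr = 0.5, fpr = 0.01,
                    n_slices = 10)
  expect_equal(elbow_threshold(one), 0.07)
  # normalized points (0,0.2), (0.1,0.9), (1,1): middle point wins
  sweep <- data.frame(contrast_threshold = c(0.01, 0.05, 0.2),
                      tpr = c(0.2, 0.9, 1.0) * 0.5 + 0.2,
                      fpr = c(0.0, 0.1, 1.0) * 0.004 + 0.001,
                      n_slices = c(30, 20, 10))
  expect_equal(elbow_threshold(sweep), 0.05)
  # a constant axis contributes zero after normalization
  flat <- data.frame(contrast_threshold = c(0.01, 0.02), tpr = c(0.4, 0.8),
                     fpr = c(0.01, 0.01), n_slices = c(5, 4))
  expect_equal(elbow_threshold(flat), 0.02)
  # min_slices crops noisy tail points
  noisy <- rbind(sweep, data.frame(contrast_threshold = 0.3, tpr = 1,
                                   fpr = 0.001, n_slices = 2))
  expect_equal(elbow_threshold(noisy, min_slices = 5), 0.05)
})

test_that("per-bin aggregation and failure shares match direct loops", {
  set.seed(107)
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  evals <- data.frame(
    slice_id = ids, detection = rbinom(n, 1, 0.8),
    dsc = runif(n), hd = runif(n, 0, 80), hd_degenerate = FALSE,
    raad = runif(n, -1, 1), stringsAsFactors = FALSE)
  evals$dsc_ok <- evals$dsc >= 0.1
  evals$hd_ok <- evals$hd <= 60
  evals$raad_ok <- abs(evals$raad) <= 0.5
  contrasts <- data.frame(slice_id = ids, fisher = runif(n, 0, 0.3))
  edges <- seq(0, 0.3, 0.1)
  bins <- bin_performance(evals, contrasts, edges)
  expect_equal(sum(bins$n), n)
  for (lev in 1:3) {
    idx <- contrasts$fisher >= edges[lev] & contrasts$fisher < edges[lev + 1]
    expect_equal(bins$n[lev], sum(idx))
    if (any(idx)) {
      expect_equal(bins$dsc_mean[lev], mean(evals$dsc[idx]))
      expect_equal(bins$n_undetected[lev], sum(evals$detection[idx] == 0))
    }
  }
  t0 <- 0.12
  fs <- failure_share_below(evals, contrasts, t0)
  undetected <- which(evals$detection == 0)
  expect_equal(fs$fraction_below[fs$metric == "detection"],
               sum(contrasts$fisher[undetected] < t0) / length(undetected))
  # all failures planted below the threshold: share = 1
  evals2 <- evals
  evals2$detection <- ifelse(contrasts$fisher < 0.05, 0L, 1L)
  fs2 <- failure_share_below(evals2, contrasts, 0.05)
  expect_equal(fs2$fraction_below[fs2$metric == "detection"], 1.0)
})

test_that("r2 sweep scores purity-silhouette correlation per threshold", {
  # 12 low-contrast, 8 mid-band, 20 high-contrast slices
  fisher <- c(rep(0.02, 12), rep(0.07, 8), rep(0.2, 20))
  band <- fisher == 0.07
  mk <- function(labels, sil) {
    structure(list(algorithm = "kmeans", distance = "euclidean",
                   labels = labels, centroids = NULL, silhouette = sil,
                   seed = 1L), class = "cg_cluster_result")
  }
  ref <- as.integer(fisher >= 0.1)
  # agreement with the 0.1 split decreases with silhouette: purity is
  # perfectly linear in silhouette at t = 0.1 but not elsewhere
  p2 <- ref; p2[1:4] <- 1L - p2[1:4]
  p3 <- ref; p3[band] <- 1L - p3[band]
  results <- list(mk(ref, 0.9), mk(p2, 0.7), mk(p3, 0.5))
  out <- r2_threshold_sweep(results, fisher, c(0.05, 0.1, 0.2))
  r2_at <- function(t) out$r2_curve$r2[out$r2_curve$threshold == t]
  expect_equal(r2_at(0.1), 1.0, tolerance = 1e-9)
  expect_lt(r2_at(0.05), 1.0)
  expect_equal(out$selected_threshold, 0.1)
  # identical partitions: zero purity variance, undefined everywhere
  same <- list(mk(ref, 0.9), mk(ref, 0.7), mk(ref, 0.5))
  out2 <- r2_threshold_sweep(same, fisher, c(0.05, 0.1))
  expect_true(all(is.na(out2$r2_curve$r2)))
  expect_true(is.na(out2$selected_threshold))
  expect_error(r2_threshold_sweep(results[1:2], fisher, c(0.1)),
               class = "cg_error_too_few_points")
})

test_that("contrast filtering reports the removed fraction exactly", {
  samples <- lapply(1:10, function(i) {
    square_lesion_slice(patient = "P1", index = i)
  })
  ids <- vapply(samples, contrastgate:::slice_id, character(1))
  contrasts <- data.frame(slice_id = ids,
                          fisher = seq(0.01, 0.1, length.out = 10))
  out <- filter_by_contrast(samples, contrasts, 0.05)
  kept_direct <- sum(contrasts$fisher >= 0.05)
  expect_length(out$samples, kept_direct)
  expect_equal(out$reduction_fraction, 1 - kept_direct / 10)
})

test_that("a threshold below the minimum contrast is a no-op comparison", {
  set.seed(109)
  train <- lapply(1:10, function(i)
    small_phantom(runif(1, 0.06, 0.25), seed = 800 + i)$sample)
  test <- lapply(1:4, function(i)
    small_phantom(runif(1, 0.06, 0.25), seed = 900 + i)$sample)
  all_samples <- c(train, test)
  ids <- vapply(all_samples, contrastgate:::slice_id, character(1))
  contrasts <- data.frame(
    slice_id = ids,
    fisher = vapply(all_samples, function(s) slice_contrast(s)$fisher,
                    numeric(1)))
  seg <- baseline_segmenter(cutoff_grid_size = 16)
  val <- validate_threshold(train, test, contrasts, threshold = 0.001,
                            segmenter = seg, seeds = 1L)
  expect_equal(val$reduction_fraction, 0)
  full <- val$comparison[val$comparison$training == "full", ]
  filt <- val$comparison[val$comparison$training == "filtered", ]
  expect_identical(full$dsc_mean, filt$dsc_mean)
  expect_identical(full$hd_mean, filt$hd_mean)
  expect_error(
    validate_threshold(train, test, contrasts, threshold = 10,
                       segmenter = seg, seeds = 1L),
    class = "cg_error_empty_dataset")
})
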