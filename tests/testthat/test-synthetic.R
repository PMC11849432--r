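test_that("phantom slices hit their planted contrast through the scorer", {
  cfg <- phantom_config(side = 96, lesion_radius_range = c(5, 9))
  for (f in c(0.02, 0.05, 0.2)) {
    g <- generate_phantom_slice(cfg, f, seed = 300 + round(1000 * f))
    expect_equal(g$achieved_f, f, tolerance = 1e-6)
    # audit independently through the contrast module
    expect_equal(slice_contrast(g$sample)$fisher, f, tolerance = 1e-6)
    expect_gte(sum(g$sample$lesion_mask), 50)
    expect_true(all(g$sample$brain_mask[g$sample$lesion_mask == 1L] == 1L))
  }
})

test_that("a zero-contrast target yields an indistinguishable lesion", {
  g <- small_phantom(0, seed = 41)
  expect_lt(g$achieved_f, 0.005)
})

test_that("phantom generation is bit-reproducible and seed-sensitive", {
  cfg <- phantom_config(side = 64, lesion_radius_range = c(4, 7))
  a <- generate_phantom_slice(cfg, 0.06, seed = 11)
  b <- generate_phantom_slice(cfg, 0.06, seed = 11)
  c <- generate_phantom_slice(cfg, 0.06, seed = 12)
  expect_identical(a$sample$image, b$sample$image)
  expect_identical(a$sample$lesion_mask, b$sample$lesion_mask)
  expect_false(identical(a$sample$image, c$sample$image))
})

test_that("infeasible contrast targets are rejected", {
  cfg <- phantom_config(side = 64, lesion_radius_range = c(4, 7))
  expect_error(generate_phantom_slice(cfg, 50, seed = 1),
               class = "cg_error_infeasible_target")
  expect_error(generate_phantom_slice(cfg, -0.1, seed = 1),
               class = "cg_error_infeasible_target")
})

test_that("the skewed dataset is dominated by low-contrast slices", {
  cfg <- phantom_config(side = 64, lesion_radius_range = c(4, 7))
  ds <- generate_synthetic_dataset(cfg, 120, 12, seed = 5,
                                   distribution = "skewed")
  expect_gt(mean(ds$truth$achieved_f < 0.05), 0.5)
  # histogram mass concentrates in the lowest bins
  h <- fisher_histogram(ds$truth$achieved_f, 0.025)
  expect_equal(which.max(h$counts), 1L)
  # round-robin patient assignment
  expect_equal(length(unique(ds$truth$patient_id)), 12)
  one_per <- generate_synthetic_dataset(cfg, 8, 8, seed = 6,
                                        distribution = "uniform")
  expect_equal(nrow(one_per$truth), 8)
  expect_equal(length(unique(one_per$truth$patient_id)), 8)
})

test_that("achieved contrasts match their targets across a dataset", {
  cfg <- phantom_config(side = 64, lesion_radius_range = c(4, 7))
  ds <- generate_synthetic_dataset(cfg, 30, 6, seed = 7,
                                   distribution = "uniform")
  expect_lt(max(abs(ds$truth$achieved_f - ds$truth$target_f)), 0.01)
})

test_that("forced detection failure yields an empty mask and RAAD of -1", {
  g <- small_phantom(0.001, seed = 77)
  sc <- surrogate_config(detection_floor = 0, miss_blob_prob = 0)
  pred <- surrogate_segment(g$sample, 0, sc, seed = 3)
  expect_equal(sum(pred), 0)
  ev <- evaluate_slice(pred, g$sample$lesion_mask)
  expect_equal(ev$detection, 0L)
  expect_equal(ev$raad, -1)
  expect_true(ev$hd_degenerate)
})

test_that("high-contrast surrogate quality approaches the ceiling", {
  sc <- surrogate_config(noise_sd = 0, raad_noise = 0)
  set.seed(113)
  dscs <- vapply(1:12, function(i) {
    g <- small_phantom(0.25, seed = 400 + i)
    pred <- surrogate_segment(g$sample, 0.25, sc, seed = 500 + i)
    dice(confusion_counts(pred, g$sample$lesion_mask))
  }, numeric(1))
  expect_lt(abs(mean(dscs) - sc$dsc_ceiling), 0.05)
})

test_that("surrogate DSC at the cliff sits near the law's midpoint", {
  sc <- surrogate_config()
  vals <- vapply(1:50, function(i) {
    g <- small_phantom(sc$critical_contrast, seed = 1400 + i)
    pred <- surrogate_segment(g$sample, sc$critical_contrast, sc,
                              seed = 1500 + i)
    dice(confusion_counts(pred, g$sample$lesion_mask))
  }, numeric(1))
  detected <- vals[vals > 0]
  mid <- (sc$dsc_floor + sc$dsc_ceiling) / 2
  expect_lt(abs(mean(detected) - mid), 0.1)
})

test_that("mean surrogate DSC increases with contrast", {
  # the grid spans the law's transition region around the default cliff
  # the grid samples the law through its transition, where consecutive
  # true increments exceed the per-point sampling noise
  sc <- surrogate_config()
  grid <- seq(0.035, 0.065, by = 0.005)
  mean_dsc <- vapply(seq_along(grid), function(j) {
    mean(vapply(1:40, function(i) {
      g <- small_phantom(grid[j], seed = 2000 + 97 * j + i)
      pred <- surrogate_segment(g$sample, grid[j], sc,
                                seed = 3000 + 89 * j + i)
      dice(confusion_counts(pred, g$sample$lesion_mask))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid, mean_dsc, method = "spearman"), 0.9)
})

test_that("surrogate predictions are deterministic given the seed", {
  g <- small_phantom(0.07, seed = 55)
  sc <- surrogate_config()
  a <- surrogate_segment(g$sample, 0.07, sc, seed = 9)
  b <- surrogate_segment(g$sample, 0.07, sc, seed = 9)
  expect_identical(unclass(a), unclass(b))
})
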