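make_grid <- function(values, side = 5) {
  img <- matrix(0, side, side)
  brain <- matrix(0L, side, side)
  img[seq_along(values)] <- values
  brain[seq_along(values)] <- 1L
  list(image = img, brain = brain)
}

test_that("HU window keeps [15, 80] and min-max normalizes survivors", {
  g <- make_grid(c(10, 20, 50, 80, 90))
  wn <- window_and_normalize(g$image, g$brain)
  vals <- wn$normalized[wn$retained_mask == 1L]
  expect_equal(sort(vals), c(0.0, 0.5, 1.0))
  expect_equal(sum(wn$retained_mask), 3)
  # boundary values are retained and map to the interval ends
  g2 <- make_grid(c(15, 40, 80))
  wn2 <- window_and_normalize(g2$image, g2$brain)
  expect_equal(min(wn2$normalized, na.rm = TRUE), 0)
  expect_equal(max(wn2$normalized, na.rm = TRUE), 1)
})

test_that("degenerate windowing raises named errors", {
  g <- make_grid(c(40, 40, 40))
  expect_error(window_and_normalize(g$image, g$brain),
               class = "cg_error_degenerate_slice")
  g2 <- make_grid(c(5, 90, 100))
  expect_error(window_and_normalize(g2$image, g2$brain),
               class = "cg_error_empty_window")
  expect_error(window_and_normalize(g$image, matrix(0L, 5, 5)),
               class = "cg_error_empty_brain")
})

test_that("fisher ratio evaluates the printed formula and its errors", {
  expect_equal(fisher_ratio(list(mean = 0.3, variance = 0.01, n = 10),
                            list(mean = 0.5, variance = 0.03, n = 10)),
               1.0)
  expect_equal(fisher_ratio(list(mean = 0.4, variance = 0.02, n = 5),
                            list(mean = 0.4, variance = 0.05, n = 5)),
               0)
  expect_error(fisher_ratio(list(mean = 1, variance = 0, n = 5),
                            list(mean = 2, variance = 0, n = 5)),
               class = "cg_error_degenerate_contrast")
  expect_error(fisher_ratio(list(mean = 1, variance = 1, n = 1),
                            list(mean = 2, variance = 1, n = 5)),
               class = "cg_error_region_too_small")
})

test_that("fisher ratio is affine-invariant and symmetric in its regions", {
  set.seed(31)
  for (rep in 1:100) {
    obj <- rnorm(sample(5:40, 1), mean = runif(1, 0.2, 0.5), sd = 0.1)
    bg <- rnorm(sample(5:40, 1), mean = runif(1, 0.4, 0.8), sd = 0.15)
    f0 <- fisher_ratio(region_stats(obj), region_stats(bg))
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    b <- runif(1, -10, 10)
    f1 <- fisher_ratio(region_stats(a * obj + b), region_stats(a * bg + b))
    expect_lt(abs(f0 - f1), 1e-9)
    expect_equal(fisher_ratio(region_stats(bg), region_stats(obj)), f0)
    expect_gte(f0, 0)
  }
})

test_that("region statistics match a per-pixel accumulation", {
  set.seed(37)
  for (rep in 1:10) {
    vals <- rnorm(32 * 32)
    st <- region_stats(vals)
    m <- 0
    for (v in vals) m <- m + v
    m <- m / length(vals)
    v2 <- 0
    for (v in vals) v2 <- v2 + (v - m)^2
    v2 <- v2 / length(vals)
    expect_lt(abs(st$mean - m), 1e-10)
    expect_lt(abs(st$variance - v2), 1e-10)
  }
})

test_that("F grows with the mean separation at fixed variances", {
  f <- vapply(seq(0, 0.4, by = 0.1), function(gap) {
    fisher_ratio(list(mean = 0.5 - gap, variance = 0.02, n = 10),
                 list(mean = 0.5, variance = 0.02, n = 10))
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("ipsilateral background excludes the lesion and the far side", {
  brain <- matrix(1L, 20, 20)
  lesion <- matrix(0L, 20, 20)
  lesion[5:6, 5:6] <- 1L
  retained <- matrix(1L, 20, 20)
  bg <- ipsilateral_background(brain, lesion, retained)
  cols <- which(bg == 1L, arr.ind = TRUE)[, 2]
  expect_true(all(cols < 10.5))
  expect_equal(sum(bg == 1L & lesion == 1L), 0)
  # brute-force count: retained left-half pixels minus the 4 lesion pixels
  expect_equal(sum(bg), 20 * 10 - 4)
})

test_that("a lesion filling its hemisphere leaves no background", {
  brain <- matrix(1L, 10, 10)
  lesion <- matrix(0L, 10, 10)
  lesion[, 1:5] <- 1L
  expect_error(ipsilateral_background(brain, lesion, matrix(1L, 10, 10)),
               class = "cg_error_empty_background")
  expect_error(ipsilateral_background(brain, matrix(0L, 10, 10),
                                      matrix(1L, 10, 10)),
               class = "cg_error_empty_lesion")
})

test_that("slice contrast is invariant to the HU windowing normalization", {
  s <- small_phantom(0.08, seed = 91)
  expect_equal(s$achieved_f, 0.08, tolerance = 1e-6)
  rec <- slice_contrast(s$sample)
  # normalized intensities live in [0, 1]
  expect_gte(rec$lesion_stats$mean, 0)
  expect_lte(rec$background_stats$mean, 1)
  expect_gte(rec$retained_fraction, 0.9)
})

test_that("contrast profile reports degenerate slices instead of raising", {
  ok <- square_lesion_slice()
  flat <- square_lesion_slice(lesion_hu = 40, ripple = FALSE)
  prof <- contrast_profile(list(ok, flat))
  expect_equal(nrow(prof$records), 1)
  expect_equal(nrow(prof$degenerate), 1)
  expect_match(prof$degenerate$reason, "constant")
  expect_equal(sum(prof$histogram$counts), 1)
  one <- contrast_profile(list(ok))
  expect_equal(nrow(one$records), 1)
})
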