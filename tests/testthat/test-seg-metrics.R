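test_that("confusion counts partition the slice and match a pixel loop", {
  set.seed(101)
  for (rep in 1:25) {
    pred <- random_mask(8, 20, function(a, b) sample(a:b, 1))
    gt <- random_mask(8, 20, function(a, b) sample(a:b, 1))
    got <- confusion_counts(pred, gt)
    want <- oracle_confusion(pred, gt)
    expect_identical(got[c("tp", "fp", "fn", "tn")],
                     want[c("tp", "fp", "fn", "tn")])
    expect_equal(got$tp + got$fp + got$fn + got$tn, 64)
  }
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               class = "cg_error_dim_mismatch")
})

test_that("dice follows 2TP/(FN+FP+2TP) and its boundary cases", {
  expect_equal(dice(list(tp = 2, fp = 2, fn = 2, tn = 10)), 0.5)
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  expect_equal(dice(confusion_counts(m, m)), 1.0)
  disjoint <- matrix(0L, 4, 4); disjoint[4, 4] <- 1L
  expect_equal(dice(confusion_counts(disjoint, m)), 0.0)
  expect_error(dice(list(tp = 0, fp = 0, fn = 0, tn = 16)),
               class = "cg_error_undefined_metric")
})

test_that("dice is symmetric in prediction and reference", {
  set.seed(7)
  for (rep in 1:10) {
    a <- random_mask(8, 30, function(x, y) sample(x:y, 1))
    b <- random_mask(8, 30, function(x, y) sample(x:y, 1))
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice(confusion_counts(a, b)), dice(confusion_counts(b, a)))
  }
})

test_that("detection requires at least one overlapping pixel", {
  gt <- matrix(0L, 5, 5); gt[2:3, 2:3] <- 1L
  one <- matrix(0L, 5, 5); one[2, 2] <- 1L
  expect_identical(detection(one, gt), 1L)
  expect_identical(detection(matrix(0L, 5, 5), gt), 0L)
  disjoint <- matrix(0L, 5, 5); disjoint[5, 5] <- 1L
  expect_identical(detection(disjoint, gt), 0L)
  expect_error(detection(one, matrix(0L, 5, 5)),
               class = "cg_error_empty_lesion")
})

test_that("hausdorff matches the all-pairs oracle and is symmetric", {
  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L
  expect_equal(as.numeric(hausdorff(a, b)), 5)
  expect_equal(as.numeric(hausdorff(b, b)), 0)
  set.seed(11)
  for (rep in 1:20) {
    p <- random_mask(12, 50, function(x, y) sample(x:y, 1))
    g <- random_mask(12, 50, function(x, y) sample(x:y, 1))
    if (sum(p) == 0 || sum(g) == 0) next
    expect_equal(as.numeric(hausdorff(p, g)), oracle_hausdorff(p, g))
    expect_equal(as.numeric(hausdorff(p, g)), as.numeric(hausdorff(g, p)))
  }
})

test_that("an empty prediction receives the Hausdorff cap, flagged", {
  gt <- matrix(0L, 6, 6); gt[3, 3] <- 1L
  hd <- hausdorff(matrix(0L, 6, 6), gt)
  expect_equal(as.numeric(hd), 60)
  expect_true(attr(hd, "degenerate"))
  hd2 <- hausdorff(matrix(0L, 6, 6), gt, cap = 10)
  expect_equal(as.numeric(hd2), 10)
})

test_that("raad is the signed relative area difference", {
  expect_equal(raad(list(tp = 4, fp = 2, fn = 0, tn = 10)), 0.5)
  expect_equal(raad(list(tp = 3, fp = 1, fn = 1, tn = 10)), 0.0)
  expect_equal(raad(list(tp = 0, fp = 0, fn = 4, tn = 12)), -1.0)
  expect_error(raad(list(tp = 0, fp = 1, fn = 0, tn = 15)),
               class = "cg_error_empty_lesion")
})

test_that("combined loss equals soft-Dice loss plus mean BCE", {
  y <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4)
  p_half <- matrix(0.5, 2, 4)
  expect_equal(combined_loss(y, p_half), 0.5 + log(2), tolerance = 1e-12)
  eps <- 1e-7
  p_perfect <- matrix(pmin(pmax(y, eps), 1 - eps), 2, 4)
  expect_lt(combined_loss(y, p_perfect, epsilon = eps), 1e-5)
  # all-empty reference: soft Dice vanishes, so the loss tends to the
  # Dice-loss unit plus an epsilon-order BCE term
  y0 <- matrix(0, 2, 4)
  expect_equal(combined_loss(y0, matrix(eps, 2, 4), epsilon = eps), 1,
               tolerance = 1e-5)
  expect_error(combined_loss(y, matrix(Inf, 2, 4)),
               class = "cg_error_nonfinite_prediction")
})

test_that("evaluation flags agree with the acceptability thresholds", {
  set.seed(23)
  for (rep in 1:20) {
    g <- random_mask(10, 20, function(x, y) sample(x:y, 1))
    if (sum(g) == 0) next
    p <- random_mask(10, 20, function(x, y) sample(x:y, 1))
    ev <- evaluate_slice(p, g)
    expect_identical(ev$dsc_ok, ev$dsc >= 0.1)
    expect_identical(ev$hd_ok, ev$hd <= 60)
    expect_identical(ev$raad_ok, abs(ev$raad) <= 0.5)
    expect_gte(ev$dsc, 0)
    expect_lte(ev$dsc, 1)
    expect_gte(ev$raad, -1)
    if (ev$detection == 1) expect_gt(ev$dsc, 0)
    if (ev$dsc == 1) {
      expect_equal(ev$hd, 0)
      expect_equal(ev$raad, 0)
    }
  }
})
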