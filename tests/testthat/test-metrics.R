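test_that("Dice handles identity, disjoint and partial overlap", {
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  a[1:2, 1:2] <- 1L; b[1:2, 1:2] <- 1L
  expect_equal(dice(a, b)$mean, 1)
  b2 <- matrix(0L, 4, 4); b2[3:4, 3:4] <- 1L
  expect_equal(dice(a, b2)$mean, 0)
  # |A| = |B| = 4 with overlap 2
  b3 <- matrix(0L, 4, 4); b3[2:3, 1:2] <- 1L
  expect_equal(dice(a, b3)$per_label[["1"]], 0.5)
})

test_that("Dice and predictive values agree through the confusion counts", {
  set.seed(4)
  a <- matrix(sample(0:3, 100, TRUE), 10, 10)
  b <- matrix(sample(0:3, 100, TRUE), 10, 10)
  for (L in 1:3) {
    cc <- confusion_counts(a, b, L)
    expect_equal(dice(a, b)$per_label[[as.character(L)]],
                 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn))
    pv <- predictive_values(a, b, L)
    expect_equal(pv$ppv, cc$tp / (cc$tp + cc$fp))
    expect_equal(pv$npv, cc$tn / (cc$tn + cc$fn))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, sum(a > 0 | b > 0))
  }
})

test_that("predictive values use the stated definitions and NA markers", {
  pred <- matrix(c(rep(1L, 10), rep(2L, 10)), 4, 5)
  ref <- pred
  ref[1] <- 2L; ref[11] <- 1L
  pv <- predictive_values(pred, ref, 1L)
  expect_equal(pv$ppv, 9 / 10)
  expect_equal(pv$npv, 9 / 10)
  expect_equal(predictive_values(pred, ref, 2L)$ppv, 9 / 10)
  # no predicted positives for an absent label
  expect_true(is.na(predictive_values(pred, ref, 5L)$ppv))
  p2 <- predictive_values(pred, pred, 1L)
  expect_equal(c(p2$ppv, p2$npv), c(1, 1))
})

test_that("necrosis fraction counts only tumour and necrosis voxels", {
  lab <- c(rep(1L, 75), rep(2L, 25), rep(3L, 50), rep(5L, 100))
  expect_equal(necrosis_fraction(lab), 0.25)
  expect_equal(necrosis_fraction(rep(1L, 10)), 0)
  expect_true(is.na(necrosis_fraction(rep(5L, 10))))
})

test_that("Pearson correlation matches the hand-computed sample value", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  # x = (1,2,3,4), y = (1,3,2,4): cov = 1.333, sd = 1.291 each
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_true(is.na(pearson_r(rep(1, 5), 1:5)$r))
})

test_that("unpaired t-test is symmetric and null on identical groups", {
  a <- c(1.2, 0.8, 1.1, 0.9)
  t0 <- unpaired_ttest(a, a)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  set.seed(5)
  g1 <- stats::rnorm(10); g2 <- stats::rnorm(10, 10)
  t1 <- unpaired_ttest(g1, g2)
  t2 <- unpaired_ttest(g2, g1)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
  expect_lt(t1$p, 0.001)
  expect_error(unpaired_ttest(1, g2), "at least 2")
})

test_that("TUNEL thresholding is strict below 0.78 and inclusive above", {
  img <- array(0.5, c(2, 2, 3))
  img[, , 3] <- matrix(c(0.50, 0.78, 0.779999, 0.90), 2, 2)
  lab <- segment_tunel(img, matrix(1, 2, 2))
  expect_equal(as.vector(lab), c(1L, 2L, 1L, 2L))
  # crop mask excludes pixels entirely
  lab2 <- segment_tunel(img, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(sum(lab2 > 0), 1L)
  img[1, 1, 1] <- 1.5
  expect_error(segment_tunel(img, matrix(1, 2, 2)), "rescale")
})

test_that("accuracy with optimal matching undoes a label permutation", {
  set.seed(6)
  truth <- matrix(sample(1:5, 100, TRUE), 10, 10)
  perm <- c(2L, 3L, 4L, 5L, 1L)
  pred <- matrix(perm[truth], 10, 10)
  expect_lt(segmentation_accuracy(pred, truth), 0.1)
  expect_equal(segmentation_accuracy(pred, truth, match = "best"), 1)
})
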