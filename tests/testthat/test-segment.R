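fake_gmm <- function(means) {
  k <- nrow(means); d <- ncol(means)
  structure(list(k = k, d = d, weights = rep(1 / k, k), means = means,
                 covs = array(diag(d), c(d, d, k)), loglik = 0, bic = 0,
                 n_obs = 100, seed = 1), class = "stx_gmm")
}

test_that("label assignment follows the published rule set", {
  means <- rbind(c(5, 1, 2), c(0, -2, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 2, 0))
  asg <- assign_cluster_labels(fake_gmm(means))
  # blood is the |IC1| extreme; the rest are ranked by IC2
  expect_equal(asg$assignment, c(3L, 5L, 4L, 2L, 1L))
  expect_equal(asg$signs, c(1, 1, 1))
})

test_that("reflection places blood in the all-positive orthant before ranking", {
  means <- rbind(c(-5, -1, 2), c(0, -2, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 2, 0))
  asg <- assign_cluster_labels(fake_gmm(means))
  expect_equal(asg$signs, c(-1, -1, 1))
  expect_true(all(asg$means_reflected[1, ] >= 0))
  # ranks are computed on the reflected IC2: cluster 5 is now most negative
  expect_equal(asg$assignment, c(3L, 1L, 2L, 4L, 5L))
})

test_that("the rule set is defined for exactly five clusters", {
  expect_error(assign_cluster_labels(fake_gmm(matrix(1:8, 4, 2))), "5")
})

test_that("observation matrix pools in-mask voxels across subjects", {
  f1 <- matrix(stats::rnorm(20), 10, 2,
               dimnames = list(NULL, c("t1_norm", "t2_norm")))
  f2 <- matrix(stats::rnorm(40), 20, 2,
               dimnames = list(NULL, c("t1_norm", "t2_norm")))
  pa <- fake_preproc("a", 10, f1)
  pb <- fake_preproc("b", 20, f2)
  m <- build_observation_matrix(list(pa, pb), c("t1_norm", "t2_norm"))
  expect_equal(dim(m), c(30L, 2L))
  expect_equal(unname(m[1:10, ]), unname(f1))
  ri <- attr(m, "row_index")
  expect_equal(table(ri$subject_id), table(c(rep("a", 10), rep("b", 20))))
  expect_error(build_observation_matrix(list(pa), c("t1_norm", "nope")),
               "nope")
})

test_that("the optimized protocol exposes 24 image types", {
  sc <- small_cohort()
  feats <- protocol_features(sc$preprocs[[1]], "optimized")
  expect_length(feats, 24)
  expect_true(all(c("t1_norm", "t2_norm") %in% feats))
  expect_length(protocol_features(sc$preprocs[[1]], "t1t2_all"), 2 + 132 + 22)
  expect_error(stx_segment(sc$preprocs, "t1t2", n_ics = 3),
               "equal to or greater")
})

test_that("segmentation is deterministic and invariant to subject order", {
  sc <- small_cohort()
  a <- stx_segment(sc$preprocs, "optimized", n_ics = 3, seed = 2,
                   n_init = 3)
  b <- stx_segment(sc$preprocs, "optimized", n_ics = 3, seed = 2,
                   n_init = 3)
  expect_identical(a$label_maps, b$label_maps)
  shuffled <- stx_segment(sc$preprocs[c(3, 1, 5, 2, 4)], "optimized",
                          n_ics = 3, seed = 2, n_init = 3)
  for (id in names(a$label_maps)) {
    expect_identical(shuffled$label_maps[[id]], a$label_maps[[id]])
  }
})

test_that("every in-mask voxel receives a tissue label", {
  sc <- small_cohort()
  seg <- stx_segment(sc$preprocs, "optimized", n_ics = 3, seed = 2,
                     n_init = 3)
  for (i in seq_along(sc$preprocs)) {
    lm <- seg$label_maps[[i]]
    idx <- sc$preprocs[[i]]$mask_idx
    expect_true(all(lm[idx] %in% 1:5))
    expect_true(all(lm[-idx] == 0))
  }
  # predicting a training subject reproduces its labels
  expect_identical(predict(seg, sc$preprocs[[1]]), seg$label_maps[[1]])
  # blood/edema mean is component-wise non-negative after reflection
  expect_true(all(seg$means_reflected[which(seg$assignment == 3), ] >= 0))
})

test_that("leave-one-out on duplicated subjects reproduces the reference", {
  # five well-separated clusters: the mixture optimum is unambiguous, so
  # retraining on any duplicate subset must give identical labels
  set.seed(9)
  mu <- rbind(c(12, 0, 0, 1), c(0, 10, 0, 0), c(0, 0, 14, 2),
              c(6, 6, 0, 0), c(0, 5, 8, 3))
  feats <- do.call(rbind, lapply(1:5, function(j) {
    sweep(matrix(stats::rnorm(160 * 4, 0, 0.3), 160, 4), 2, mu[j, ], `+`)
  }))
  colnames(feats) <- c("t1_norm", "t2_norm", "f3", "f4")
  p <- fake_preproc("orig", 800, feats)
  trio <- list(p, p, p)
  trio[[2]]$subject_id <- "copy2"
  trio[[3]]$subject_id <- "copy3"
  loo <- leave_one_out(trio, colnames(feats), n_ics = 3, seed = 1,
                       n_init = 3)
  expect_equal(nrow(loo), 3L)
  expect_equal(loo$dice, rep(1, 3))
})

test_that("protocol optimization reports feasibility and correlations", {
  sc <- small_cohort()
  # reference fractions equal to one combination's own output make that
  # combination correlate perfectly
  seg_ref <- stx_segment(sc$preprocs, "high_b1", n_ics = 2, seed = 1,
                         n_init = 2)
  nf_ref <- unname(summary(seg_ref)$necrosis_fraction)
  res <- optimize_protocol(sc$preprocs, nf_ref,
                           protocols = c("t1t2", "high_b1"),
                           ics_range = 2:3, seed = 1, n_init = 2)
  tab <- res$table
  # two maps cannot support three ICs
  expect_true(is.na(tab$rho[tab$protocol == "t1t2" & tab$n_ics == 3]))
  expect_equal(tab$rho[tab$protocol == "high_b1" & tab$n_ics == 2], 1)
  expect_equal(res$best_protocol, "high_b1")
  expect_equal(res$best_n_ics, 2)
})

test_that("feature selection scores the full pool as a perfect subset", {
  sc <- small_cohort()
  ref <- stx_segment(sc$preprocs, "optimized", n_ics = 3, seed = 1,
                     n_init = 3)
  pool <- ref$features[1:5]
  ref5 <- stx_segment(sc$preprocs, pool, n_ics = 3, seed = 1, n_init = 3)
  fs <- feature_select(sc$preprocs, ref5$label_maps, subset_sizes = 5,
                       pool = pool, n_ics = 3, seed = 1, n_init = 3)
  expect_equal(fs$best$dice, 1)
  expect_equal(fs$best$ppv_tumour, 1)
  expect_equal(fs$best$npv_necrosis, 1)
  expect_equal(nrow(fs$evaluated[["5"]]), 1L)
})
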