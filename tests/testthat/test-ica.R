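test_that("ICA recovers independent heavy-tailed sources up to sign/permutation", {
  set.seed(42)
  S <- matrix(stats::rexp(3000 * 3) * sample(c(-1, 1), 9000, TRUE), 3000, 3)
  A <- matrix(stats::rnorm(18), 3, 6)
  X <- S %*% A
  ic <- fit_ica(X, 3, seed = 7)
  sc <- project_ica(ic, X)
  cc <- abs(stats::cor(sc, S))
  # every source matched by exactly one component
  expect_true(all(apply(cc, 2, max) >= 0.99))
  expect_equal(sort(apply(cc, 2, which.max)), 1:3)
})

test_that("ICA inverts a rotation of two independent uniforms at k = n = 2", {
  set.seed(8)
  S <- matrix(stats::runif(4000 * 2, -1, 1), 4000, 2)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  X <- S %*% R
  ic <- fit_ica(X, 2, seed = 3)
  cc <- abs(stats::cor(project_ica(ic, X), S))
  expect_true(all(apply(cc, 2, max) >= 0.99))
})

test_that("component count is capped by the number of image types", {
  X <- matrix(stats::rnorm(200), 100, 2)
  expect_error(fit_ica(X, 3), "image")
})

test_that("ICA transforms are deterministic and portable to new data", {
  set.seed(1)
  X <- matrix(stats::rnorm(500 * 4), 500, 4) %*% matrix(stats::rnorm(16), 4)
  a <- fit_ica(X, 2, seed = 5)
  b <- fit_ica(X, 2, seed = 5)
  expect_identical(a$unmixing, b$unmixing)
  # stored transform reproduces training scores on a held-out slice
  sc_all <- project_ica(a, X)
  expect_equal(project_ica(a, X[1:10, ]), sc_all[1:10, ])
})

test_that("NMI ordering ranks components by relatedness to the mean image", {
  set.seed(33)
  n <- 1e4
  # two independent non-Gaussian sources mixed so that the second cancels
  # from the channel mean: the mean image equals source 1, and the IC
  # recovering source 2 is statistically independent of it
  s1 <- sample(c(-2, 2), n, TRUE) + 0.3 * stats::rnorm(n)
  s2 <- stats::rexp(n) * sample(c(-1, 1), n, TRUE)
  X <- cbind(s1 + s2, s1 - s2)
  ic <- fit_ica(X, 2, seed = 1)
  ic <- order_components(ic, X)
  expect_true(all(diff(ic$mi_scores) >= 0))
  sc <- project_ica(ic, X)
  # the last (most informative) component tracks the mean image
  expect_gt(abs(stats::cor(sc[, 2], rowMeans(X))), 0.9)
  expect_gt(ic$mi_scores[2], 0.5)
  # the first is the independent source
  expect_lt(ic$mi_scores[1], 0.05)
})

test_that("NMI handles identical and constant signals", {
  a <- stats::rnorm(5000)
  expect_equal(stxseg:::.nmi(a, a), 1)
  expect_equal(stxseg:::.nmi(rep(1, 100), a[1:100]), 0)
  expect_lt(stxseg:::.nmi(a, stats::rnorm(5000)), 0.05)
})
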