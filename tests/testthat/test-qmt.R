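tumour_params <- function() qmt_params(2200, 53, 25, 1.2 / 25, 8.2)

test_that("two-pool Z reduces to the direct-saturation closed form at m0b = 0", {
  p <- qmt_params(2000, 100, 25, 0, 10)
  offs <- c(0.2, 1, 3, 10, 48)
  z <- two_pool_z(p, 0.5, offs)
  s <- steady_state_de_signal(ppm_to_angular(offs, 7), 2, 0.1,
                              b1_to_omega1(0.5))
  expect_equal(z, s, tolerance = 1e-12)
})

test_that("direct-saturation signal matches hand-evaluated values", {
  # omega1 = 0 leaves the magnetization untouched
  expect_equal(steady_state_de_signal(1000, 2, 0.1, 0, s0 = 3), 3)
  # T1 = 2000 ms, T2 = 100 ms, B1 = 0.1 uT on resonance:
  # S/S0 = R1 R2^2/(R1 R2^2 + w1^2 R2) with w1 = 26.75 rad/s
  w1 <- b1_to_omega1(0.1)
  expect_equal(steady_state_de_signal(0, 2, 0.1, w1),
               (0.5 * 100) / (0.5 * 100 + w1^2 * 10), tolerance = 1e-12)
  # monotone in |offset|
  s <- steady_state_de_signal(ppm_to_angular(seq(0, 5, 0.5), 7), 2, 0.1, w1)
  expect_true(all(diff(s) > 0))
})

test_that("closed-form Z agrees with the ODE steady state", {
  p <- tumour_params()
  expect_equal(two_pool_z(p, c(0.5, 3, 6), c(300, 48, 10)),
               two_pool_z_ode(p, c(0.5, 3, 6), c(300, 48, 10)),
               tolerance = 1e-6)
  # at 300 ppm and 0.5 uT saturation barely touches the water signal
  expect_gte(two_pool_z(p, 0.5, 300), 0.99)
})

test_that("observed-rate constraint matches the relaxation eigenvalue", {
  set.seed(42)
  for (i in 1:20) {
    r1obs <- runif(1, 0.3, 1.2)
    r <- runif(1, 5, 80)
    m0b <- runif(1, 0.01, 0.2)
    r1b <- 1
    r1a <- r1a_from_observed(r1obs, r, m0b, r1b)
    # slow eigenvalue of the longitudinal exchange matrix
    A <- matrix(c(-(r1a + r * m0b), r, r * m0b, -(r1b + r)), 2, 2,
                byrow = TRUE)
    expect_equal(min(abs(eigen(A)$values)), r1obs, tolerance = 1e-10)
  }
})

test_that("qmt_params enforces its invariants", {
  p <- tumour_params()
  expect_equal(p$rm0b, p$r_exchange_per_s * p$m0b)
  expect_error(qmt_params(-1, 53, 25, 0.05, 8.2))
  expect_error(qmt_params(2200, 53, 25, 1.2, 8.2))  # m0b >= 1
})

test_that("two-pool fit recovers generating parameters from clean spectra", {
  true <- tumour_params()
  sch <- stx_schedule()
  blocks <- lapply(c(1, 4, 5), function(bi) {
    b <- sch$blocks[[bi]]
    list(b1_uT = b$b1_uT, offsets_ppm = b$offsets_ppm,
         z = two_pool_z(true, b$b1_uT, b$offsets_ppm))
  })
  fit <- fit_qmt(blocks, 2200, n_voxels = 50)
  cf <- coef(fit)
  expect_lt(abs(cf[["rm0b"]] - 1.2) / 1.2, 0.05)
  expect_lt(abs(cf[["t2b_us"]] - 8.2) / 8.2, 0.05)
  expect_lt(abs(cf[["t2a_ms"]] - 53) / 53, 0.10)
  expect_true(fit$converged)
})

test_that("clusters below seven voxels are rejected from fitting", {
  expect_error(fit_qmt(list(), 2200, n_voxels = 6), "at least 7")
})

test_that("pairwise contrast offsets behave symmetrically and degenerately", {
  a <- tumour_params()
  b <- qmt_params(2600, 80, 25, 1.1 / 25, 7.8)
  same <- pairwise_contrast_offsets(a, a, 6)
  expect_identical(same$offset_ppm, NA_real_)
  expect_equal(same$max_diff, 0)
  ab <- pairwise_contrast_offsets(a, b, 6)
  ba <- pairwise_contrast_offsets(b, a, 6)
  expect_equal(ab$offset_ppm, ba$offset_ppm)
  expect_equal(ab$max_diff, ba$max_diff)
  expect_gt(ab$max_diff, 0)
})

test_that("AREX arithmetic follows the inverse-Z definitions", {
  expect_equal(mtr_arex(0.5, 0.8), 1 / 0.5 - 1 / 0.8)  # 0.75
  expect_equal(mtr_arex(0.7, 0.7), 0)
  expect_true(is.na(mtr_arex(-0.1, 0.5)))
  # z_lab below the reference implies a positive exchange contribution
  expect_gt(mtr_arex(0.6, 0.7), 0)
  expect_equal(arex(0.75, 2200), 0.75 / 2.2)
  expect_equal(arex(0, 1500), 0)
  expect_equal(arex(0.4, 1000), 2 * arex(0.4, 2000))
})

test_that("EMR reference equals the pure direct-saturation curve at m0b = 0", {
  p <- qmt_params(2000, 80, 25, 0, 10)
  offs <- seq(-5, 5, length.out = 21)
  expect_equal(emr_reference(p, 2, offs),
               steady_state_de_signal(ppm_to_angular(offs, 7), 2, 0.08,
                                      b1_to_omega1(2)),
               tolerance = 1e-12)
})
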