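test_that("phantoms are reproducible from their seed", {
  a <- make_phantom(seed = 3)
  b <- make_phantom(seed = 3)
  expect_identical(a$label_map, b$label_map)
  expect_identical(a$maps, b$maps)
  sch <- stx_schedule()
  expect_identical(simulate_zspectra(a, sch, seed = 9),
                   simulate_zspectra(b, sch, seed = 9))
})

test_that("label geometry honours the requested class fractions", {
  ph <- make_phantom(seed = 21)   # default necrosis share 0.03/0.12 = 0.25
  expect_true(abs(ph$true_necrosis_fraction - 0.25) <= 0.05)
  counts <- tabulate(ph$label_map[ph$label_map > 0], nbins = 5)
  expect_true(all(counts > 0))
  # removing a class removes its label entirely
  ph0 <- make_phantom(seed = 21,
                      class_fractions = c(active_tumour = 0.09,
                                          necrosis_apoptosis = 0.03,
                                          blood_edema = 0,
                                          muscle_connective = 0.05,
                                          muscle = 0.18))
  expect_equal(sum(ph0$label_map == 3), 0)
  # B0 field stays within its stated bound
  expect_lte(max(abs(ph$b0_ppm)), 0.3)
})

test_that("simulated spectra match the two-pool closed form without nuisances", {
  ph <- make_phantom(seed = 3, jitter_sd = 0, blood_jitter_sd = 0,
                     noise_sd = 0, drift_per_frame = 0, b0_max_ppm = 1e-9)
  ph$maps$amide_f[] <- 0; ph$maps$amine_f[] <- 0; ph$maps$noe_f[] <- 0
  idx <- which(ph$label_map == 1)[1:5]
  ref <- qmt_params(2200, 53, 25, 1.2 / 25, 8.2)
  for (off in c(300, 48, 10, 3)) {
    z <- stxseg:::.phantom_z(ph, idx, 6, off, 7)
    expect_equal(z, rep(two_pool_z(ref, 6, off), 5), tolerance = 1e-6)
  }
})

test_that("reference frames are nearly unsaturated", {
  cp <- clean_phantom()
  fr <- cp$study$frames
  idx <- which(cp$truth$label_map > 0)
  s0 <- cp$truth$s0[idx]
  for (i in which(fr$kind == "reference")[c(1, 10, 20)]) {
    z <- cp$study$images[, , i][idx] / s0
    expect_true(all(abs(z - 1) < 0.01))
  }
})

test_that("water saturation deepens with the semisolid pool size", {
  ph <- make_phantom(seed = 3, jitter_sd = 0, noise_sd = 0,
                     drift_per_frame = 0, b0_max_ppm = 1e-9)
  idx <- which(ph$label_map > 0)
  z1 <- stxseg:::.phantom_z(ph, idx, 6, 48, 7)
  ph$maps$m0b <- ph$maps$m0b * 1.5
  z2 <- stxseg:::.phantom_z(ph, idx, 6, 48, 7)
  expect_true(all(z2 < z1))
})

test_that("simulated noise level matches the configured noise_sd", {
  ph <- make_phantom(seed = 4)   # noise_sd = 0.01
  ph0 <- make_phantom(seed = 4, noise_sd = 0)
  sch <- stx_schedule()
  noisy <- simulate_zspectra(ph, sch, seed = 31)
  clean <- simulate_zspectra(ph0, sch, seed = 31)
  idx <- which(ph$label_map > 0)
  resid <- vapply(seq(1, 100), function(i) {
    (noisy[, , i][idx] - clean[, , i][idx]) / ph$s0[idx]
  }, numeric(length(idx)))
  expect_lt(abs(stats::sd(resid) - 0.01) / 0.01, 0.10)
})

test_that("IR series follows the signed full-inversion model", {
  ph <- make_phantom(seed = 6, noise_sd = 0, jitter_sd = 0)
  sch <- stx_schedule()
  ir <- simulate_ir_series(ph, sch)
  idx <- which(ph$label_map == 1)[1]
  t1 <- ph$maps$t1_obs_ms[idx]; s0 <- ph$s0[idx]
  expect_equal(ir[, , 5][idx] / s0, 1 - 2 * exp(-5000 / t1),
               tolerance = 1e-12)
  # TI = T1 log 2 nulls the signal
  sch0 <- stx_schedule(inversion_times_ms = c(100, t1 * log(2), 5000))
  ir0 <- simulate_ir_series(ph, sch0)
  expect_lt(abs(ir0[, , 2][idx]), 1e-9)
})

test_that("cohort generator produces the configured between-subject spread", {
  truths <- make_cohort(50, shape = c(24, 24), seed = 9,
                        between_subject_sd = 0.05, jitter_sd = 0)
  t1_tum <- vapply(truths, function(ph) {
    mean(ph$maps$t1_obs_ms[ph$label_map == 1])
  }, numeric(1))
  rel_sd <- stats::sd(t1_tum) / mean(t1_tum)
  expect_gt(rel_sd, 0.05 * 0.6)
  expect_lt(rel_sd, 0.05 * 1.6)
  # necrosis fractions span the requested range
  nf <- vapply(truths, `[[`, numeric(1), "true_necrosis_fraction")
  expect_gt(max(nf), 0.3); expect_lt(min(nf), 0.2)
})

test_that("TUNEL image renders the histology threshold by construction", {
  cp <- clean_phantom()
  tn <- simulate_tunel_image(cp$truth, upscale = 2)
  expect_true(all(tn$image >= 0 & tn$image <= 1))
  lab <- segment_tunel(tn$image, tn$crop_mask)
  got <- necrosis_fraction(lab)
  expect_lt(abs(got - cp$truth$true_necrosis_fraction), 0.02)
  # zero-necrosis phantom keeps every in-crop pixel below the threshold
  ph0 <- make_phantom(seed = 13,
                      class_fractions = c(active_tumour = 0.12,
                                          necrosis_apoptosis = 0,
                                          blood_edema = 0.015,
                                          muscle_connective = 0.05,
                                          muscle = 0.18))
  tn0 <- simulate_tunel_image(ph0, upscale = 2)
  expect_true(all(tn0$image[, , 3][tn0$crop_mask] < 0.78))
})
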