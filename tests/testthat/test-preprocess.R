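test_that("drift correction is the identity on drift-free data", {
  cp <- clean_phantom()
  out <- drift_correct(cp$study)
  # references at different block B1 carry minutely different residual
  # saturation, so the fitted line is flat only to that physical level
  expect_equal(out$images, cp$study$images, tolerance = 1e-3)
  expect_lt(abs(attr(out, "qc")$drift_slope_per_frame), 1e-6)
})

test_that("injected linear drift is removed by the reference fit", {
  cp <- clean_phantom()
  ph <- cp$truth
  ph$drift_per_frame <- -0.001
  st <- simulate_study(ph, cp$study$schedule)
  out <- drift_correct(st)
  # residual trend of the corrected in-mask reference means
  idx <- which(ph$label_map > 0)
  ref <- which(out$frames$kind == "reference")
  y <- vapply(ref, function(i) mean(out$images[, , i][idx]), numeric(1))
  y <- y / mean(y)
  slope <- stats::coef(stats::lm(y ~ out$frames$order[ref]))[2]
  expect_lt(abs(slope), 1e-4)
})

test_that("drift correction requires at least two references", {
  st <- clean_phantom()$study
  keep <- which(st$frames$kind == "reference")[1]
  drop <- setdiff(which(st$frames$kind == "reference"), keep)
  st2 <- st
  st2$frames <- st$frames[-drop, ]
  st2$images <- st$images[, , -drop]
  expect_error(drift_correct(st2), "reference")
})

test_that("WASSR B0 fit recovers known field offsets", {
  cp <- clean_phantom()
  for (shift in c(0, 0.10, 0.25)) {
    ph <- cp$truth
    ph$b0_ppm[] <- shift
    st <- simulate_study(ph, cp$study$schedule)
    b0 <- fit_wassr_b0(st)
    idx <- which(ph$label_map > 0)
    tol <- if (shift == 0) 1e-4 else if (shift == 0.10) 0.005 else 0.01
    expect_lt(stats::median(abs(b0[idx] - shift)), tol)
  }
})

test_that("two-Lorentzian recentring restores shifted low-B1 spectra", {
  cp <- clean_phantom()
  ph <- cp$truth
  st0 <- cp$study                      # unshifted truth
  ph$b0_ppm[] <- 0.2
  st <- simulate_study(ph, cp$study$schedule)
  b0 <- fit_wassr_b0(st)
  out <- b0_correct_low_b1(st, b0)
  idx <- which(ph$label_map > 0)
  z <- stxseg:::.study_z(out, idx)
  z0 <- stxseg:::.study_z(st0, idx)
  for (bi in 2:3) {   # the 0.5 and 2 uT blocks
    dev <- abs(z$blocks[[bi]]$z - z0$blocks[[bi]]$z)
    # interior offsets; the shifted edge is held, not extrapolated
    interior <- which(abs(z$blocks[[bi]]$offsets_ppm) < 4.5)
    expect_lt(stats::median(dev[, interior]), 0.01)
    expect_true(all(is.finite(dev)))
  }
  # a zero-shift voxelwise correction changes nothing beyond interpolation
  # error (checked on CEST-free spectra: asymmetric CEST dips genuinely
  # displace the fitted direct-effect centre by ~0.01 ppm)
  ph_sym <- cp$truth
  ph_sym$maps$amide_f[] <- 0; ph_sym$maps$amine_f[] <- 0
  ph_sym$maps$noe_f[] <- 0
  ph_sym$b0_ppm[] <- 0
  st_sym <- simulate_study(ph_sym, cp$study$schedule)
  z_sym <- stxseg:::.study_z(st_sym, idx)
  out0 <- b0_correct_low_b1(st_sym, matrix(0, 32, 32))
  zz <- stxseg:::.study_z(out0, idx)
  expect_lt(max(abs(zz$blocks[[3]]$z - z_sym$blocks[[3]]$z)), 1e-3)
})

test_that("T1 fitting recovers relaxation times to sub-percent accuracy", {
  tis <- c(30, 110, 390, 1400, 5000)
  mask <- matrix(1L, 2, 2)
  for (t1 in c(800, 2200)) {
    ir <- array(0, c(2, 2, 5))
    for (i in 1:5) ir[, , i] <- 1000 * (1 - 2 * exp(-tis[i] / t1))
    fit <- fit_t1_map(ir, tis, mask)
    tol <- if (t1 == 2200) 2 else 0.005 * 800
    expect_lt(max(abs(fit$t1_obs_ms - t1)), tol)
    expect_equal(fit$s0[1, 1], 1000, tolerance = 1e-3)
  }
  # a voxel with no recovery contrast is flagged
  ir <- array(500, c(2, 2, 5))
  fit <- fit_t1_map(ir, tis, mask)
  expect_equal(fit$n_flagged, 4L)
  expect_true(all(is.na(fit$t1_obs_ms)))
})

test_that("T2 fitting from the WASSR spectrum inverts the generator", {
  cp <- clean_phantom()
  st <- cp$study
  t2map <- fit_t2_from_wassr(st, cp$truth$maps$t1_obs_ms,
                             b0_map = cp$truth$b0_ppm)
  idx <- which(cp$truth$label_map == 1)
  err <- abs(t2map[idx] - cp$truth$maps$t2a_ms[idx])
  expect_lt(stats::median(err), 0.5)
  # doubling the true T2 doubles the recovered T2
  ph2 <- cp$truth
  ph2$maps$t2a_ms <- ph2$maps$t2a_ms * 2
  st2 <- simulate_study(ph2, st$schedule)
  t2b <- fit_t2_from_wassr(st2, ph2$maps$t1_obs_ms, b0_map = ph2$b0_ppm)
  ratio <- t2b[idx] / t2map[idx]
  expect_lt(abs(stats::median(ratio) - 2) / 2, 0.02)
})

test_that("flat WASSR spectra are flagged instead of fitted", {
  cp <- clean_phantom()
  st <- cp$study
  # overwrite the WASSR frames with the reference signal (no dip)
  wassr_frames <- which(st$frames$block == 1 & st$frames$kind == "zspec")
  for (i in wassr_frames) st$images[, , i] <- st$truth$s0
  t2 <- fit_t2_from_wassr(st, cp$truth$maps$t1_obs_ms)
  expect_equal(attr(t2, "n_flagged"), sum(st$mask))
})

test_that("relaxation maps normalize by 4000 and 300 ms", {
  n <- normalize_relaxation_maps(matrix(2200), matrix(300))
  expect_equal(n$t1_norm[1, 1], 0.55)
  expect_equal(n$t2_norm[1, 1], 1)
  expect_equal(normalize_relaxation_maps(matrix(0), matrix(1))$t1_norm[1, 1],
               0)
})

test_that("mask erosion strips exactly the 8-neighbour boundary", {
  m3 <- matrix(0L, 5, 5); m3[2:4, 2:4] <- 1L
  e3 <- erode_mask(m3)
  expect_equal(sum(e3), 1L)
  expect_equal(e3[3, 3], 1L)
  m4 <- matrix(0L, 6, 6); m4[2:5, 2:5] <- 1L
  e4 <- erode_mask(m4)
  expect_equal(which(e4 == 1L), which(matrix(seq_len(36), 6, 6) %in%
                                        c(15, 16, 21, 22)))
  expect_equal(sum(erode_mask(matrix(0L, 4, 4))), 0L)
  # subset property and boundary removal on a random blob
  set.seed(2)
  m <- matrix(rbinom(400, 1, 0.7), 20, 20)
  e <- erode_mask(m)
  expect_true(all(e <= m))
  boundary <- m == 1 & (row(m) %in% c(1, 20) | col(m) %in% c(1, 20))
  expect_true(all(e[boundary] == 0))
})

test_that("full preprocessing is near-identity on a nuisance-free phantom", {
  cp <- clean_phantom()
  ph <- cp$truth
  ph$b0_ppm[] <- 0
  st <- simulate_study(ph, cp$study$schedule)
  pp <- preprocess_study(st, correct_low_b1 = FALSE)
  idx <- pp$mask_idx
  expect_lt(stats::median(abs(pp$t1_ms[idx] - ph$maps$t1_obs_ms[idx]) /
                            ph$maps$t1_obs_ms[idx]), 0.01)
  expect_lt(stats::median(abs(pp$t2_ms[idx] - ph$maps$t2a_ms[idx]) /
                            ph$maps$t2a_ms[idx]), 0.01)
  # Z features reproduce the simulated Z values
  zb <- pp$zblocks[[5]]     # 6 uT block
  ztrue <- vapply(seq_along(zb$offsets_ppm), function(j) {
    stxseg:::.phantom_z(ph, idx, 6, zb$offsets_ppm[j], 7)
  }, numeric(length(idx)))
  expect_lt(max(abs(zb$z - ztrue)), 1e-3)
})
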