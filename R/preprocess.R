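# Preprocessing: interleaved-reference drift correction, WASSR and
# two-Lorentzian B0 correction, inversion-recovery T1 mapping, T2 from the
# WASSR spectrum via the steady-state direct-saturation signal, map
# normalization, mask erosion, and assembly of the normalized feature
# images used for segmentation.

#' Correct linear signal drift using the interleaved reference scans
#'
#' Fits a straight line to the mean in-mask intensity of the reference
#' frames against acquisition order and divides every frame by the fitted
#' line, rescaled to 1 at the first acquired frame.
#'
#' @param study an [stx_study].
#' @return the drift-corrected [stx_study]; the fitted relative drift
#'   slope per frame is recorded in `attr(, "qc")`.
#' @export
drift_correct <- function(study) {
  stopifnot(inherits(study, "stx_study"))
  ref <- which(study$frames$kind == "reference")
  if (length(ref) < 2) stop("at least 2 reference frames are required")
  idx <- which(study$mask > 0)
  y <- vapply(ref, function(i) mean(study$images[, , i][idx]), numeric(1))
  x <- study$frames$order[ref]
  fit <- stats::lm(y ~ x)
  x0 <- min(study$frames$order)
  line <- function(o) unname(stats::predict(fit, data.frame(x = o)))
  if (any(line(study$frames$order) <= 0)) {
    stop("fitted reference drift line is non-positive")
  }
  scale <- line(study$frames$order) / line(x0)
  out <- study
  for (i in seq_len(dim(study$images)[3])) {
    out$images[, , i] <- study$images[, , i] / scale[i]
  }
  attr(out, "qc") <- list(
    drift_slope_per_frame = unname(stats::coef(fit)[2] / line(x0)))
  out
}

# normalized Z data per block: S0 is the voxelwise mean of the reference
# frames (assumed drift-corrected); z matrices are n_mask_voxels x n_offsets
.study_z <- function(study, mask_idx = which(study$mask > 0)) {
  ref <- which(study$frames$kind == "reference")
  s0 <- matrix(0, dim(study$images)[1], dim(study$images)[2])
  for (i in ref) s0 <- s0 + study$images[, , i]
  s0 <- s0 / length(ref)
  blocks <- lapply(seq_along(study$schedule$blocks), function(bi) {
    b <- study$schedule$blocks[[bi]]
    fi <- which(study$frames$kind == "zspec" & study$frames$block == bi)
    fi <- fi[order(study$frames$offset_idx[fi])]
    z <- vapply(fi, function(i) study$images[, , i][mask_idx] / s0[mask_idx],
                numeric(length(mask_idx)))
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    list(b1_uT = b$b1_uT, role = b$role, offsets_ppm = b$offsets_ppm, z = z)
  })
  list(mask_idx = mask_idx, s0 = s0, blocks = blocks)
}

.lorentzian <- function(x, center, width) {
  width^2 / (width^2 + (x - center)^2)
}

#' Map the B0 offset field from the WASSR spectrum
#'
#' Fits `Z = 1 - A * G^2 / (G^2 + (offset - d0)^2)` (the direct-saturation
#' Lorentzian) to each in-mask voxel's WASSR Z-spectrum and returns the
#' fitted centre d0 as the per-voxel B0 offset. Voxels with a flat
#' spectrum (fitted amplitude below 0.05) are flagged and set to 0.
#'
#' @param study a drift-corrected [stx_study] with a WASSR block.
#' @return matrix of B0 offsets (ppm) with attribute `n_flagged`.
#' @export
fit_wassr_b0 <- function(study) {
  stopifnot(inherits(study, "stx_study"))
  zd <- .study_z(study)
  wi <- which(vapply(zd$blocks, `[[`, "", "role") == "wassr")
  if (!length(wi)) stop("no WASSR block in schedule")
  blk <- zd$blocks[[wi[1]]]
  off <- blk$offsets_ppm
  b0 <- matrix(0, dim(study$images)[1], dim(study$images)[2])
  n_flagged <- 0L
  for (v in seq_along(zd$mask_idx)) {
    z <- blk$z[v, ]
    init <- c(d0 = off[which.min(z)], a = max(1 - min(z), 0.05), g = 0.1)
    fit <- try(minpack.lm::nls.lm(
      par = init,
      lower = c(d0 = min(off), a = 0.01, g = 0.02),
      upper = c(d0 = max(off), a = 1.5, g = 1),
      fn = function(p) 1 - p["a"] * .lorentzian(off, p["d0"], p["g"]) - z,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error") || fit$par[["a"]] < 0.05) {
      n_flagged <- n_flagged + 1L
    } else {
      b0[zd$mask_idx[v]] <- fit$par[["d0"]]
    }
  }
  attr(b0, "n_flagged") <- n_flagged
  b0
}

# shift a spectrum to remove a d0 offset: the measured spectrum is
# Z_meas(o) = Z_true(o - d0), so Z_true is the measured curve interpolated
# at o + d0; edge values are held (no extrapolation)
.recentre <- function(offsets, z, d0) {
  stats::approx(offsets, z, xout = offsets + d0, rule = 2)$y
}

#' B0-correct the WASSR and low-B1 Z-spectra
#'
#' Low-B1 spectra are recentred voxel-by-voxel to the centre of the
#' direct-effect Lorentzian of a two-Lorentzian (direct effect + broad MT
#' baseline) fit; the WASSR block is recentred by the supplied WASSR B0
#' map. Spectra are shifted and linearly re-interpolated onto the original
#' offset grid with edge values held. High-B1 blocks, whose offsets start
#' at 3 ppm, are untouched. Voxels whose two-Lorentzian fit fails fall
#' back to the WASSR shift and are counted in `attr(, "qc")$n_fallback`.
#'
#' @param study a drift-corrected [stx_study].
#' @param b0_map WASSR B0 map from [fit_wassr_b0()], ppm.
#' @param roi optional logical/integer matrix restricting the corrected
#'   voxels of the low-B1 blocks (e.g. a tumour mask); others keep their
#'   measured spectra. The WASSR recentring always covers the whole mask.
#' @param roles block roles to correct.
#' @return the corrected [stx_study].
#' @export
b0_correct_low_b1 <- function(study, b0_map, roi = NULL,
                              roles = c("wassr", "low_b1")) {
  stopifnot(inherits(study, "stx_study"))
  mask_all <- which(study$mask > 0)
  mask_roi <- if (is.null(roi)) mask_all else
    intersect(mask_all, which(roi > 0))
  out <- study
  n_fallback <- 0L
  for (bi in seq_along(study$schedule$blocks)) {
    role_bi <- study$schedule$blocks[[bi]]$role
    if (!role_bi %in% roles || role_bi == "high_b1") next
    mask_idx <- if (role_bi == "wassr") mask_all else mask_roi
    zd <- .study_z(study, mask_idx)
    blk <- zd$blocks[[bi]]
    off <- blk$offsets_ppm
    fi <- which(study$frames$kind == "zspec" & study$frames$block == bi)
    fi <- fi[order(study$frames$offset_idx[fi])]
    znew_all <- blk$z
    for (v in seq_along(mask_idx)) {
      z <- blk$z[v, ]
      d0_w <- b0_map[mask_idx[v]]
      if (blk$role == "wassr") {
        d0 <- d0_w
      } else {
        init <- c(d0 = d0_w, a1 = max(1 - min(z), 0.05), g1 = 1,
                  a2 = 0.1, g2 = 30)
        fit <- try(minpack.lm::nls.lm(
          par = init,
          lower = c(d0 = -0.5, a1 = 0, g1 = 0.2, a2 = 0, g2 = 5),
          upper = c(d0 = 0.5, a1 = 1.2, g1 = 5, a2 = 1, g2 = 400),
          fn = function(p) {
            1 - p["a1"] * .lorentzian(off, p["d0"], p["g1"]) -
              p["a2"] * .lorentzian(off, p["d0"], p["g2"]) - z
          },
          control = minpack.lm::nls.lm.control(maxiter = 100)),
          silent = TRUE)
        if (inherits(fit, "try-error") || !fit$info %in% 1:3) {
          d0 <- d0_w
          n_fallback <- n_fallback + 1L
        } else {
          d0 <- fit$par[["d0"]]
        }
      }
      znew_all[v, ] <- .recentre(off, z, d0)
    }
    # write back on the raw signal scale (Z times the reference S0)
    for (j in seq_along(fi)) {
      img <- out$images[, , fi[j]]
      img[mask_idx] <- znew_all[, j] * zd$s0[mask_idx]
      out$images[, , fi[j]] <- img
    }
  }
  attr(out, "qc") <- c(attr(study, "qc"), list(n_fallback = n_fallback))
  out
}

#' Fit a T1 map from the inversion-recovery series
#'
#' Per-voxel least-squares fit of the signed three-parameter model
#' `S(TI) = a + b * exp(-TI / T1)` (a coarse log-grid search over T1 with
#' the linear parameters profiled out, refined by 1D minimization).
#' Voxels without recovery contrast (`b >= 0`) or with a degenerate fit
#' are flagged (`T1 = NA`).
#'
#' @param ir 3D array (x, y, TI) of signed IR images.
#' @param inversion_times_ms inversion times, ms (at least 3).
#' @param mask matrix of voxels to fit.
#' @return list with matrices `t1_obs_ms` and `s0` (= the plateau value
#'   `a`), and `n_flagged`.
#' @export
fit_t1_map <- function(ir, inversion_times_ms, mask) {
  stopifnot(length(inversion_times_ms) >= 3,
            dim(ir)[3] == length(inversion_times_ms))
  idx <- which(mask > 0)
  Y <- vapply(seq_along(inversion_times_ms),
              function(i) ir[, , i][idx], numeric(length(idx)))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  ti <- inversion_times_ms
  nti <- length(ti)
  rss_at <- function(t1) {
    e <- exp(-ti / t1)
    se <- sum(e); see <- sum(e^2)
    ybar <- rowMeans(Y)
    ye <- Y %*% e
    denom <- see - se^2 / nti
    b <- (ye - se * ybar) / denom
    a <- ybar - b * se / nti
    rowSums(Y^2) + nti * a^2 + b^2 * see + 2 * a * b * se -
      2 * a * nti * ybar - 2 * b * ye
  }
  grid <- exp(seq(log(30), log(8000), length.out = 60))
  rss <- vapply(grid, rss_at, numeric(nrow(Y)))
  if (is.null(dim(rss))) rss <- matrix(rss, nrow = 1)
  best <- max.col(-rss)
  t1v <- numeric(nrow(Y)); s0v <- numeric(nrow(Y)); bad <- logical(nrow(Y))
  for (v in seq_len(nrow(Y))) {
    lo <- grid[max(best[v] - 1, 1)]
    hi <- grid[min(best[v] + 1, length(grid))]
    y <- Y[v, ]
    f <- function(t1) {
      e <- exp(-ti / t1)
      r <- stats::lm.fit(cbind(1, e), y)
      sum(r$residuals^2)
    }
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-4)
    e <- exp(-ti / opt$minimum)
    cf <- stats::lm.fit(cbind(1, e), y)$coefficients
    if (!is.finite(cf[2]) || cf[2] >= 0) {
      bad[v] <- TRUE
      t1v[v] <- NA_real_; s0v[v] <- cf[1]
    } else {
      t1v[v] <- opt$minimum; s0v[v] <- cf[1]
    }
  }
  t1 <- matrix(NA_real_, nrow(mask), ncol(mask))
  s0 <- matrix(NA_real_, nrow(mask), ncol(mask))
  t1[idx] <- t1v; s0[idx] <- s0v
  list(t1_obs_ms = t1, s0 = s0, n_flagged = sum(bad))
}

#' Steady-state direct water saturation signal
#'
#' \deqn{S = S_0 \frac{R_1 (R_2^2 + \Delta\omega^2)}
#'   {R_1 (R_2^2 + \Delta\omega^2) + \omega_1^2 R_2}}
#'
#' @param d_omega offset(s) from water, rad/s.
#' @param t1_s,t2_s relaxation times, seconds.
#' @param omega1 saturation nutation rate, rad/s.
#' @param s0 equilibrium signal.
#' @return steady-state signal(s).
#' @export
steady_state_de_signal <- function(d_omega, t1_s, t2_s, omega1, s0 = 1) {
  stopifnot(all(t1_s > 0), all(t2_s > 0))
  r1 <- 1 / t1_s; r2 <- 1 / t2_s
  s0 * r1 * (r2^2 + d_omega^2) / (r1 * (r2^2 + d_omega^2) + omega1^2 * r2)
}

#' Fit a T2 map from the WASSR spectrum and the T1 map
#'
#' Per in-mask voxel, least-squares fit of the steady-state
#' direct-saturation signal over the WASSR offsets with R1 fixed from the
#' T1 map; free parameters are R2 and a scale. If a B0 map is supplied the
#' dip centre is fixed at the voxel's delta0 and the fit runs on the
#' uncorrected spectrum — the WASSR dip is only about twice as wide as the
#' offset spacing, so this preserves more information than re-interpolating
#' a recentred spectrum. Voxels without a saturation dip (depth < 0.05)
#' are flagged.
#'
#' @param study a drift-corrected [stx_study].
#' @param t1_obs_map T1 map, ms.
#' @param b0_map optional WASSR B0 map (ppm) giving the fixed dip centre
#'   per voxel; without it the spectrum is assumed already centred.
#' @return matrix of T2 (ms) with attribute `n_flagged`.
#' @export
fit_t2_from_wassr <- function(study, t1_obs_map, b0_map = NULL) {
  stopifnot(inherits(study, "stx_study"))
  zd <- .study_z(study)
  wi <- which(vapply(zd$blocks, `[[`, "", "role") == "wassr")
  if (!length(wi)) stop("no WASSR block in schedule")
  blk <- zd$blocks[[wi[1]]]
  if (blk$b1_uT <= 0) stop("WASSR block has zero B1: no saturation information")
  w1 <- b1_to_omega1(blk$b1_uT)
  idx <- zd$mask_idx
  r1 <- 1000 / t1_obs_map[idx]
  d0 <- if (is.null(b0_map)) numeric(length(idx)) else b0_map[idx]
  # per-voxel effective offsets (dip centre fixed at delta0)
  dwm <- ppm_to_angular(
    outer(d0, blk$offsets_ppm, function(a, b) b - a),
    study$schedule$field_T)
  Y <- blk$z
  t2 <- matrix(NA_real_, nrow(study$mask), ncol(study$mask))
  n_flagged <- 0L
  # coarse vectorized grid over T2 with the scale profiled out
  grid <- exp(seq(log(5), log(400), length.out = 60))
  rss <- matrix(Inf, nrow(Y), length(grid))
  for (gi in seq_along(grid)) {
    r2 <- 1000 / grid[gi]
    Fm <- r1 * (r2^2 + dwm^2) / (r1 * (r2^2 + dwm^2) + w1^2 * r2)
    s0h <- rowSums(Y * Fm) / rowSums(Fm^2)
    rss[, gi] <- rowSums(Y^2) - s0h^2 * rowSums(Fm^2)
  }
  best <- max.col(-rss)
  for (v in seq_len(nrow(Y))) {
    y <- Y[v, ]
    if (1 - min(y) < 0.05 || !is.finite(r1[v])) {
      n_flagged <- n_flagged + 1L
      next
    }
    dwv <- dwm[v, ]
    f <- function(t2_ms) {
      r2 <- 1000 / t2_ms
      fv <- r1[v] * (r2^2 + dwv^2) / (r1[v] * (r2^2 + dwv^2) + w1^2 * r2)
      s0h <- sum(y * fv) / sum(fv^2)
      sum((y - s0h * fv)^2)
    }
    lo <- grid[max(best[v] - 1, 1)]; hi <- grid[min(best[v] + 1, length(grid))]
    t2[idx[v]] <- stats::optimize(f, c(lo, hi), tol = 1e-5)$minimum
  }
  attr(t2, "n_flagged") <- n_flagged
  t2
}

#' Normalize T1 and T2 maps to the Z-image range
#'
#' Divides T1 by 4000 ms and T2 by 300 ms — values slightly above the
#' largest seen in tumours — so the maps share the 0..1 scale of the
#' normalized saturation images.
#'
#' @param t1_obs_ms,t2_ms relaxation maps, ms.
#' @return list with `t1_norm` and `t2_norm`.
#' @export
normalize_relaxation_maps <- function(t1_obs_ms, t2_ms) {
  list(t1_norm = t1_obs_ms / 4000, t2_norm = t2_ms / 300)
}

#' Binary mask erosion with the 3x3 all-neighbour structuring element
#'
#' A pixel survives iff it and all 8 neighbours are set; this strips every
#' boundary pixel, removing partial-volume-contaminated edge voxels.
#'
#' @param mask binary matrix.
#' @return eroded binary (integer) matrix.
#' @export
erode_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  out <- matrix(1L, nrow(m), ncol(m))
  for (di in 0:2) {
    for (dj in 0:2) {
      out <- out & p[di + seq_len(nrow(m)), dj + seq_len(ncol(m))]
    }
  }
  matrix(as.integer(out), nrow(m), ncol(m))
}

#' Preprocess a study into segmentation-ready feature images
#'
#' Runs the full preprocessing chain: drift correction, WASSR B0 mapping,
#' B0 recentring of the WASSR and low-B1 spectra, T1 and T2 mapping, map
#' normalization and mask erosion, and assembles the per-voxel feature
#' matrix (normalized T1/T2 plus one normalized Z image per saturation
#' measurement) over the eroded mask.
#'
#' @param study an [stx_study].
#' @param correct_low_b1 fit the two-Lorentzian B0 recentring of the
#'   low-B1 blocks (needed for CEST/AREX analyses; the high-B1 blocks and
#'   maps used for segmentation do not require it).
#' @param low_b1_roi optional matrix restricting the low-B1 correction to
#'   a region of interest.
#' @return object of class `stx_preproc`.
#' @export
preprocess_study <- function(study, correct_low_b1 = TRUE,
                             low_b1_roi = NULL) {
  stopifnot(inherits(study, "stx_study"))
  dc <- drift_correct(study)
  qc <- attr(dc, "qc")
  b0 <- fit_wassr_b0(dc)
  qc$n_b0_flagged <- attr(b0, "n_flagged")
  t1fit <- fit_t1_map(dc$ir, dc$schedule$inversion_times_ms, dc$mask)
  qc$n_t1_flagged <- t1fit$n_flagged
  # T2 before recentring: the fit takes the dip centre from the B0 map
  t2 <- fit_t2_from_wassr(dc, t1fit$t1_obs_ms, b0)
  roles <- if (correct_low_b1) c("wassr", "low_b1") else "wassr"
  dc <- b0_correct_low_b1(dc, b0, roi = low_b1_roi, roles = roles)
  qc$n_fallback <- attr(dc, "qc")$n_fallback
  qc$n_t2_flagged <- attr(t2, "n_flagged")
  norms <- normalize_relaxation_maps(t1fit$t1_obs_ms, t2)
  eroded <- erode_mask(dc$mask)
  mask_idx <- which(eroded > 0)
  zd <- .study_z(dc, mask_idx)

  feats <- list(t1_norm = norms$t1_norm[mask_idx],
                t2_norm = norms$t2_norm[mask_idx])
  info <- data.frame(name = c("t1_norm", "t2_norm"),
                     type = "map", role = "map",
                     b1_uT = NA_real_, offset_ppm = NA_real_,
                     stringsAsFactors = FALSE)
  for (bi in seq_along(zd$blocks)) {
    blk <- zd$blocks[[bi]]
    if (blk$role == "wassr") next
    for (j in seq_along(blk$offsets_ppm)) {
      nm <- sprintf("b%g_%0.5gppm", blk$b1_uT, blk$offsets_ppm[j])
      feats[[nm]] <- blk$z[, j]
      info <- rbind(info, data.frame(name = nm, type = "zspec",
                                     role = blk$role, b1_uT = blk$b1_uT,
                                     offset_ppm = blk$offsets_ppm[j],
                                     stringsAsFactors = FALSE))
    }
  }
  features <- do.call(cbind, feats)
  rownames(features) <- NULL

  structure(list(
    subject_id = study$subject_id,
    schedule = study$schedule,
    shape = dim(study$mask),
    mask = study$mask,
    eroded_mask = eroded,
    mask_idx = mask_idx,
    features = features,
    feature_info = info,
    t1_ms = t1fit$t1_obs_ms,
    t2_ms = t2,
    s0 = t1fit$s0,
    b0_ppm = b0,
    zblocks = zd$blocks,
    qc = qc,
    truth = study$truth
  ), class = "stx_preproc")
}

#' @export
print.stx_preproc <- function(x, ...) {
  cat(sprintf("stx_preproc '%s': %d eroded-mask voxels, %d features\n",
              x$subject_id, length(x$mask_idx), ncol(x$features)))
  invisible(x)
}
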