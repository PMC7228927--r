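# Isolation of aggregate CEST and relayed-NOE contributions: the fitted
# two-pool MT parameters predict a CEST-free reference Z-spectrum (the
# extrapolated MT reference, EMR); inverse-Z subtraction against the
# measured low-B1 spectrum gives MTR_AREX, and division by T1,obs the
# T1-compensated AREX rate.

#' Extrapolated MT reference spectrum
#'
#' Evaluates the fitted two-pool MT model at the requested offsets and
#' B1: a Z-spectrum containing the semisolid MT and direct-saturation
#' contributions only, used as the CEST-free baseline.
#'
#' @param params a [qmt_params] object (typically from [fit_qmt()]).
#' @param b1_uT saturation amplitude, microtesla.
#' @param offsets_ppm offsets, ppm.
#' @param field_T static field, tesla.
#' @return Z values.
#' @export
emr_reference <- function(params, b1_uT, offsets_ppm, field_T = 7) {
  two_pool_z(params, b1_uT, offsets_ppm, field_T)
}

#' Inverse-Z magnetization transfer ratio
#'
#' \deqn{MTR_{AREX} = 1/Z_{lab} - 1/Z_{EMR}}
#'
#' @param z_lab measured Z values.
#' @param z_emr extrapolated MT reference Z values.
#' @return MTR_AREX values; `NA` where either Z is non-positive.
#' @export
mtr_arex <- function(z_lab, z_emr) {
  out <- 1 / z_lab - 1 / z_emr
  out[z_lab <= 0 | z_emr <= 0] <- NA_real_
  out
}

#' Apparent exchange-dependent relaxation
#'
#' \deqn{AREX = MTR_{AREX} / T_{1,obs}} with T1 in seconds, giving a
#' rate in 1/s compensated for T1 differences.
#'
#' @param mtr_value MTR_AREX value(s).
#' @param t1_obs_ms observed T1, ms.
#' @return AREX rate(s), 1/s.
#' @export
arex <- function(mtr_value, t1_obs_ms) {
  stopifnot(all(t1_obs_ms > 0))
  mtr_value / (t1_obs_ms / 1000)
}

#' Assemble an AREX spectrum
#'
#' @param params fitted [qmt_params] for the cluster.
#' @param offsets_ppm offsets of the measured low-B1 spectrum.
#' @param z_lab measured Z values at those offsets.
#' @param b1_uT saturation amplitude of the measurement.
#' @param t1_obs_ms observed T1 of the cluster, ms.
#' @param field_T static field.
#' @return object of class `arex_spectrum` with `z_lab`, `z_emr`,
#'   `mtr_arex` and `arex_per_s`.
#' @export
arex_spectrum <- function(params, offsets_ppm, z_lab, b1_uT, t1_obs_ms,
                          field_T = 7) {
  stopifnot(length(offsets_ppm) == length(z_lab))
  z_emr <- emr_reference(params, b1_uT, offsets_ppm, field_T)
  mtr <- mtr_arex(z_lab, z_emr)
  structure(list(
    offsets_ppm = offsets_ppm, z_lab = z_lab, z_emr = z_emr,
    mtr_arex = mtr, arex_per_s = arex(mtr, t1_obs_ms),
    b1_uT = b1_uT, t1_obs_ms = t1_obs_ms
  ), class = "arex_spectrum")
}

#' @export
print.arex_spectrum <- function(x, ...) {
  cat(sprintf("AREX spectrum at B1 = %g uT over %d offsets (T1,obs = %.0f ms)\n",
              x$b1_uT, length(x$offsets_ppm), x$t1_obs_ms))
  invisible(x)
}

#' @export
plot.arex_spectrum <- function(x, ...) {
  graphics::plot(x$offsets_ppm, x$arex_per_s, type = "l",
                 xlab = "offset (ppm)", ylab = "AREX (1/s)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' AREX value at a specific offset
#'
#' @param x an `arex_spectrum`.
#' @param offset_ppm requested offset; the nearest measured offset is
#'   used.
#' @return AREX rate, 1/s.
#' @export
arex_at <- function(x, offset_ppm) {
  stopifnot(inherits(x, "arex_spectrum"))
  x$arex_per_s[which.min(abs(x$offsets_ppm - offset_ppm))]
}

# mean Z-spectra of a labelled cluster over the eroded mask
.cluster_mean_blocks <- function(preproc, label_map, label) {
  stopifnot(inherits(preproc, "stx_preproc"))
  sel <- label_map[preproc$mask_idx] == label
  n <- sum(sel)
  blocks <- lapply(preproc$zblocks, function(b) {
    list(b1_uT = b$b1_uT, role = b$role, offsets_ppm = b$offsets_ppm,
         z = colMeans(b$z[sel, , drop = FALSE]))
  })
  list(blocks = blocks, n_voxels = n,
       t1_obs_ms = mean(preproc$t1_ms[preproc$mask_idx][sel], na.rm = TRUE))
}

#' Fit the two-pool MT model per labelled cluster
#'
#' Averages each cluster's Z-spectra at the fitting saturation amplitudes
#' (by default the WASSR block and both high-B1 blocks) and the T1 map
#' over the cluster's eroded-mask voxels, then fits the two-pool model.
#' Blood/edema clusters use the Lorentzian semisolid lineshape, others
#' the super-Lorentzian. Clusters with fewer than `min_voxels` voxels are
#' excluded (`NULL` entry).
#'
#' @param preproc an `stx_preproc`.
#' @param label_map integer tissue label map (segmentation result or
#'   phantom truth).
#' @param labels tissue labels to fit.
#' @param fit_b1 B1 amplitudes (uT) of the blocks entering the fit.
#' @param min_voxels minimum cluster size (default 7).
#' @return named list of `qmt_fit` objects (or `NULL` where excluded).
#' @export
fit_qmt_clusters <- function(preproc, label_map, labels = 1:5,
                             fit_b1 = c(0.1, 3, 6), min_voxels = 7) {
  out <- lapply(labels, function(L) {
    cm <- .cluster_mean_blocks(preproc, label_map, L)
    if (cm$n_voxels < min_voxels) return(NULL)
    blocks <- Filter(function(b) any(abs(b$b1_uT - fit_b1) < 1e-9),
                     cm$blocks)
    ls <- if (L == .tissue_labels[["blood_edema"]]) "lorentzian"
    else "super_lorentzian"
    fit_qmt(lapply(blocks, function(b) b[c("b1_uT", "offsets_ppm", "z")]),
            t1_obs_ms = cm$t1_obs_ms, lineshape = ls,
            field_T = preproc$schedule$field_T,
            n_voxels = cm$n_voxels, min_voxels = min_voxels)
  })
  names(out) <- names(.tissue_labels)[match(labels, .tissue_labels)]
  out
}

#' Per-cluster AREX spectra from a low-B1 block
#'
#' For each fitted cluster, takes the cluster-mean measured Z-spectrum of
#' the low-B1 block at `b1_uT` as Z_lab and the two-pool model prediction
#' as Z_EMR, and returns the AREX spectrum.
#'
#' @param preproc an `stx_preproc` (low-B1 spectra should be
#'   B0-corrected).
#' @param label_map integer tissue label map.
#' @param fits result of [fit_qmt_clusters()].
#' @param b1_uT which low-B1 block to use (0.5 or 2 under the default
#'   schedule).
#' @return named list of `arex_spectrum` objects (`NULL` where the
#'   cluster was excluded).
#' @export
arex_clusters <- function(preproc, label_map, fits, b1_uT = 2) {
  out <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) return(NULL)
    L <- .tissue_labels[[nm]]
    cm <- .cluster_mean_blocks(preproc, label_map, L)
    blk <- Filter(function(b) abs(b$b1_uT - b1_uT) < 1e-9, cm$blocks)
    if (!length(blk)) stop("no block at B1 = ", b1_uT, " uT")
    blk <- blk[[1]]
    arex_spectrum(f$params, blk$offsets_ppm, blk$z, b1_uT,
                  cm$t1_obs_ms, preproc$schedule$field_T)
  })
  names(out) <- names(fits)
  out
}
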