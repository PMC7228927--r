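# Synthetic xenograft phantom: a hind-limb cross-section with an
# off-centre tumour containing a necrotic core and blood/edema pockets,
# surrounded by muscle with a connective-tissue rim. Per-voxel relaxation
# and MT parameters are the published cluster means with Gaussian jitter;
# Z-spectrum acquisitions are simulated with the steady-state multi-pool
# model plus B0 inhomogeneity, linear signal drift and Gaussian noise.

.tissue_labels <- c(active_tumour = 1L, necrosis_apoptosis = 2L,
                    blood_edema = 3L, muscle_connective = 4L, muscle = 5L)

#' Reference tissue parameter table
#'
#' Mean relaxation and two-pool MT parameters of the five tissue classes
#' (observed T1, liquid T2, the MT effect R*M0B, semisolid T2B and the
#' lineshape kind), together with default aggregate CEST/NOE pool
#' fractions. The MT effect is reported as a product; the default split
#' assumes an exchange rate R = 25/s, a typical literature value. The
#' amide fraction is higher in active tumour than in necrosis/apoptosis so
#' the amide-offset AREX contrast has a known direction.
#'
#' @return data.frame with one row per tissue class.
#' @export
tissue_table <- function() {
  data.frame(
    class = names(.tissue_labels),
    label = as.integer(.tissue_labels),
    t1_obs_ms = c(2200, 2600, 2800, 1810, 1840),
    t2a_ms = c(53, 80, 130, 31, 27),
    rm0b = c(1.2, 1.1, 0.9, 1.5, 3.8),
    t2b_us = c(8.2, 7.8, 100, 7.4, 7.2),
    lineshape = c("super_lorentzian", "super_lorentzian", "lorentzian",
                  "super_lorentzian", "super_lorentzian"),
    amide_f = c(0.0014, 0.0006, 0.0008, 0.0009, 0.0009),
    amine_f = c(0.0009, 0.0007, 0.0008, 0.0006, 0.0006),
    noe_f = c(0.0030, 0.0022, 0.0015, 0.0032, 0.0035),
    stringsAsFactors = FALSE
  )
}

# shared CEST/NOE pool kinetics (per-voxel fractions come from the maps)
.cest_kinetics <- function() {
  list(
    amide = list(offset_ppm = 3.5, k_per_s = 30, t2_ms = 15, r1_per_s = 1),
    amine = list(offset_ppm = 2.0, k_per_s = 700, t2_ms = 8, r1_per_s = 1),
    noe = list(offset_ppm = -3.5, k_per_s = 20, t2_ms = 5, r1_per_s = 1)
  )
}

.ellipse_mask <- function(shape, center, ax, ay, phi = 0) {
  x <- matrix(seq_len(shape[1]), shape[1], shape[2])
  y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dx <- x - center[1]; dy <- y - center[2]
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  (u / ax)^2 + (v / ay)^2 <= 1
}

#' Generate a synthetic phantom subject
#'
#' Lays out the tissue-class label map (leg, tumour with necrotic core and
#' blood/edema pockets, connective rim) to approximately match the
#' requested per-class area fractions, then draws per-voxel biophysical
#' parameter maps as class means times `(1 + N(0, jitter_sd))`, a smooth
#' polynomial B0 offset field, and the acquisition nuisance settings
#' (drift slope, noise level).
#'
#' @param shape image dimensions, at least 16 x 16.
#' @param class_fractions named per-class fractions of the image area;
#'   the remainder is background.
#' @param jitter_sd relative SD of within-subject voxel jitter.
#' @param blood_jitter_sd relative voxel jitter of the blood/edema class,
#'   which is a mix of vasculature and edema and far more heterogeneous
#'   than the other classes (its published parameter SDs reach 100%).
#' @param seed RNG seed; the phantom is reproducible from it.
#' @param b0_max_ppm maximum magnitude of the B0 offset field (must stay
#'   within the +/-0.5 ppm WASSR sampling; default 0.15 ppm).
#' @param drift_per_frame relative signal drift per acquired frame.
#' @param noise_sd relative Gaussian noise SD of simulated images.
#' @param tissue tissue parameter table (defaults to [tissue_table()]).
#' @param r_exchange_per_s exchange rate R used to split the tabulated MT
#'   effect into R and M0B.
#' @return object of class `stx_phantom` with the label map, per-voxel
#'   parameter maps, B0 field and `true_necrosis_fraction`.
#' @export
make_phantom <- function(shape = c(64, 64),
                         class_fractions = c(active_tumour = 0.09,
                                             necrosis_apoptosis = 0.03,
                                             blood_edema = 0.015,
                                             muscle_connective = 0.05,
                                             muscle = 0.18),
                         jitter_sd = 0.03, blood_jitter_sd = 0.25, seed = 1,
                         b0_max_ppm = 0.15,
                         drift_per_frame = -3e-4,
                         noise_sd = 0.01,
                         tissue = tissue_table(),
                         r_exchange_per_s = 25) {
  stopifnot(all(shape >= 16), all(class_fractions >= 0),
            sum(class_fractions) <= 1, b0_max_ppm <= 0.3)
  missing_cls <- setdiff(names(.tissue_labels), names(class_fractions))
  class_fractions[missing_cls] <- 0
  cf <- class_fractions[names(.tissue_labels)]
  set.seed(seed)
  npix <- prod(shape)
  lab <- matrix(0L, shape[1], shape[2])

  # leg ellipse holding all tissue
  a_total <- sum(cf) * npix
  ratio <- stats::runif(1, 1.15, 1.35)
  ax <- sqrt(a_total * ratio / pi); ay <- ax / ratio
  cen <- shape / 2 + stats::runif(2, -1.5, 1.5)
  phi <- stats::runif(1, 0, pi)
  leg <- .ellipse_mask(shape, cen, ax, ay, phi)
  lab[leg] <- .tissue_labels["muscle"]

  # tumour (active + necrosis + blood) placed off-centre inside the leg
  a_tum <- sum(cf[c("active_tumour", "necrosis_apoptosis", "blood_edema")]) *
    npix
  if (a_tum > 0) {
    tratio <- stats::runif(1, 1.05, 1.25)
    tax <- sqrt(a_tum * tratio / pi); tay <- tax / tratio
    ang <- stats::runif(1, 0, 2 * pi)
    shift <- c(cos(ang) * cos(phi) - sin(ang) * sin(phi),
               cos(ang) * sin(phi) + sin(ang) * cos(phi)) *
      c(0.35 * ax, 0.35 * ay)
    tcen <- cen + shift
    tum <- .ellipse_mask(shape, tcen, tax, tay, phi) & leg
    lab[tum] <- .tissue_labels["active_tumour"]

    # necrotic core
    f_nec <- cf["necrosis_apoptosis"] /
      max(sum(cf[c("active_tumour", "necrosis_apoptosis")]), 1e-12)
    if (f_nec > 0) {
      s <- sqrt(f_nec)
      nec <- .ellipse_mask(shape, tcen, tax * s, tay * s, phi) & tum
      lab[nec] <- .tissue_labels["necrosis_apoptosis"]
    }
    # blood/edema pockets between core and rim
    a_bld <- cf["blood_edema"] * npix
    if (a_bld > 0) {
      rb <- sqrt(a_bld / (2 * pi))
      for (th in stats::runif(2, 0, 2 * pi)) {
        pc <- tcen + c(cos(th) * 0.7 * tax, sin(th) * 0.7 * tay)
        pocket <- .ellipse_mask(shape, pc, rb, rb) & tum &
          lab != .tissue_labels["necrosis_apoptosis"]
        lab[pocket] <- .tissue_labels["blood_edema"]
      }
    }
  }

  # connective rim: outermost non-tumour leg pixels by elliptical radius
  a_conn <- round(cf["muscle_connective"] * npix)
  if (a_conn > 0) {
    x <- matrix(seq_len(shape[1]), shape[1], shape[2])
    y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    dx <- x - cen[1]; dy <- y - cen[2]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    rho <- (u / ax)^2 + (v / ay)^2
    cand <- which(leg & lab == .tissue_labels["muscle"])
    conn <- cand[order(rho[cand], decreasing = TRUE)[seq_len(min(a_conn,
                                                                 length(cand)))]]
    lab[conn] <- .tissue_labels["muscle_connective"]
  }

  # per-voxel parameter maps; the blood/edema class gets its own, much
  # larger jitter reflecting its mixed composition
  jit <- function(mean_by_class) {
    m <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(tissue))) {
      idx <- which(lab == tissue$label[i])
      if (!length(idx)) next
      sdi <- if (tissue$label[i] == .tissue_labels[["blood_edema"]])
        blood_jitter_sd else jitter_sd
      m[idx] <- mean_by_class[i] *
        pmax(0.3, 1 + stats::rnorm(length(idx), 0, sdi))
    }
    m
  }
  maps <- list(
    t1_obs_ms = jit(tissue$t1_obs_ms),
    t2a_ms = jit(tissue$t2a_ms),
    rm0b = jit(tissue$rm0b),
    t2b_us = jit(tissue$t2b_us),
    amide_f = jit(tissue$amide_f),
    amine_f = jit(tissue$amine_f),
    noe_f = jit(tissue$noe_f)
  )
  maps$r <- matrix(r_exchange_per_s, shape[1], shape[2])
  maps$m0b <- maps$rm0b / r_exchange_per_s

  # smooth low-order polynomial B0 field, capped at b0_max_ppm
  xn <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  yn <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
               byrow = TRUE)
  co <- stats::rnorm(6)
  b0 <- co[1] * 0.2 + co[2] * xn + co[3] * yn + co[4] * xn * yn +
    co[5] * xn^2 + co[6] * yn^2
  b0 <- b0 / max(abs(b0)) * b0_max_ppm

  # receive-profile-like smooth S0 map
  s0 <- 1000 * (1 + 0.1 * xn + 0.05 * yn)

  n_nec <- sum(lab == .tissue_labels["necrosis_apoptosis"])
  n_tum <- sum(lab == .tissue_labels["active_tumour"])
  structure(list(
    shape = shape,
    label_map = lab,
    maps = maps,
    cest_kinetics = .cest_kinetics(),
    b0_ppm = b0,
    s0 = s0,
    drift_per_frame = drift_per_frame,
    noise_sd = noise_sd,
    jitter_sd = jitter_sd,
    seed = seed,
    class_fractions = cf,
    tissue = tissue,
    true_necrosis_fraction = if (n_nec + n_tum > 0) n_nec / (n_nec + n_tum)
    else NA_real_
  ), class = "stx_phantom")
}

#' @export
print.stx_phantom <- function(x, ...) {
  cat(sprintf("stx_phantom %dx%d (seed %d)\n", x$shape[1], x$shape[2],
              x$seed))
  tab <- table(factor(x$label_map, levels = 0:5,
                      labels = c("background", names(.tissue_labels))))
  print(tab)
  cat(sprintf("  true necrosis fraction: %.3f\n", x$true_necrosis_fraction))
  invisible(x)
}

# multi-pool steady-state Z for the in-mask voxels of a phantom at one
# (b1, offset) measurement, including the per-voxel B0 shift. With
# de_only = TRUE only direct water saturation acts (used for the WASSR
# block, which probes the direct effect alone): the water pool then
# relaxes with the observed T1.
.phantom_z <- function(truth, idx, b1_uT, offset_ppm, field_T,
                       de_only = FALSE) {
  if (de_only) {
    m <- truth$maps
    dw <- ppm_to_angular(offset_ppm - truth$b0_ppm[idx], field_T)
    w1 <- b1_to_omega1(b1_uT)
    return(steady_state_de_signal(dw, m$t1_obs_ms[idx] / 1000,
                                  m$t2a_ms[idx] / 1000, w1))
  }
  m <- truth$maps
  lab <- truth$label_map[idx]
  r1obs <- 1000 / m$t1_obs_ms[idx]
  r <- m$r[idx]
  m0b <- m$m0b[idx]
  r1a <- r1a_from_observed(r1obs, r, m0b, 1)
  r2a <- 1000 / m$t2a_ms[idx]
  dw <- ppm_to_angular(offset_ppm - truth$b0_ppm[idx], field_T)
  w1 <- b1_to_omega1(b1_uT)
  t2b <- m$t2b_us[idx] * 1e-6
  wb <- numeric(length(idx))
  sl <- lab != .tissue_labels["blood_edema"]
  if (any(sl)) {
    wb[sl] <- pi * w1^2 *
      absorption_lineshape(dw[sl], t2b[sl], "super_lorentzian")
  }
  if (any(!sl)) {
    wb[!sl] <- pi * w1^2 * absorption_lineshape(dw[!sl], t2b[!sl],
                                                "lorentzian")
  }
  pools <- list(list(f = m0b, k = r, r1 = 1, w = wb))
  for (nm in names(truth$cest_kinetics)) {
    kin <- truth$cest_kinetics[[nm]]
    f <- m[[paste0(nm, "_f")]][idx]
    r2 <- 1000 / kin$t2_ms
    dwp <- dw - ppm_to_angular(kin$offset_ppm, field_T)
    wi <- w1^2 * r2 / (r2^2 + dwp^2)
    pools[[length(pools) + 1]] <-
      list(f = f, k = kin$k_per_s, r1 = kin$r1_per_s, w = wi)
  }
  .steady_state_z(dw, w1, r1a, r2a, pools)
}

#' Simulate the saturation-weighted image series of a phantom
#'
#' Evaluates the steady-state multi-pool saturation model (water, semisolid
#' MT pool, and aggregate amide/amine/NOE CEST pools) per voxel for every
#' frame of the schedule — Z-spectrum measurements and interleaved 667 ppm
#' references — with the per-voxel B0 shift, multiplicative linear drift in
#' acquisition order, and seeded additive Gaussian noise. The WASSR block,
#' which probes the direct water saturation effect alone, is simulated
#' from the observed T1/T2 via [steady_state_de_signal()].
#'
#' @param truth an [stx_phantom].
#' @param schedule an [stx_schedule].
#' @param seed noise RNG seed (default derived from the phantom seed).
#' @return 3D array (x, y, frame) of simulated signals.
#' @export
simulate_zspectra <- function(truth, schedule, seed = truth$seed + 1) {
  stopifnot(inherits(truth, "stx_phantom"), inherits(schedule, "stx_schedule"))
  frames <- schedule_frames(schedule)
  idx <- which(truth$label_map > 0)
  imgs <- array(0, c(truth$shape, nrow(frames)))
  set.seed(seed)
  s0_in <- truth$s0[idx]
  sd_bg <- truth$noise_sd * stats::median(truth$s0)
  roles <- vapply(schedule$blocks, `[[`, "", "role")
  for (i in seq_len(nrow(frames))) {
    z <- .phantom_z(truth, idx, frames$b1_uT[i], frames$offset_ppm[i],
                    schedule$field_T,
                    de_only = roles[frames$block[i]] == "wassr")
    frame <- matrix(0, truth$shape[1], truth$shape[2])
    frame[idx] <- s0_in * z * (1 + truth$drift_per_frame * (frames$order[i] - 1))
    if (truth$noise_sd > 0) {
      noise <- matrix(stats::rnorm(prod(truth$shape), 0, sd_bg),
                      truth$shape[1], truth$shape[2])
      noise[idx] <- stats::rnorm(length(idx), 0, truth$noise_sd * s0_in)
      frame <- frame + noise
    }
    imgs[, , i] <- frame
  }
  imgs
}

#' Simulate the inversion-recovery series of a phantom
#'
#' Signed full-inversion recovery `S(TI) = S0 (1 - 2 exp(-TI/T1))` per
#' voxel with seeded Gaussian noise (long-TR limit).
#'
#' @inheritParams simulate_zspectra
#' @return 3D array (x, y, TI) of signed signals.
#' @export
simulate_ir_series <- function(truth, schedule, seed = truth$seed + 2) {
  stopifnot(inherits(truth, "stx_phantom"), inherits(schedule, "stx_schedule"))
  tis <- schedule$inversion_times_ms
  idx <- which(truth$label_map > 0)
  out <- array(0, c(truth$shape, length(tis)))
  set.seed(seed)
  sd_bg <- truth$noise_sd * stats::median(truth$s0)
  for (i in seq_along(tis)) {
    frame <- matrix(0, truth$shape[1], truth$shape[2])
    frame[idx] <- truth$s0[idx] *
      (1 - 2 * exp(-tis[i] / truth$maps$t1_obs_ms[idx]))
    if (truth$noise_sd > 0) {
      noise <- matrix(stats::rnorm(prod(truth$shape), 0, sd_bg),
                      truth$shape[1], truth$shape[2])
      noise[idx] <- stats::rnorm(length(idx), 0,
                                 truth$noise_sd * truth$s0[idx])
      frame <- frame + noise
    }
    out[, , i] <- frame
  }
  out
}

#' Simulate a complete phantom study
#'
#' @param truth an [stx_phantom].
#' @param schedule an [stx_schedule].
#' @param subject_id subject identifier.
#' @param seed RNG seed for the simulated noise.
#' @return an [stx_study] with the ground truth attached.
#' @export
simulate_study <- function(truth, schedule = stx_schedule(),
                           subject_id = sprintf("phantom_%04d", truth$seed),
                           seed = truth$seed) {
  stx_study(subject_id, schedule,
            images = simulate_zspectra(truth, schedule, seed = seed + 1),
            ir = simulate_ir_series(truth, schedule, seed = seed + 2),
            mask = truth$label_map > 0,
            truth = truth)
}

#' Generate a phantom cohort
#'
#' Draws `n_subjects` phantoms whose class-mean parameters vary between
#' subjects with relative SD `between_subject_sd` and whose intratumoural
#' necrosis fraction is uniform over `necrosis_range` (the tumour +
#' necrosis area staying fixed), emulating cohort-level biological
#' variation.
#'
#' @param n_subjects number of subjects.
#' @param shape image dimensions.
#' @param seed cohort RNG seed.
#' @param necrosis_range range of per-subject necrosis fractions.
#' @param between_subject_sd relative SD of class-mean parameters across
#'   subjects.
#' @param tumour_fraction image-area fraction of tumour + necrosis.
#' @param ... further arguments to [make_phantom()].
#' @return list of `stx_phantom` objects.
#' @export
make_cohort <- function(n_subjects, shape = c(64, 64), seed = 1,
                        necrosis_range = c(0.10, 0.40),
                        between_subject_sd = 0.05,
                        tumour_fraction = 0.12, ...) {
  set.seed(seed)
  sub_seeds <- sample.int(1e6, n_subjects)
  nec_frac <- stats::runif(n_subjects, necrosis_range[1], necrosis_range[2])
  scale_mat <- matrix(pmax(0.7, 1 + stats::rnorm(n_subjects * 4, 0,
                                                 between_subject_sd)),
                      n_subjects, 4)
  lapply(seq_len(n_subjects), function(s) {
    tis <- tissue_table()
    tis$t1_obs_ms <- tis$t1_obs_ms * scale_mat[s, 1]
    tis$t2a_ms <- tis$t2a_ms * scale_mat[s, 2]
    tis$rm0b <- tis$rm0b * scale_mat[s, 3]
    tis$t2b_us <- tis$t2b_us * scale_mat[s, 4]
    cf <- c(active_tumour = tumour_fraction * (1 - nec_frac[s]),
            necrosis_apoptosis = tumour_fraction * nec_frac[s],
            blood_edema = 0.015, muscle_connective = 0.05, muscle = 0.18)
    make_phantom(shape = shape, class_fractions = cf, seed = sub_seeds[s],
                 tissue = tis, ...)
  })
}

#' Simulate a phantom cohort of studies
#'
#' @inheritParams make_cohort
#' @param schedule an [stx_schedule].
#' @return list of [stx_study] objects with truths attached.
#' @export
simulate_cohort <- function(n_subjects, shape = c(64, 64), seed = 1,
                            schedule = stx_schedule(), ...) {
  truths <- make_cohort(n_subjects, shape = shape, seed = seed, ...)
  lapply(seq_along(truths), function(i) {
    simulate_study(truths[[i]], schedule,
                   subject_id = sprintf("phantom_%02d", i))
  })
}

#' Simulate a TUNEL-like histology image for a phantom
#'
#' Renders an RGB image at `upscale` times the MRI resolution in which the
#' blue channel separates tumour (below the 0.78 threshold) from
#' necrosis/apoptosis (at or above it), with texture noise that never
#' crosses the threshold, together with the crop mask excluding
#' non-tumour tissue.
#'
#' @param truth an [stx_phantom].
#' @param upscale integer upsampling factor.
#' @param seed RNG seed for the stain texture.
#' @return list with `image` (h x w x 3 array in [0, 1]) and `crop_mask`.
#' @export
simulate_tunel_image <- function(truth, upscale = 4, seed = truth$seed + 3) {
  stopifnot(inherits(truth, "stx_phantom"), upscale >= 1)
  set.seed(seed)
  up <- function(m) m[rep(seq_len(nrow(m)), each = upscale),
                      rep(seq_len(ncol(m)), each = upscale)]
  lab <- up(truth$label_map)
  h <- nrow(lab); w <- ncol(lab)
  img <- array(0, c(h, w, 3))
  blue <- matrix(1, h, w)  # slide background: white-ish
  red <- matrix(1, h, w)
  green <- matrix(1, h, w)
  tum <- lab == .tissue_labels["active_tumour"] |
    lab == .tissue_labels["blood_edema"]
  nec <- lab == .tissue_labels["necrosis_apoptosis"]
  other <- lab > 0 & !tum & !nec
  # haematoxylin-dominated viable tumour: blue strictly below threshold
  blue[tum] <- pmin(0.74, pmax(0.30,
                               0.55 + stats::rnorm(sum(tum), 0, 0.08)))
  red[tum] <- 0.55 + stats::rnorm(sum(tum), 0, 0.05)
  green[tum] <- 0.45 + stats::rnorm(sum(tum), 0, 0.05)
  # TUNEL-positive necrosis/apoptosis: blue at or above threshold
  blue[nec] <- pmin(0.97, pmax(0.80,
                               0.88 + stats::rnorm(sum(nec), 0, 0.04)))
  red[nec] <- 0.60 + stats::rnorm(sum(nec), 0, 0.05)
  green[nec] <- 0.50 + stats::rnorm(sum(nec), 0, 0.05)
  # muscle/skin outside the crop mask
  blue[other] <- 0.60 + stats::rnorm(sum(other), 0, 0.10)
  red[other] <- 0.75 + stats::rnorm(sum(other), 0, 0.05)
  green[other] <- 0.55 + stats::rnorm(sum(other), 0, 0.05)
  img[, , 1] <- pmin(1, pmax(0, red))
  img[, , 2] <- pmin(1, pmax(0, green))
  img[, , 3] <- pmin(1, pmax(0, blue))
  # the crop mask stands in for the manual crop to the tumour+necrosis
  # region (blood pockets are excluded like muscle and skin)
  list(image = img,
       crop_mask = lab == .tissue_labels[["active_tumour"]] | nec)
}

# ---- ground-truth serialization -------------------------------------------

.truth_layers <- c("t1_obs_ms", "t2a_ms", "rm0b", "t2b_us",
                   "amide_f", "amine_f", "noe_f", "r", "m0b")

.save_truth <- function(truth, path) {
  RNifti::writeNifti(RNifti::asNifti(truth$label_map, datatype = "uint8"),
                     file.path(path, "truth_labels.nii.gz"))
  stack <- array(0, c(truth$shape, 1, length(.truth_layers) + 2))
  for (i in seq_along(.truth_layers)) {
    stack[, , 1, i] <- truth$maps[[.truth_layers[i]]]
  }
  stack[, , 1, length(.truth_layers) + 1] <- truth$b0_ppm
  stack[, , 1, length(.truth_layers) + 2] <- truth$s0
  .write_nifti(stack, file.path(path, "truth_params.nii.gz"))
  meta <- list(
    layers = c(.truth_layers, "b0_ppm", "s0"),
    cest_kinetics = truth$cest_kinetics,
    drift_per_frame = truth$drift_per_frame,
    noise_sd = truth$noise_sd,
    jitter_sd = truth$jitter_sd,
    seed = truth$seed,
    class_fractions = as.list(truth$class_fractions),
    tissue = truth$tissue,
    true_necrosis_fraction = truth$true_necrosis_fraction
  )
  jsonlite::write_json(meta, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
}

.load_truth <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "truth.json"),
                              simplifyVector = TRUE)
  labn <- RNifti::readNifti(file.path(path, "truth_labels.nii.gz"))
  lab <- matrix(as.integer(labn), dim(labn)[1], dim(labn)[2])
  stackn <- RNifti::readNifti(file.path(path, "truth_params.nii.gz"))
  d <- dim(stackn)
  maps <- list()
  for (i in seq_along(meta$layers)) {
    maps[[meta$layers[i]]] <- matrix(stackn[, , 1, i], d[1], d[2])
  }
  b0 <- maps$b0_ppm; s0 <- maps$s0
  maps$b0_ppm <- NULL; maps$s0 <- NULL
  kin <- lapply(meta$cest_kinetics, function(k) {
    list(offset_ppm = k$offset_ppm, k_per_s = k$k_per_s, t2_ms = k$t2_ms,
         r1_per_s = k$r1_per_s)
  })
  structure(list(
    shape = c(d[1], d[2]),
    label_map = lab,
    maps = maps,
    cest_kinetics = kin,
    b0_ppm = b0,
    s0 = s0,
    drift_per_frame = meta$drift_per_frame,
    noise_sd = meta$noise_sd,
    jitter_sd = meta$jitter_sd,
    seed = meta$seed,
    class_fractions = unlist(meta$class_fractions),
    tissue = as.data.frame(meta$tissue),
    true_necrosis_fraction = meta$true_necrosis_fraction
  ), class = "stx_phantom")
}
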