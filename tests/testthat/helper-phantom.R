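# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a small noise-free phantom study for exactness checks
clean_phantom <- function() {
  if (is.null(.fixtures$clean)) {
    ph <- make_phantom(shape = c(32, 32), seed = 7, noise_sd = 0,
                       drift_per_frame = 0)
    .fixtures$clean <- list(truth = ph,
                            study = simulate_study(ph, stx_schedule()))
  }
  .fixtures$clean
}

# the 10-subject default-condition cohort used by the end-to-end checks;
# low-B1 correction is skipped because the optimized protocol (T1/T2 +
# high-B1 images) does not use the low-B1 blocks
acceptance_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    studies <- simulate_cohort(10, seed = 11)
    preprocs <- lapply(studies, preprocess_study, correct_low_b1 = FALSE)
    .fixtures$cohort <- list(studies = studies, preprocs = preprocs)
  }
  .fixtures$cohort
}

# three tiny preprocessed subjects for segmentation mechanics tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    studies <- simulate_cohort(5, shape = c(32, 32), seed = 5)
    .fixtures$small <- list(
      studies = studies,
      preprocs = lapply(studies, preprocess_study, correct_low_b1 = FALSE))
  }
  .fixtures$small
}

# a synthetic stx_preproc with hand-set features, for observation-matrix
# mechanics
fake_preproc <- function(id, n_voxels, features) {
  shape <- c(max(n_voxels, 4), 4)
  mask <- matrix(0L, shape[1], shape[2])
  mask[seq_len(n_voxels)] <- 1L
  structure(list(
    subject_id = id, shape = shape, mask = mask, eroded_mask = mask,
    mask_idx = which(mask > 0),
    features = features,
    feature_info = data.frame(name = colnames(features), type = "map",
                              role = "map", b1_uT = NA, offset_ppm = NA),
    t1_ms = NULL, t2_ms = NULL, qc = list()
  ), class = "stx_preproc")
}
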