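# The per-subject study container and its on-disk format:
#   <dir>/zspec.nii.gz   4D (x, y, 1, n_frames), Z-spectrum + reference
#                        frames in acquisition order
#   <dir>/ir.nii.gz      4D over inversion times
#   <dir>/mask.nii.gz    uint8 tissue mask
#   <dir>/schedule.json  blocks, frame map, reference convention, TIs
# Phantom subjects additionally carry truth_labels.nii.gz, truth.json and
# truth_params.nii.gz (per-voxel ground-truth parameter stack).

#' Construct a saturation-transfer study dataset
#'
#' @param subject_id subject identifier string.
#' @param schedule an [stx_schedule].
#' @param images 3D array (x, y, frame) of saturation-weighted images in
#'   acquisition order, matching `schedule_frames(schedule)` row for row.
#' @param ir 3D array (x, y, TI) of inversion-recovery images (signed).
#' @param mask integer/logical matrix of non-background voxels.
#' @param frames optional frame table; defaults to
#'   [schedule_frames()] of `schedule`.
#' @param truth optional `stx_phantom` ground truth for synthetic subjects.
#' @return object of class `stx_study`.
#' @export
stx_study <- function(subject_id, schedule, images, ir, mask,
                      frames = schedule_frames(schedule), truth = NULL) {
  stopifnot(inherits(schedule, "stx_schedule"))
  if (length(dim(images)) != 3) stop("images must be a 3D (x, y, frame) array")
  if (dim(images)[3] != nrow(frames)) {
    stop("frame count mismatch: schedule expects ", nrow(frames),
         " frames but ", dim(images)[3], " image volumes are present")
  }
  if (!all(is.finite(images))) stop("non-finite pixel values in images")
  if (!all(is.finite(ir))) stop("non-finite pixel values in IR series")
  if (!identical(dim(images)[1:2], dim(ir)[1:2]) ||
      !identical(dim(images)[1:2], dim(mask))) {
    stop("images, IR series and mask must share one in-plane shape")
  }
  if (dim(ir)[3] != length(schedule$inversion_times_ms)) {
    stop("IR series must have one volume per inversion time")
  }
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  z <- frames[frames$kind == "zspec", ]
  if (anyDuplicated(z[, c("block", "offset_idx")])) {
    stop("duplicate (block, offset) frames in schedule")
  }
  structure(list(
    subject_id = as.character(subject_id),
    schedule = schedule,
    frames = frames,
    images = images,
    ir = ir,
    mask = mask,
    n_voxels = sum(mask),
    truth = truth
  ), class = "stx_study")
}

#' @export
print.stx_study <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("stx_study '%s': %dx%d, %d saturation frames, %d IR frames, %d mask voxels\n",
              x$subject_id, d[1], d[2], d[3], dim(x$ir)[3], x$n_voxels))
  if (!is.null(x$truth)) cat("  (synthetic; ground truth attached)\n")
  invisible(x)
}

.write_nifti <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
}

#' Save a study dataset to a directory
#'
#' Writes the NIfTI volumes and JSON schedule sidecar described in the
#' package format (see [stx_study()]). Pixel data are stored as float64 so
#' the round trip through [load_study()] is bit-exact.
#'
#' @param study an [stx_study].
#' @param path directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
save_study <- function(study, path) {
  stopifnot(inherits(study, "stx_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  d <- dim(study$images)
  .write_nifti(array(study$images, c(d[1], d[2], 1, d[3])),
               file.path(path, "zspec.nii.gz"))
  di <- dim(study$ir)
  .write_nifti(array(study$ir, c(di[1], di[2], 1, di[3])),
               file.path(path, "ir.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$mask, datatype = "uint8"),
                     file.path(path, "mask.nii.gz"))
  sched <- study$schedule
  sidecar <- list(
    subject_id = study$subject_id,
    field_T = sched$field_T,
    blocks = lapply(sched$blocks, function(b) {
      list(b1_uT = b$b1_uT, offsets_ppm = b$offsets_ppm, role = b$role)
    }),
    reference_offset_ppm = sched$reference_offset_ppm,
    reference_interleave = sched$reference_interleave,
    inversion_times_ms = sched$inversion_times_ms,
    saturation_duration_ms = sched$saturation_duration_ms,
    frames = study$frames
  )
  jsonlite::write_json(sidecar, file.path(path, "schedule.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(study$truth)) .save_truth(study$truth, path)
  invisible(path)
}

#' Load a study dataset from a directory
#'
#' @param path directory written by [save_study()].
#' @return an [stx_study].
#' @export
load_study <- function(path) {
  sidecar_path <- file.path(path, "schedule.json")
  if (!file.exists(sidecar_path)) {
    stop("schedule sidecar not found: ", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  blocks <- if (is.data.frame(sc$blocks)) {
    lapply(seq_len(nrow(sc$blocks)), function(i) {
      list(b1_uT = sc$blocks$b1_uT[i],
           offsets_ppm = unlist(sc$blocks$offsets_ppm[i]),
           role = sc$blocks$role[i])
    })
  } else {
    lapply(sc$blocks, function(b) {
      list(b1_uT = b$b1_uT, offsets_ppm = unlist(b$offsets_ppm), role = b$role)
    })
  }
  schedule <- stx_schedule(
    field_T = sc$field_T, blocks = blocks,
    reference_offset_ppm = sc$reference_offset_ppm,
    reference_interleave = sc$reference_interleave,
    inversion_times_ms = unlist(sc$inversion_times_ms),
    saturation_duration_ms = sc$saturation_duration_ms
  )
  frames <- as.data.frame(sc$frames)
  frames$offset_idx <- as.integer(frames$offset_idx)
  imgs <- RNifti::readNifti(file.path(path, "zspec.nii.gz"))
  d <- dim(imgs)
  images <- array(as.numeric(imgs), c(d[1], d[2], d[4]))
  if (dim(images)[3] != nrow(frames)) {
    stop("frame count mismatch: sidecar lists ", nrow(frames),
         " frames but ", dim(images)[3], " volumes are present")
  }
  if (!all(is.finite(images))) stop("non-finite pixel values in zspec.nii.gz")
  irn <- RNifti::readNifti(file.path(path, "ir.nii.gz"))
  di <- dim(irn)
  ir <- array(as.numeric(irn), c(di[1], di[2], di[4]))
  mask <- matrix(as.integer(RNifti::readNifti(file.path(path, "mask.nii.gz"))),
                 d[1], d[2])
  truth <- if (file.exists(file.path(path, "truth.json"))) {
    .load_truth(path)
  }
  stx_study(sc$subject_id, schedule, images, ir, mask,
            frames = frames, truth = truth)
}
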