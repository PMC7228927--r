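# Acquisition schedule: which saturation blocks are acquired at which B1
# and offsets, where the interleaved reference scans sit, and the
# inversion-recovery timing.

#' Construct a saturation-transfer acquisition schedule
#'
#' A schedule is a list of saturation blocks, each a B1 amplitude with an
#' ordered offset list and a role (`wassr`, `low_b1` or `high_b1`), plus
#' the reference-scan convention (reference offset, and how many Z-spectrum
#' measurements are acquired between consecutive reference scans) and the
#' inversion-recovery times for T1 mapping.
#'
#' The default reproduces the 7 T xenograft protocol: Z-spectra at
#' B1 = 0.5 and 2 uT over 66 offsets spanning +/-5 ppm; B1 = 3 and 6 uT at
#' 11 logarithmically spaced offsets from 300 down to 3 ppm; a WASSR
#' spectrum at 0.1 uT over 21 offsets within +/-0.5 ppm; reference scans at
#' 667 ppm before, after, and between every five measurements; and
#' TI = 30, 110, 390, 1400, 5000 ms.
#'
#' @param field_T static magnetic field, tesla.
#' @param blocks list of blocks `list(b1_uT =, offsets_ppm =, role =)`.
#' @param reference_offset_ppm offset of the reference scans, ppm.
#' @param reference_interleave number of Z-spectrum measurements between
#'   consecutive reference scans.
#' @param inversion_times_ms strictly increasing inversion times, ms.
#' @param saturation_duration_ms saturation block pulse length, ms
#'   (metadata; the simulator assumes steady-state saturation).
#' @return object of class `stx_schedule`.
#' @export
stx_schedule <- function(field_T = 7,
                         blocks = default_blocks(),
                         reference_offset_ppm = 667,
                         reference_interleave = 5,
                         inversion_times_ms = c(30, 110, 390, 1400, 5000),
                         saturation_duration_ms = 490) {
  stopifnot(field_T > 0, reference_interleave >= 1,
            all(diff(inversion_times_ms) > 0))
  roles <- vapply(blocks, `[[`, "", "role")
  if (sum(roles == "wassr") != 1) {
    stop("schedule must contain exactly one WASSR block")
  }
  for (b in blocks) {
    stopifnot(b$b1_uT >= 0, all(is.finite(b$offsets_ppm)),
              b$role %in% c("wassr", "low_b1", "high_b1"))
  }
  structure(list(
    field_T = field_T,
    gyromagnetic_ratio = GAMMA_MHZ_PER_T,
    blocks = blocks,
    reference_offset_ppm = reference_offset_ppm,
    reference_interleave = reference_interleave,
    inversion_times_ms = inversion_times_ms,
    saturation_duration_ms = saturation_duration_ms
  ), class = "stx_schedule")
}

#' Default saturation block layout
#' @return list of blocks for [stx_schedule()].
#' @export
default_blocks <- function() {
  list(
    list(b1_uT = 0.1, offsets_ppm = seq(-0.5, 0.5, length.out = 21),
         role = "wassr"),
    list(b1_uT = 0.5, offsets_ppm = seq(-5, 5, length.out = 66),
         role = "low_b1"),
    list(b1_uT = 2, offsets_ppm = seq(-5, 5, length.out = 66),
         role = "low_b1"),
    list(b1_uT = 3, offsets_ppm = exp(seq(log(300), log(3), length.out = 11)),
         role = "high_b1"),
    list(b1_uT = 6, offsets_ppm = exp(seq(log(300), log(3), length.out = 11)),
         role = "high_b1")
  )
}

#' @export
print.stx_schedule <- function(x, ...) {
  cat("Saturation-transfer acquisition schedule @", x$field_T, "T\n")
  for (b in x$blocks) {
    cat(sprintf("  %-8s B1 = %-4g uT, %d offsets [%g, %g] ppm\n",
                b$role, b$b1_uT, length(b$offsets_ppm),
                min(b$offsets_ppm), max(b$offsets_ppm)))
  }
  cat(sprintf("  references at %g ppm every %d measurements\n",
              x$reference_offset_ppm, x$reference_interleave))
  cat("  TI:", paste(x$inversion_times_ms, collapse = ", "), "ms\n")
  invisible(x)
}

#' Frame table of a schedule
#'
#' Expands a schedule into the per-frame acquisition order: each saturation
#' block contributes a leading reference scan, its Z-spectrum measurements
#' with a reference interleaved after every `reference_interleave` of them,
#' and a trailing reference. Blocks are acquired in schedule order.
#'
#' @param schedule an [stx_schedule].
#' @return data.frame with columns `order` (1-based acquisition order),
#'   `kind` (`"zspec"`/`"reference"`), `block` (block index), `offset_idx`
#'   (index into the block's offsets, `NA` for references), `b1_uT` and
#'   `offset_ppm`.
#' @export
schedule_frames <- function(schedule) {
  stopifnot(inherits(schedule, "stx_schedule"))
  rows <- list()
  for (bi in seq_along(schedule$blocks)) {
    b <- schedule$blocks[[bi]]
    n <- length(b$offsets_ppm)
    ref_row <- function() {
      data.frame(kind = "reference", block = bi, offset_idx = NA_integer_,
                 b1_uT = b$b1_uT, offset_ppm = schedule$reference_offset_ppm)
    }
    rows[[length(rows) + 1]] <- ref_row()
    for (j in seq_len(n)) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = "zspec", block = bi, offset_idx = j,
        b1_uT = b$b1_uT, offset_ppm = b$offsets_ppm[j])
      if (j %% schedule$reference_interleave == 0 && j < n) {
        rows[[length(rows) + 1]] <- ref_row()
      }
    }
    rows[[length(rows) + 1]] <- ref_row()
  }
  out <- do.call(rbind, rows)
  out$order <- seq_len(nrow(out))
  out[, c("order", "kind", "block", "offset_idx", "b1_uT", "offset_ppm")]
}
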