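#' Proton gyromagnetic ratio over 2*pi (MHz/T)
#'
#' The constant gamma/2*pi used throughout for converting between ppm
#' frequency offsets, Hz and rad/s, and between B1 amplitude (uT) and the
#' nutation rate omega1 (rad/s).
#' @export
GAMMA_MHZ_PER_T <- 42.577

#' Convert a frequency offset in ppm to angular frequency (rad/s)
#'
#' The chemical-shift offset convention is
#' \eqn{\Delta\omega_{ppm} = (\omega - \omega_0)/\omega_0 \times 10^6},
#' so at a static field `b0_T` one ppm corresponds to
#' `GAMMA_MHZ_PER_T * b0_T` Hz.
#'
#' @param offset_ppm frequency offset(s) relative to water, ppm.
#' @param b0_T static magnetic field, tesla.
#' @return angular frequency offset(s), rad/s.
#' @examples
#' ppm_to_angular(1, 7) / (2 * pi) # 298.039 Hz
#' @export
ppm_to_angular <- function(offset_ppm, b0_T) {
  2 * pi * offset_ppm * GAMMA_MHZ_PER_T * b0_T # MHz * ppm = Hz
}

#' Convert angular frequency (rad/s) back to ppm
#' @param angular angular frequency offset(s), rad/s.
#' @param b0_T static magnetic field, tesla.
#' @return offset(s) in ppm.
#' @export
angular_to_ppm <- function(angular, b0_T) {
  angular / (2 * pi * GAMMA_MHZ_PER_T * b0_T)
}

#' Convert saturation amplitude B1 (uT) to omega1 = gamma * B1 (rad/s)
#' @param b1_uT saturation amplitude(s), microtesla.
#' @return nutation rate(s) omega1, rad/s.
#' @examples
#' b1_to_omega1(1) # 2 * pi * 42.577
#' @export
b1_to_omega1 <- function(b1_uT) {
  2 * pi * GAMMA_MHZ_PER_T * b1_uT # MHz/T * uT = Hz
}
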