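# Physical constants and unit conversions.
#
# Internal unit system: length in Angstrom, time in fs, energy in eV,
# mass in amu. In these units 1 amu * (A/fs)^2 = 103.642697 eV, so kinetic
# energy is 0.5 * m[amu] * v[A/fs]^2 * .amu_ev below.

#' Unit constants used throughout the package
#'
#' A named list of the conversion factors the package relies on:
#' `hbar_ev_fs` (reduced Planck constant, eV fs), `hartree_ev` (1 Hartree in
#' eV), `amu_ev` (1 amu A^2/fs^2 in eV, i.e. the factor turning
#' `0.5 * m * v^2` with amu and A/fs into eV) and `cm_per_fs` (speed of
#' light in cm/fs, for converting wavenumbers to angular frequencies).
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' hop_units()$hbar_ev_fs
hop_units <- function() {
  list(
    hbar_ev_fs = 0.6582119569,
    hartree_ev = 27.211386245988,
    amu_ev     = 103.642696562,
    cm_per_fs  = 2.99792458e-5
  )
}

.hbar <- 0.6582119569
.hartree_ev <- 27.211386245988
.amu_ev <- 103.642696562
.c_cm_fs <- 2.99792458e-5
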