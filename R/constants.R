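#' Physical constants used throughout the package
#'
#' CODATA 2018 values, collected in one place so that every module (harmonic
#' analysis, thermochemistry, dispersion, spectra) draws from the same table.
#' Energies are exchanged in kJ mol\eqn{^{-1}}, lengths in Angstrom, masses in
#' amu, wavenumbers in cm\eqn{^{-1}}.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{c}{speed of light, m s\eqn{^{-1}}}
#'   \item{c_cm}{speed of light, cm s\eqn{^{-1}}}
#'   \item{kB}{Boltzmann constant, J K\eqn{^{-1}}}
#'   \item{N_A}{Avogadro constant, mol\eqn{^{-1}}}
#'   \item{R}{molar gas constant, J mol\eqn{^{-1}} K\eqn{^{-1}}}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{hartree_kjmol}{1 hartree in kJ mol\eqn{^{-1}} (applied only at ingestion)}
#'   \item{atm_Pa}{1 atm in Pa}
#'   \item{ir_intensity_factor}{IR intensity conversion,
#'     km mol\eqn{^{-1}} per (D \eqn{\mbox{\AA}^{-1}} amu\eqn{^{-1/2}})\eqn{^2};
#'     equals \eqn{N_A \pi / (3 c^2)} in those units}
#' }
#' @export
phys_const <- list(
  h  = 6.62607015e-34,
  c  = 2.99792458e8,
  c_cm = 2.99792458e10,
  kB = 1.380649e-23,
  N_A = 6.02214076e23,
  R  = 8.314462618,
  amu = 1.66053906660e-27,
  hartree_kjmol = 2625.4996394799,
  atm_Pa = 101325,
  ir_intensity_factor = 42.2561
)

# eigenvalue (kJ mol^-1 A^-2 amu^-1) -> angular frequency^2 (s^-2)
.lambda_to_omega2 <- function(lambda) {
  lambda * 1e3 / phys_const$N_A / (phys_const$amu * 1e-20)
}

# wavenumber (cm^-1, signed) -> mass-weighted Hessian eigenvalue
.wavenumber_to_lambda <- function(nu) {
  omega <- 2 * pi * phys_const$c_cm * abs(nu)
  sign(nu) * omega^2 * phys_const$N_A * phys_const$amu * 1e-20 / 1e3
}

# eigenvalue -> signed wavenumber (negative encodes imaginary modes)
.lambda_to_wavenumber <- function(lambda) {
  sign(lambda) * sqrt(.lambda_to_omega2(abs(lambda))) / (2 * pi * phys_const$c_cm)
}

#' Round half away from zero
#'
#' Rounding convention of printed population tables (0.005 -> 0.01), unlike
#' base [round()] which rounds half to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
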