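#' Harmonic-oscillator vibrational thermochemistry
#'
#' Standard quantum harmonic-oscillator partition-function results per mode,
#' summed over modes. With \eqn{x = hc\tilde\nu/k_BT}:
#' \deqn{ZPE = \sum \tfrac12 N_A hc\tilde\nu, \quad
#'       U_{vib} = ZPE + RT\sum \frac{x}{e^x-1}, \quad
#'       S_{vib} = R\sum\left[\frac{x}{e^x-1} - \ln(1-e^{-x})\right].}
#'
#' @param frequencies real wavenumbers, cm\eqn{^{-1}}; imaginary (negative)
#'   modes must be filtered out by the caller (see [normal_modes()])
#' @param T temperature, K, > 0
#' @return list with \code{ZPE}, \code{U_vib}, \code{S_vib} — energies in
#'   kJ mol\eqn{^{-1}}, entropy in kJ mol\eqn{^{-1}} K\eqn{^{-1}}
#' @export
vibrational_thermo <- function(frequencies, T = 298.15) {
  if (T <= 0) stop("temperature must be > 0 K")
  frequencies <- as.numeric(frequencies)
  if (any(frequencies < 0))
    stop("negative (imaginary) frequencies passed in; filter them upstream")
  if (length(frequencies) == 0L)
    return(list(ZPE = 0, U_vib = 0, S_vib = 0))
  x <- phys_const$h * phys_const$c_cm * frequencies /
    (phys_const$kB * T)
  R <- phys_const$R / 1e3                      # kJ/mol/K
  zpe <- sum(phys_const$N_A * phys_const$h * phys_const$c_cm * frequencies / 2) / 1e3
  u_th <- R * T * sum(x / expm1(x))
  s <- R * sum(x / expm1(x) - log1p(-exp(-x)))
  list(ZPE = zpe, U_vib = zpe + u_th, S_vib = s)
}

#' Ideal-gas rigid-rotor harmonic-oscillator thermochemistry
#'
#' Full RRHO state functions for a gas-phase species: Sackur–Tetrode
#' translation, classical rigid-rotor rotation with symmetry number, and
#' harmonic vibration via [vibrational_thermo()]. \eqn{H = U + RT} (ideal
#' gas), \eqn{G = H - TS}.
#'
#' @param mass molecular mass, amu
#' @param frequencies vibrational wavenumbers, cm\eqn{^{-1}} (empty for a
#'   rigid species)
#' @param rot_constants rotational constants in cm\eqn{^{-1}}: length 3
#'   (nonlinear), length 1 (linear), or \code{NULL} (atom)
#' @param sigma rotational symmetry number
#' @param T temperature, K
#' @param P pressure, atm
#' @return object of class \code{thermo_state}: the per-contribution terms
#'   and totals \code{U}, \code{H}, \code{S}, \code{G} (kJ mol\eqn{^{-1}};
#'   entropies kJ mol\eqn{^{-1}} K\eqn{^{-1}})
#' @export
gas_rrho <- function(mass, frequencies = numeric(0), rot_constants = NULL,
                     sigma = 1, T = 298.15, P = 1) {
  if (mass <= 0) stop("mass must be positive")
  if (T <= 0 || P <= 0) stop("T and P must be positive")
  kB <- phys_const$kB; h <- phys_const$h
  R <- phys_const$R / 1e3
  m <- mass * phys_const$amu
  p_pa <- P * phys_const$atm_Pa
  # translation (Sackur-Tetrode)
  q_trans_V <- (2 * pi * m * kB * T / h^2)^1.5 * (kB * T / p_pa)
  S_trans <- R * (log(q_trans_V) + 5 / 2)
  U_trans <- 1.5 * R * T
  # rotation
  if (is.null(rot_constants) || length(rot_constants) == 0L) {
    S_rot <- 0; U_rot <- 0
  } else if (length(rot_constants) == 1L) {
    theta <- h * phys_const$c_cm * rot_constants / kB
    S_rot <- R * (log(T / (sigma * theta)) + 1)
    U_rot <- R * T
  } else if (length(rot_constants) == 3L) {
    theta <- h * phys_const$c_cm * rot_constants / kB
    q_rot <- sqrt(pi) / sigma * sqrt(T^3 / prod(theta))
    S_rot <- R * (log(q_rot) + 3 / 2)
    U_rot <- 1.5 * R * T
  } else stop("rot_constants must have length 0, 1 or 3")
  vib <- vibrational_thermo(frequencies, T)
  U <- U_trans + U_rot + vib$U_vib
  S <- S_trans + S_rot + vib$S_vib
  H <- U + R * T                               # PV term for an ideal gas
  out <- list(T = T, P = P,
              ZPE = vib$ZPE, U_vib = vib$U_vib, S_vib = vib$S_vib,
              U_trans = U_trans, S_trans = S_trans,
              U_rot = U_rot, S_rot = S_rot,
              U = U, H = H, S = S, G = H - T * S)
  class(out) <- "thermo_state"
  out
}

#' Vibration-only thermochemistry of an adsorbed (immobile) species
#'
#' A bound adsorbate has no meaningful translational or rotational degrees
#' of freedom in the fixed-environment fragment scheme; its thermal state
#' functions are purely vibrational and \eqn{H = U} (no PV term for a
#' surface species).
#'
#' @param frequencies fragment wavenumbers, cm\eqn{^{-1}}; imaginary modes
#'   are dropped with a warning
#' @param T temperature, K
#' @return a \code{thermo_state} with translational/rotational terms zero
#' @export
adsorbed_thermo <- function(frequencies, T = 298.15) {
  frequencies <- as.numeric(frequencies)
  n_imag <- sum(frequencies < 0)
  if (n_imag > 0) {
    warning(n_imag, " imaginary mode(s) excluded from thermochemistry")
    frequencies <- frequencies[frequencies >= 0]
  }
  vib <- vibrational_thermo(frequencies, T)
  out <- list(T = T, P = NA_real_,
              ZPE = vib$ZPE, U_vib = vib$U_vib, S_vib = vib$S_vib,
              U_trans = 0, S_trans = 0, U_rot = 0, S_rot = 0,
              U = vib$U_vib, H = vib$U_vib, S = vib$S_vib,
              G = vib$U_vib - T * vib$S_vib)
  class(out) <- "thermo_state"
  out
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state at T = %.2f K: H = %.3f, S = %.6f, G = %.3f kJ/mol\n",
              x$T, x$H, x$S, x$G))
  invisible(x)
}

#' Counterpoise ledger of complex/fragment energies
#'
#' Energies (kJ mol\eqn{^{-1}}) entering the counterpoise correction of the
#' basis-set superposition error: the complex, each fragment at the complex
#' geometry in the full (ghost-augmented) and in its own basis, and the
#' relaxed isolated fragments.
#'
#' @param E_complex complex energy at its geometry
#' @param E_fragA_ghost,E_fragB_ghost fragments at complex geometry, full basis
#' @param E_fragA_own,E_fragB_own fragments at complex geometry, own basis
#' @param E_A_relaxed,E_B_relaxed isolated relaxed fragments
#' @return object of class \code{cp_ledger}
#' @export
cp_ledger <- function(E_complex, E_fragA_ghost, E_fragB_ghost,
                      E_fragA_own, E_fragB_own, E_A_relaxed, E_B_relaxed) {
  vals <- c(E_complex, E_fragA_ghost, E_fragB_ghost, E_fragA_own,
            E_fragB_own, E_A_relaxed, E_B_relaxed)
  if (!all(is.finite(vals))) stop("all ledger energies must be finite")
  if (E_fragA_ghost > E_fragA_own + 1e-9 || E_fragB_ghost > E_fragB_own + 1e-9)
    stop("ghost-basis fragment energy above own-basis energy: violates the ",
         "variational bound; check the ledger")
  out <- list(E_complex = E_complex,
              E_fragA_ghost = E_fragA_ghost, E_fragB_ghost = E_fragB_ghost,
              E_fragA_own = E_fragA_own, E_fragB_own = E_fragB_own,
              E_A_relaxed = E_A_relaxed, E_B_relaxed = E_B_relaxed)
  class(out) <- "cp_ledger"
  out
}

#' Counterpoise-corrected interaction energy
#'
#' \deqn{\Delta E^{CP} = E_{complex} - E_A^{ghost} - E_B^{ghost}
#'   + (E_A^{own} - E_A^{relaxed}) + (E_B^{own} - E_B^{relaxed})}
#' The parenthesised terms are the fragment deformation energies, included
#' by default; with \code{deformation = FALSE} the correction reduces to the
#' rigid-fragment counterpoise interaction.
#'
#' @param ledger a [cp_ledger()]
#' @param deformation include fragment deformation contributions?
#' @return corrected interaction energy, kJ mol\eqn{^{-1}} (negative = bound)
#' @export
counterpoise <- function(ledger, deformation = TRUE) {
  stopifnot(inherits(ledger, "cp_ledger"))
  de <- ledger$E_complex - ledger$E_fragA_ghost - ledger$E_fragB_ghost
  if (deformation)
    de <- de + (ledger$E_fragA_own - ledger$E_A_relaxed) +
      (ledger$E_fragB_own - ledger$E_B_relaxed)
  de
}

#' Reaction deltas: products minus reactants
#'
#' \eqn{\Delta X = X_{products} - X_{reactants}} for \eqn{X = E, H, G};
#' negative values mean the product side is bound. Inputs are named numeric
#' vectors with components \code{E}, \code{H}, \code{G} (kJ mol\eqn{^{-1}}),
#' or \code{thermo_state} objects (whose \code{U} plays the role of E).
#' Multiple species on one side are passed as a list and summed.
#'
#' @param products,reactants a species (named vector or \code{thermo_state})
#'   or list of species
#' @param reaction optional label, e.g. \code{"first_adsorption"}
#' @return list of class \code{reaction_delta} with \code{dE}, \code{dH},
#'   \code{dG}
#' @export
reaction_delta <- function(products, reactants, reaction = NULL) {
  tot <- function(side) {
    if (inherits(side, "thermo_state") || is.numeric(side)) side <- list(side)
    Reduce(`+`, lapply(side, .ehg))
  }
  d <- tot(products) - tot(reactants)
  out <- list(dE = d[["E"]], dH = d[["H"]], dG = d[["G"]], reaction = reaction)
  class(out) <- "reaction_delta"
  out
}

.ehg <- function(x) {
  if (inherits(x, "thermo_state"))
    return(c(E = x$U, H = x$H, G = x$G))
  if (is.numeric(x) && all(c("E", "H", "G") %in% names(x)))
    return(c(E = unname(x["E"]), H = unname(x["H"]), G = unname(x["G"])))
  stop("species must be a thermo_state or a named vector with E, H, G")
}

#' @export
print.reaction_delta <- function(x, ...) {
  cat(sprintf("reaction_delta%s: dE = %.2f, dH = %.2f, dG = %.2f kJ/mol\n",
              if (!is.null(x$reaction)) paste0(" (", x$reaction, ")") else "",
              x$dE, x$dH, x$dG))
  invisible(x)
}
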