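#' Specification for synthetic fixtures
#'
#' One object carries every knob of the generators, and one integer seed
#' fixes every stochastic draw end-to-end. Defaults emulate the amide
#' adsorption study conditions: a gas-phase carbonyl stretch at 1754
#' cm\eqn{^{-1}} red-shifting to 1690--1710 cm\eqn{^{-1}} on H-bonding to a
#' surface silanol, an NH2 bend near 1600 cm\eqn{^{-1}}, five low-coverage
#' and seven high-coverage adducts with the reference Gibbs energies, and
#' pseudo-experimental traces with a gentle linear baseline and small
#' Gaussian noise.
#'
#' @param seed integer seed for all stochastic draws
#' @param n_atoms fragment size for generated Hessians
#' @param frequencies prescribed wavenumbers (cm\eqn{^{-1}}), length
#'   \code{3 * n_atoms}, all positive
#' @param intensities prescribed IR intensities (km mol\eqn{^{-1}}), same
#'   length
#' @param masses fragment masses, amu
#' @param dG_LC,dG_HC prescribed Gibbs energies (kJ mol\eqn{^{-1}}) for the
#'   low- and high-coverage adduct sets
#' @param co_shift range (cm\eqn{^{-1}}) of the adsorption red shift drawn
#'   for each adduct's carbonyl mode, relative to the 1754 cm\eqn{^{-1}} gas
#'   phase position
#' @param nh2_center,nh2_jitter NH2 bend position (cm\eqn{^{-1}}) and its
#'   half-spread
#' @param noise_sd standard deviation of spectral noise (absorbance units,
#'   relative to unit peak height)
#' @param baseline_offset,baseline_slope linear baseline added to
#'   pseudo-experimental traces
#' @return list of class \code{synthetic_spec}
#' @export
synthetic_spec <- function(seed = 1L, n_atoms = 2L,
                           frequencies = c(250, 420, 610, 980, 1600, 1754),
                           intensities = c(5, 10, 2, 40, 60, 400),
                           masses = NULL,
                           dG_LC = c(-13.3, 8.6, -9.6, -21.3, -19.3),
                           dG_HC = c(-1.7, -6.3, -17.9, 7.2, -12.0, 2.3, -1.5),
                           co_shift = c(44, 64),
                           nh2_center = 1600, nh2_jitter = 5,
                           noise_sd = 0.01,
                           baseline_offset = 0.02, baseline_slope = 1e-4) {
  if (length(frequencies) != 3L * n_atoms)
    stop("need 3 * n_atoms prescribed frequencies")
  if (any(frequencies <= 0)) stop("prescribed frequencies must be positive")
  if (length(intensities) != length(frequencies))
    stop("one intensity per frequency required")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (is.null(masses)) masses <- rep(12, n_atoms)
  if (length(masses) != n_atoms || any(masses <= 0))
    stop("need n_atoms positive masses")
  out <- list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
              frequencies = sort(as.numeric(frequencies)),
              intensities = as.numeric(intensities)[order(frequencies)],
              masses = as.numeric(masses),
              dG_LC = dG_LC, dG_HC = dG_HC, co_shift = co_shift,
              nh2_center = nh2_center, nh2_jitter = nh2_jitter,
              noise_sd = noise_sd, baseline_offset = baseline_offset,
              baseline_slope = baseline_slope)
  class(out) <- "synthetic_spec"
  out
}

# seeded random orthonormal matrix via QR, sign-fixed for reproducibility
.random_orthonormal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))), n)
}

#' Generate a fragment Hessian with known normal modes
#'
#' Builds the mass-weighted matrix \eqn{L\,\Lambda\,L^T} from the prescribed
#' wavenumbers and a seeded random orthonormal \eqn{L}, un-mass-weights it
#' to a Cartesian Hessian, and constructs dipole derivatives so that every
#' mode's IR intensity equals its prescription. The returned ground truth is
#' the certificate the analysis modules must recover.
#'
#' @param spec a [synthetic_spec()]
#' @return list with \code{fh} (a [fragment_hessian()]) and \code{truth}
#'   (a [mode_set()] with the prescribed frequencies and intensities)
#' @export
make_fragment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n3 <- 3L * spec$n_atoms
  withr_seed <- spec$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  L <- .random_orthonormal(n3)
  lambda <- .wavenumber_to_lambda(spec$frequencies)
  Hmw <- L %*% diag(lambda, n3) %*% t(L)
  msqrt <- rep(sqrt(spec$masses), each = 3L)
  H <- Hmw * outer(msqrt, msqrt)
  # dipole derivatives D = M^{1/2} L C with row i of C the per-mode target
  # dmu/dQ vector; then t(D) %*% (M^{-1/2} L) reproduces C column-wise
  dmudQ <- sqrt(spec$intensities / phys_const$ir_intensity_factor)
  C <- cbind(dmudQ, 0, 0)
  D <- (L * msqrt) %*% C
  fh <- fragment_hessian(H, spec$masses, dipole_derivatives = D)
  truth <- mode_set(frequencies = spec$frequencies, modes = L,
                    masses = spec$masses, intensities = spec$intensities)
  list(fh = fh, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic adduct ensemble with mode sets
#'
#' Emulates the two coverage regimes of an adsorption study: adducts carry
#' the prescribed Gibbs energies, and each gets a small fragment whose
#' carbonyl-stretch mode is red-shifted from the 1754 cm\eqn{^{-1}} gas
#' phase position by a seeded draw (H-bond shift) plus an NH2-bend mode near
#' 1600 cm\eqn{^{-1}}. Mode sets come from [make_fragment()] so the full
#' Hessian-to-spectrum pipeline is exercised, and scaled via
#' [apply_scaling()].
#'
#' @param spec a [synthetic_spec()]
#' @param coverage \code{"LC"}, \code{"HC"}, or \code{"both"}
#' @param T temperature for the populations, K
#' @param rules scale rules applied to each generated mode set
#' @return a single [adduct_ensemble()] for \code{"LC"}/\code{"HC"}, or a
#'   list of the two for \code{"both"}; each ensemble records the generator
#'   truth (unscaled carbonyl and NH2 positions) in attribute \code{"truth"}
#' @export
make_adduct_ensemble <- function(spec, coverage = c("LC", "HC", "both"),
                                 T = 298.15, rules = default_scale_rules()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  coverage <- match.arg(coverage)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  build <- function(dG, cov, names_, topo) {
    n <- length(dG)
    co_pos <- 1754 - stats::runif(n, spec$co_shift[1], spec$co_shift[2])
    nh2_pos <- spec$nh2_center +
      stats::runif(n, -spec$nh2_jitter, spec$nh2_jitter)
    mode_sets <- vector("list", n)
    for (i in seq_len(n)) {
      raw_f <- c(250 + 50 * i, 600, 980, 1200, nh2_pos[i], co_pos[i])
      raw_I <- c(5, 2, 40, 20, 60, 400)   # marker modes carry 60 and 400
      ord <- order(raw_f)
      sub <- spec
      sub$seed <- spec$seed + 100L * (cov == "HC") + i
      sub$n_atoms <- 2L
      sub$frequencies <- raw_f[ord]
      sub$intensities <- raw_I[ord]
      sub$masses <- rep(10, 2L)
      fr <- make_fragment(sub)
      ms <- normal_modes(fr$fh)
      ms <- ir_intensities(fr$fh, ms)
      mode_sets[[i]] <- apply_scaling(ms, rules)
    }
    en <- data.frame(name = names_, coverage = cov, topology = topo,
                     dE_c = NA_real_, dE_disp = NA_real_, dH_c = NA_real_,
                     dG_c = dG, stringsAsFactors = FALSE)
    class(en) <- c("adduct_energetics", "data.frame")
    e <- adduct_ensemble(en, mode_sets, T = T)
    attr(e, "truth") <- data.frame(name = names_, co_position = co_pos,
                                   nh2_position = nh2_pos)
    e
  }
  lc <- if (coverage != "HC")
    build(spec$dG_LC, "LC", paste0("SiO2-FA", seq_along(spec$dG_LC)),
          "monomer")
  hc <- if (coverage != "LC")
    build(spec$dG_HC, "HC",
          c(paste0("SiO2-2FA", seq_len(min(3, length(spec$dG_HC)))),
            paste0("SiO2-Dim", seq_len(max(0, length(spec$dG_HC) - 3)))),
          c(rep("double_monomer", min(3, length(spec$dG_HC))),
            rep("dimer", max(0, length(spec$dG_HC) - 3))))
  switch(coverage, LC = lc, HC = hc, both = list(LC = lc, HC = hc))
}

#' Generate a pseudo-experimental spectrum with known truth
#'
#' The ensemble spectrum of \code{e} plus a linear baseline and seeded
#' Gaussian noise, tagged \code{"experimental"}. The true underlying peak
#' positions (the ensemble's population-weighted band centres) are recorded
#' in attribute \code{"truth"} so recovery by [baseline_and_peaks()] can be
#' validated.
#'
#' @param e an [adduct_ensemble()] with mode sets
#' @param spec a [synthetic_spec()] (supplies seed, noise, baseline)
#' @param params a [synthesis_params()]
#' @return an experimental-kind [spectrum_ir()]
#' @export
make_experimental_spectrum <- function(e, spec, params = synthesis_params()) {
  stopifnot(inherits(e, "adduct_ensemble"), inherits(spec, "synthetic_spec"))
  sim <- ensemble_spectrum(e, params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 2L)
  w <- sim$wavenumbers
  scale_ref <- max(sim$absorbance)
  base <- spec$baseline_offset + spec$baseline_slope * (w - w[1])
  noise <- stats::rnorm(length(w), sd = spec$noise_sd) * max(scale_ref, 1e-12)
  out <- spectrum_ir(w, sim$absorbance + (base + noise) * 1,
                     kind = "experimental",
                     meta = list(generator = "synthetic",
                                 noise_sd = spec$noise_sd))
  attr(out, "truth") <- attr(e, "truth")
  out
}
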