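#' Fragment Hessian for partial vibrational analysis
#'
#' Bundles the Cartesian second-derivative block of the fragment whose
#' vibrations are analysed (the adsorbed molecule(s) plus the surface
#' hydroxyls, with all other atoms held fixed), the fragment atomic masses,
#' and optionally the Cartesian dipole derivatives needed for IR
#' intensities.
#'
#' @param H symmetric 3N x 3N matrix of energy second derivatives,
#'   kJ mol\eqn{^{-1}} \eqn{\mbox{\AA}^{-2}}
#' @param masses N atomic masses, amu
#' @param dipole_derivatives optional 3N x 3 matrix of Cartesian dipole
#'   derivatives, D \eqn{\mbox{\AA}^{-1}}
#' @param fragment_atoms optional index list into a parent structure
#' @return object of class \code{fragment_hessian}
#' @export
fragment_hessian <- function(H, masses, dipole_derivatives = NULL,
                             fragment_atoms = NULL) {
  H <- as.matrix(H)
  n <- length(masses)
  if (n < 1L) stop("fragment must contain at least one atom")
  if (any(masses <= 0)) stop("atomic masses must be positive")
  if (nrow(H) != 3L * n || ncol(H) != 3L * n)
    stop("H must be 3N x 3N for N = length(masses)")
  asym <- max(abs(H - t(H)))
  scale <- max(abs(H), 1e-300)
  if (asym / scale > 1e-8)
    stop("Hessian is not symmetric (relative asymmetry ",
         format(asym / scale, digits = 3), ")")
  if (!is.null(dipole_derivatives)) {
    dipole_derivatives <- as.matrix(dipole_derivatives)
    if (nrow(dipole_derivatives) != 3L * n || ncol(dipole_derivatives) != 3L)
      stop("dipole_derivatives must be 3N x 3")
  }
  out <- list(H = (H + t(H)) / 2, masses = as.numeric(masses),
              dipole_derivatives = dipole_derivatives,
              fragment_atoms = fragment_atoms)
  class(out) <- "fragment_hessian"
  out
}

#' Extract a fragment sub-Hessian from a full Hessian
#'
#' The environment is treated as fixed: rows and columns of non-fragment
#' atoms are deleted outright (no projection), the convention of partial
#' Hessian vibrational analysis with frozen surroundings.
#'
#' @param full_H 3M x 3M Cartesian Hessian over all M atoms
#' @param fragment_atoms unique 1-based atom indices defining the fragment
#' @param masses length-M atomic masses (amu); subset is carried along
#' @param dipole_derivatives optional 3M x 3 Cartesian dipole derivatives
#' @return a [fragment_hessian()] over the fragment atoms
#' @export
reduce_hessian <- function(full_H, fragment_atoms, masses,
                           dipole_derivatives = NULL) {
  full_H <- as.matrix(full_H)
  M <- nrow(full_H) / 3L
  if (length(fragment_atoms) == 0L) stop("fragment_atoms must be non-empty")
  if (anyDuplicated(fragment_atoms)) stop("fragment_atoms must be unique")
  if (any(fragment_atoms < 1L | fragment_atoms > M))
    stop("fragment_atoms out of range 1..", M)
  idx <- as.vector(vapply(fragment_atoms,
                          function(a) (3L * (a - 1L) + 1L):(3L * a),
                          integer(3)))
  fragment_hessian(full_H[idx, idx, drop = FALSE], masses[fragment_atoms],
                   dipole_derivatives = if (!is.null(dipole_derivatives))
                     as.matrix(dipole_derivatives)[idx, , drop = FALSE],
                   fragment_atoms = fragment_atoms)
}

#' Harmonic normal modes of a fragment Hessian
#'
#' Diagonalises the mass-weighted matrix \eqn{M^{-1/2} H M^{-1/2}}.
#' Wavenumbers are \eqn{\tilde\nu_i = \sqrt{\lambda_i}/(2\pi c)} for
#' non-negative eigenvalues; negative eigenvalues (imaginary modes) are
#' encoded as negative wavenumbers. No translation/rotation projection is
#' applied — the fragment is embedded in a fixed environment, so all 3N
#' degrees of freedom are genuine.
#'
#' @param fh a [fragment_hessian()]
#' @return object of class \code{mode_set}: ascending \code{frequencies}
#'   (cm\eqn{^{-1}}), orthonormal mass-weighted \code{modes} (columns),
#'   \code{masses}, and empty intensity/scaling slots
#' @export
normal_modes <- function(fh) {
  stopifnot(inherits(fh, "fragment_hessian"))
  minv <- rep(1 / sqrt(fh$masses), each = 3L)
  Hmw <- fh$H * outer(minv, minv)
  eig <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  lambda <- rev(eig$values)
  L <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  nu <- .lambda_to_wavenumber(lambda)
  ord <- order(nu)
  mode_set(frequencies = nu[ord], modes = L[, ord, drop = FALSE],
           masses = fh$masses)
}

#' Construct a mode set
#'
#' Usually produced by [normal_modes()]; the constructor is exported so that
#' prescribed mode sets (e.g., synthetic fixtures) can be built directly.
#'
#' @param frequencies wavenumbers, cm\eqn{^{-1}}, ascending; negative values
#'   encode imaginary modes
#' @param modes mass-weighted orthonormal mode vectors (columns); may be
#'   \code{NULL} for prescribed sets used only in spectrum synthesis
#' @param masses fragment atomic masses, amu (required with \code{modes})
#' @param intensities per-mode IR intensities, km mol\eqn{^{-1}}
#' @param scaled_frequencies per-mode scaled wavenumbers
#' @param scale_class per-mode scale class label or \code{NA}
#' @return object of class \code{mode_set}
#' @export
mode_set <- function(frequencies, modes = NULL, masses = NULL,
                     intensities = NULL, scaled_frequencies = NULL,
                     scale_class = NULL) {
  frequencies <- as.numeric(frequencies)
  if (is.unsorted(frequencies)) stop("frequencies must be ascending")
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    if (ncol(modes) != length(frequencies))
      stop("one mode vector per frequency required")
    G <- crossprod(modes)
    if (max(abs(G - diag(ncol(modes)))) > 1e-8)
      stop("mode vectors are not orthonormal to 1e-8")
    if (is.null(masses)) stop("masses required when mode vectors are given")
  }
  out <- list(frequencies = frequencies, modes = modes,
              masses = if (!is.null(masses)) as.numeric(masses),
              intensities = if (!is.null(intensities)) as.numeric(intensities),
              scaled_frequencies = if (!is.null(scaled_frequencies))
                as.numeric(scaled_frequencies),
              scale_class = if (!is.null(scale_class)) as.character(scale_class))
  class(out) <- "mode_set"
  out
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d modes, %.1f-%.1f cm^-1%s%s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              if (!is.null(x$intensities)) ", with IR intensities" else "",
              if (!is.null(x$scaled_frequencies)) ", scaled" else ""))
  invisible(x)
}

#' Harmonic IR intensities from dipole derivatives
#'
#' For each mode the dipole derivative along the normal coordinate is
#' \eqn{\partial\mu/\partial Q_i = \sum_k (\partial\mu/\partial x_k)\,
#' (M^{-1/2} L_i)_k}; the intensity is its squared norm times a single
#' conversion constant (42.2561 km mol\eqn{^{-1}} per
#' (D \eqn{\mbox{\AA}^{-1}} amu\eqn{^{-1/2}})\eqn{^2}, i.e.
#' \eqn{N_A\pi/3c^2} in these units).
#'
#' @param fh the [fragment_hessian()] carrying \code{dipole_derivatives}
#' @param ms the [normal_modes()] of \code{fh}
#' @return \code{ms} with the \code{intensities} slot filled (km mol\eqn{^{-1}})
#' @export
ir_intensities <- function(fh, ms) {
  stopifnot(inherits(fh, "fragment_hessian"), inherits(ms, "mode_set"))
  if (is.null(fh$dipole_derivatives))
    stop("no dipole derivatives in this fragment Hessian; rebuild it with ",
         "dipole_derivatives or use the intensity-free workflow ",
         "(frequencies only)")
  if (is.null(ms$modes)) stop("mode set carries no mode vectors")
  minv <- rep(1 / sqrt(fh$masses), each = 3L)
  Lcart <- ms$modes * minv                       # M^{-1/2} L, per column
  dmudQ <- crossprod(fh$dipole_derivatives, Lcart)  # 3 x nmodes
  ms$intensities <- phys_const$ir_intensity_factor * colSums(dmudQ^2)
  ms
}

#' Define a frequency scaling rule
#'
#' Mode-class scaling corrects systematic harmonic/anharmonic offsets: all
#' modes falling in the window are multiplied by the factor, the ratio of an
#' experimental to a calculated reference frequency for that mode type.
#'
#' @param class_label e.g. \code{"CO_stretch"}
#' @param window c(lo, hi) wavenumber window selecting candidate modes,
#'   cm\eqn{^{-1}}
#' @param factor positive dimensionless scale factor
#' @return object of class \code{scale_rule}
#' @export
scale_rule <- function(class_label, window, factor) {
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lo < hi)")
  if (factor <= 0) stop("scale factor must be positive")
  out <- list(class_label = as.character(class_label), window = window,
              factor = as.numeric(factor))
  class(out) <- "scale_rule"
  out
}

#' Default scale rules for the amide carbonyl-stretch / NH2-bend analysis
#'
#' C=O stretch modes (window 1600-1800 cm\eqn{^{-1}}) scaled by 0.9972 and
#' NH2 bending modes (1500-1600 cm\eqn{^{-1}}) by 1.0102, the factors
#' obtained from the experimental/calculated frequency ratio of free
#' formamide. Windows are an implementation vehicle for the per-mode-type
#' assignment and can be overridden in the run configuration.
#'
#' @return list of two [scale_rule()]s
#' @export
default_scale_rules <- function() {
  list(scale_rule("CO_stretch", c(1600, 1800), 0.9972),
       scale_rule("NH2_bend",   c(1500, 1600), 1.0102))
}

#' Apply mode-class frequency scaling
#'
#' @param ms a [mode_set()]
#' @param rules list of [scale_rule()]s with pairwise non-overlapping windows
#' @return \code{ms} with \code{scaled_frequencies} and \code{scale_class}
#'   filled; modes outside every window keep their unscaled frequency and
#'   class \code{NA}
#' @export
apply_scaling <- function(ms, rules = default_scale_rules()) {
  stopifnot(inherits(ms, "mode_set"))
  if (inherits(rules, "scale_rule")) rules <- list(rules)
  if (length(rules) > 1L) {
    wins <- t(vapply(rules, function(r) r$window, numeric(2)))
    ord <- order(wins[, 1])
    if (any(wins[ord, 2][-nrow(wins)] > wins[ord, 1][-1]))
      stop("scale-rule windows overlap: mode class would be ambiguous")
  }
  scaled <- ms$frequencies
  cls <- rep(NA_character_, length(scaled))
  for (r in rules) {
    # half-open [lo, hi) so that touching windows stay unambiguous
    sel <- ms$frequencies >= r$window[1] & ms$frequencies < r$window[2]
    scaled[sel] <- ms$frequencies[sel] * r$factor
    cls[sel] <- r$class_label
  }
  ms$scaled_frequencies <- scaled
  ms$scale_class <- cls
  ms
}

#' Export a mode set as a data frame
#'
#' @param x a [mode_set()]
#' @param ... unused
#' @return data.frame with mode index, frequency, scaled frequency,
#'   intensity, and scale class
#' @export
as.data.frame.mode_set <- function(x, ...) {
  n <- length(x$frequencies)
  data.frame(mode = seq_len(n), frequency = x$frequencies,
             scaled_frequency = x$scaled_frequencies %||% x$frequencies,
             intensity = x$intensities %||% rep(NA_real_, n),
             scale_class = x$scale_class %||% rep(NA_character_, n),
             stringsAsFactors = FALSE)
}
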