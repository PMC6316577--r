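#' Boltzmann populations from Gibbs energies
#'
#' \deqn{p_i = \frac{e^{-\Delta G_i/RT}}{\sum_j e^{-\Delta G_j/RT}}}
#' computed shift-stably (the minimum \eqn{\Delta G} is subtracted before
#' exponentiation, which leaves the populations unchanged and avoids
#' overflow).
#'
#' @param dG Gibbs energies, kJ mol\eqn{^{-1}}; any common shift cancels
#' @param T temperature, K
#' @return populations summing to 1
#' @export
boltzmann_populations <- function(dG, T = 298.15) {
  if (length(dG) == 0L) stop("dG list must be non-empty")
  if (T <= 0) stop("temperature must be > 0 K")
  dG <- as.numeric(dG)
  if (any(!is.finite(dG))) stop("dG values must be finite")
  RT <- phys_const$R / 1e3 * T
  w <- exp(-(dG - min(dG)) / RT)
  w / sum(w)
}

#' Build an ensemble of competing surface adducts
#'
#' Members must all belong to one coverage class: populations are meaningful
#' only among adducts competing for the same adsorption state (single
#' adducts at low coverage, double adducts at high coverage), so mixing
#' classes is an error.
#'
#' @param energetics an \code{adduct_energetics} data.frame
#'   (see [read_energy_table()])
#' @param mode_sets optional named or positional list of [mode_set()]s, one
#'   per member (may contain \code{NULL}s)
#' @param T temperature for the populations, K
#' @return object of class \code{adduct_ensemble} with a \code{populations}
#'   vector summing to 1
#' @export
adduct_ensemble <- function(energetics, mode_sets = NULL, T = 298.15) {
  stopifnot(is.data.frame(energetics))
  cov <- unique(energetics$coverage[!is.na(energetics$coverage)])
  if (length(cov) > 1L)
    stop("mixed coverage classes in one ensemble (", paste(cov, collapse = ", "),
         "); build one ensemble per class")
  if (!is.null(mode_sets)) {
    if (length(mode_sets) != nrow(energetics))
      stop("need one mode set (possibly NULL) per adduct")
    if (!is.null(names(mode_sets)))
      mode_sets <- mode_sets[match(energetics$name, names(mode_sets))]
  }
  p <- boltzmann_populations(energetics$dG_c, T)
  out <- list(energetics = energetics, mode_sets = mode_sets,
              T = T, populations = p,
              coverage = if (length(cov)) cov else NA_character_)
  class(out) <- "adduct_ensemble"
  out
}

#' @export
print.adduct_ensemble <- function(x, ...) {
  cat(sprintf("adduct_ensemble (%s): %d members at T = %.2f K\n",
              x$coverage, nrow(x$energetics), x$T))
  print(populations_table(x))
  invisible(x)
}

#' Populations table of an ensemble
#'
#' @param e an [adduct_ensemble()]
#' @param digits decimals for the rounded column (half-up, the convention of
#'   printed population tables)
#' @return data.frame with name, dG_c, population, rounded population
#' @export
populations_table <- function(e, digits = 2) {
  stopifnot(inherits(e, "adduct_ensemble"))
  data.frame(name = e$energetics$name, dG_c = e$energetics$dG_c,
             p = e$populations, p_rounded = round_half_up(e$populations, digits),
             stringsAsFactors = FALSE)
}

#' Spectrum synthesis parameters
#'
#' @param fwhm Gaussian full width at half maximum, cm\eqn{^{-1}}
#' @param grid c(lo, hi, step), cm\eqn{^{-1}}
#' @param amplitude \code{"height"}: each Gaussian's peak height equals the
#'   mode intensity; \code{"area"}: each integrates to the intensity
#' @return list of class \code{synthesis_params}
#' @export
synthesis_params <- function(fwhm = 20, grid = c(1500, 1800, 0.5),
                             amplitude = c("height", "area")) {
  amplitude <- match.arg(amplitude)
  if (fwhm <= 0) stop("fwhm must be positive")
  if (length(grid) != 3L || grid[1] >= grid[2] || grid[3] <= 0)
    stop("grid must be c(lo < hi, step > 0)")
  out <- list(fwhm = fwhm, grid = as.numeric(grid), amplitude = amplitude)
  class(out) <- "synthesis_params"
  out
}

.grid_points <- function(grid) seq(grid[1], grid[2], by = grid[3])

#' Simulated IR spectrum of a single adduct
#'
#' Overlapping Gaussians centred at the scaled mode frequencies with a
#' common FWHM. Under the height convention each Gaussian's maximum equals
#' the mode's IR intensity; under the area convention its integral does.
#'
#' @param ms a [mode_set()] with \code{scaled_frequencies} (see
#'   [apply_scaling()]) and \code{intensities}
#' @param params a [synthesis_params()]
#' @return a simulated [spectrum_ir()]
#' @export
adduct_spectrum <- function(ms, params = synthesis_params()) {
  stopifnot(inherits(ms, "mode_set"), inherits(params, "synthesis_params"))
  if (is.null(ms$scaled_frequencies))
    stop("mode set has no scaled frequencies; run apply_scaling() first")
  w <- .grid_points(params$grid)
  centers <- ms$scaled_frequencies
  inten <- ms$intensities %||% rep(1, length(centers))
  keep <- centers > 0
  centers <- centers[keep]; inten <- inten[keep]
  sigma <- params$fwhm / (2 * sqrt(2 * log(2)))
  a <- numeric(length(w))
  if (length(centers)) {
    lo <- params$grid[1] - 4 * params$fwhm
    hi <- params$grid[2] + 4 * params$fwhm
    inside <- centers >= params$grid[1] & centers <= params$grid[2]
    if (!any(centers >= lo & centers <= hi) && length(centers))
      warning("grid excludes all modes; returning a zero spectrum")
    for (k in seq_along(centers)) {
      amp <- if (params$amplitude == "height") inten[k]
      else inten[k] / (sigma * sqrt(2 * pi))
      a <- a + amp * exp(-(w - centers[k])^2 / (2 * sigma^2))
    }
  }
  spectrum_ir(w, a, kind = "simulated",
              meta = list(fwhm = params$fwhm, amplitude = params$amplitude))
}

#' Population-weighted ensemble spectrum
#'
#' Linear combination \eqn{\sum_i p_i \cdot} (adduct spectrum \eqn{i}) on a
#' common grid. Members whose population falls below \code{threshold} may
#' lack a mode set and contribute nothing (nil components); a member above
#' the threshold without modes is an error.
#'
#' @param e an [adduct_ensemble()] carrying mode sets
#' @param params a [synthesis_params()]
#' @param threshold population below which a missing mode set is tolerated
#' @return a simulated [spectrum_ir()]
#' @export
ensemble_spectrum <- function(e, params = synthesis_params(),
                              threshold = 0.005) {
  stopifnot(inherits(e, "adduct_ensemble"))
  if (is.null(e$mode_sets)) stop("ensemble has no mode sets")
  w <- .grid_points(params$grid)
  a <- numeric(length(w))
  for (i in seq_along(e$populations)) {
    ms <- e$mode_sets[[i]]
    if (is.null(ms)) {
      if (e$populations[i] > threshold)
        stop("member '", e$energetics$name[i], "' has population ",
             format(e$populations[i], digits = 3),
             " above threshold but no mode set")
      next
    }
    a <- a + e$populations[i] * adduct_spectrum(ms, params)$absorbance
  }
  spectrum_ir(w, a, kind = "simulated",
              meta = list(fwhm = params$fwhm, amplitude = params$amplitude,
                          coverage = e$coverage, T = e$T))
}

#' Normalize a simulated spectrum to an experimental reference
#'
#' Rescales the simulated trace so that its maximum inside the window equals
#' the experimental maximum there, the convention used when overlaying
#' simulated and measured bands. Idempotent.
#'
#' @param sim simulated [spectrum_ir()]
#' @param exp experimental [spectrum_ir()]
#' @param window c(lo, hi) wavenumber range; default: the overlap of the two
#'   grids
#' @return rescaled copy of \code{sim}
#' @export
normalize_to_reference <- function(sim, exp, window = NULL) {
  stopifnot(inherits(sim, "spectrum_ir"), inherits(exp, "spectrum_ir"))
  if (is.null(window))
    window <- c(max(min(sim$wavenumbers), min(exp$wavenumbers)),
                min(max(sim$wavenumbers), max(exp$wavenumbers)))
  if (window[1] >= window[2]) stop("window does not overlap both grids")
  in_s <- sim$wavenumbers >= window[1] & sim$wavenumbers <= window[2]
  in_e <- exp$wavenumbers >= window[1] & exp$wavenumbers <= window[2]
  if (!any(in_s) || !any(in_e)) stop("window does not overlap both grids")
  ms <- max(sim$absorbance[in_s]); me <- max(exp$absorbance[in_e])
  if (ms <= 0) stop("simulated spectrum has non-positive maximum in window; ",
                    "cannot normalize")
  out <- sim
  out$absorbance <- sim$absorbance * (me / ms)
  out$meta$normalization <- list(window = window, factor = me / ms)
  out
}

#' Baseline subtraction and peak/shoulder picking
#'
#' Subtracts the linear baseline through the window endpoints, then locates
#' band maxima (local maxima above a prominence threshold) and shoulders
#' (dips of the smoothed second derivative away from any maximum — the
#' curvature signature of an unresolved component).
#'
#' @param sp a [spectrum_ir()]
#' @param window c(lo, hi) within the grid, spanning at least 5 grid points
#' @param prominence minimum height above baseline for a maximum or
#'   shoulder, as a fraction of the window's tallest signal
#' @param smooth half-width (grid points) of the cubic Savitzky-Golay
#'   filter used for smoothing and differentiation; the default (12 points,
#'   i.e. 6 cm\eqn{^{-1}} on a 0.5 cm\eqn{^{-1}} grid) preserves bands of
#'   ~20 cm\eqn{^{-1}} FWHM while suppressing white noise
#' @return list with \code{corrected} (baseline-subtracted [spectrum_ir()]
#'   over the window), \code{maxima} and \code{shoulders} (wavenumbers,
#'   cm\eqn{^{-1}})
#' @export
baseline_and_peaks <- function(sp, window = NULL, prominence = 0.05,
                               smooth = 12) {
  stopifnot(inherits(sp, "spectrum_ir"))
  if (is.null(window)) window <- range(sp$wavenumbers)
  idx <- which(sp$wavenumbers >= window[1] & sp$wavenumbers <= window[2])
  if (length(idx) < 5L) stop("window narrower than 5 grid points")
  w <- sp$wavenumbers[idx]; a <- sp$absorbance[idx]
  n <- length(w)
  base <- a[1] + (a[n] - a[1]) * (w - w[1]) / (w[n] - w[1])
  y <- a - base
  corrected <- spectrum_ir(w, y, kind = sp$kind,
                           meta = c(sp$meta, list(baseline = "linear")))
  step <- diff(w)[1]
  sgfilt <- function(v, m = 0, half = as.integer(smooth)) {
    nwin <- min(2L * half + 1L, if (n %% 2L) n else n - 1L)
    if (nwin < 5L) { if (m == 0) return(v) else
      return(c(NA, diff(v, differences = 2), NA) / step^2) }
    as.numeric(signal::sgolayfilt(v, p = 3, n = nwin, m = m)) /
      if (m == 2) step^2 else 1
  }
  ys <- sgfilt(y)
  top <- max(ys)
  # a trace that is flat to rounding noise has no peaks
  has_signal <- top > 1e-10 * max(abs(a), 1)
  maxima <- numeric(0)
  if (has_signal) {
    k <- max(2L, as.integer(smooth) %/% 2L)
    for (i in 2:(n - 1L)) {
      lo <- max(1L, i - k); hi <- min(n, i + k)
      if (ys[i] >= max(ys[lo:hi]) && ys[i] > ys[lo] && ys[i] > ys[hi] &&
          ys[i] >= prominence * top)
        maxima <- c(maxima, w[i])
    }
    if (length(maxima) > 1L)      # merge plateau duplicates
      maxima <- maxima[c(TRUE, diff(maxima) > k * step)]
  }
  # shoulders: local minima of the second derivative away from any located
  # maximum — an unresolved component pulls the curvature down locally even
  # when the trace itself has no separate maximum there. A persistence
  # criterion (the dip must rise by eps on both sides before a deeper
  # minimum occurs) rejects noise wiggles.
  shoulders <- numeric(0)
  if (n >= 11L && has_signal) {
    # a narrower window for the derivative: resolving a shoulder needs the
    # curvature dip to survive the filter
    d2s <- sgfilt(y, m = 2, half = max(3L, as.integer(smooth) %/% 2L))
    eps <- 0.002 * max(abs(d2s), na.rm = TRUE)
    excl <- max(5, 4 * step)                  # cm^-1 around a located maximum
    cand <- integer(0)
    for (i in 2:(n - 1L)) {
      if (is.na(d2s[i]) || is.na(d2s[i - 1]) || is.na(d2s[i + 1])) next
      if (!(d2s[i] < 0 && d2s[i] <= d2s[i - 1] && d2s[i] <= d2s[i + 1])) next
      if (ys[i] < prominence * top) next
      if (length(maxima) && min(abs(maxima - w[i])) <= excl) next
      if (.dip_persistence(d2s, i) >= eps) cand <- c(cand, i)
    }
    if (length(cand)) {                        # cluster near-adjacent dips
      cl <- cumsum(c(1L, diff(cand) > max(4L, as.integer(smooth) %/% 2L)))
      shoulders <- vapply(split(cand, cl), function(ix)
        w[ix[which.min(d2s[ix])]], numeric(1))
      names(shoulders) <- NULL
    }
  }
  list(corrected = corrected, maxima = maxima, shoulders = shoulders)
}

# smallest rise of v on either side of a local minimum at i before a value
# below v[i] is reached (a 1D topographic prominence)
.dip_persistence <- function(v, i) {
  rise <- function(ix) {
    best <- 0
    for (j in ix) {
      if (is.na(v[j])) break
      if (v[j] < v[i]) break
      best <- max(best, v[j] - v[i])
    }
    best
  }
  n <- length(v)
  left <- if (i > 1L) rise((i - 1L):1L) else 0
  right <- if (i < n) rise((i + 1L):n) else 0
  min(left, right)
}
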