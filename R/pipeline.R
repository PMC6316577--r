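#' Run the full adduct-spectrum analysis
#'
#' Orchestrates the stages end-to-end: ingest (or synthesize) adduct
#' energetics and mode sets, compute Boltzmann populations per coverage
#' class, synthesize the population-weighted spectrum, optionally normalize
#' against an experimental reference, and report peak positions. Low- and
#' high-coverage ensembles are always treated separately: their members
#' compete for different adsorption states.
#'
#' @param config a [run_config()]
#' @param energy_table path to an adduct energy CSV (see
#'   [read_energy_table()]); ignored when \code{synthetic} is given
#' @param experimental path to an experimental spectrum (CSV or JCAMP-DX),
#'   or a [spectrum_ir()]; optional
#' @param mode_sets list of [mode_set()]s matching the energy table rows;
#'   optional (populations-only run without them)
#' @param synthetic a [synthetic_spec()] to generate all inputs instead of
#'   reading them
#' @param out_dir if given, writes \code{populations.csv},
#'   \code{spectrum_<coverage>.csv} and \code{report.json} there
#' @return list of class \code{run_report}: \code{populations} data.frame,
#'   \code{spectrum} (or NULL), \code{peaks}, \code{settings}, and paths of
#'   files written
#' @export
run_pipeline <- function(config = run_config(), energy_table = NULL,
                         experimental = NULL, mode_sets = NULL,
                         synthetic = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(synthetic)) {
    ens <- make_adduct_ensemble(synthetic, coverage = config$coverage,
                                T = config$temperature,
                                rules = config$scale_rules)
    if (is.null(experimental))
      experimental <- make_experimental_spectrum(
        ens, synthetic, synthesis_params(config$fwhm, config$grid,
                                         config$amplitude))
  } else {
    if (is.null(energy_table)) stop("need an energy table or a synthetic spec")
    en <- read_energy_table(energy_table)
    keep <- is.na(en$coverage) | en$coverage == config$coverage
    if (!any(keep))
      stop("no rows of coverage class ", config$coverage, " in ", energy_table)
    en <- en[keep, , drop = FALSE]
    class(en) <- c("adduct_energetics", "data.frame")
    ens <- adduct_ensemble(en, mode_sets = mode_sets, T = config$temperature)
  }
  if (is.character(experimental)) experimental <- read_spectrum(experimental)

  pops <- populations_table(ens)
  params <- synthesis_params(config$fwhm, config$grid, config$amplitude)
  spectrum <- NULL; peaks <- NULL
  if (!is.null(ens$mode_sets)) {
    spectrum <- ensemble_spectrum(ens, params)
    if (!is.null(experimental)) {
      spectrum <- normalize_to_reference(spectrum, experimental)
    } else {
      warning("no experimental reference; spectrum written unnormalized")
    }
    bp_sim <- baseline_and_peaks(spectrum)
    peaks <- list(simulated = bp_sim[c("maxima", "shoulders")])
    if (!is.null(experimental)) {
      bp_exp <- baseline_and_peaks(experimental,
                                   window = range(spectrum$wavenumbers))
      peaks$experimental <- bp_exp[c("maxima", "shoulders")]
      peaks$offsets <- compare_peaks(spectrum, experimental)
    }
  }
  settings <- list(temperature = config$temperature, fwhm = config$fwhm,
                   grid = config$grid, coverage = config$coverage,
                   amplitude = config$amplitude,
                   R = phys_const$R,
                   scale_factors = vapply(config$scale_rules,
                                          function(r) r$factor, numeric(1)))
  report <- list(populations = pops, spectrum = spectrum, peaks = peaks,
                 settings = settings, files = character(0))
  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_pop <- file.path(out_dir, "populations.csv")
    write.csv(pops, f_pop, row.names = FALSE)
    report$files <- f_pop
    if (!is.null(spectrum)) {
      f_sp <- file.path(out_dir, sprintf("spectrum_%s.csv", config$coverage))
      write_spectrum(spectrum, f_sp)
      report$files <- c(report$files, f_sp)
    }
    f_rep <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(populations = pops, peaks = peaks, settings = settings),
      f_rep, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    report$files <- c(report$files, f_rep)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s, T = %.2f K)\n", x$settings$coverage,
              x$settings$temperature))
  print(x$populations)
  if (!is.null(x$peaks)) {
    cat("simulated maxima (cm^-1):",
        paste(sprintf("%.1f", x$peaks$simulated$maxima), collapse = ", "), "\n")
    if (length(x$peaks$simulated$shoulders))
      cat("simulated shoulders (cm^-1):",
          paste(sprintf("%.1f", x$peaks$simulated$shoulders), collapse = ", "),
          "\n")
  }
  invisible(x)
}

#' Peak offsets between a simulated and an experimental spectrum
#'
#' Picks band maxima in both traces over their shared window and pairs each
#' simulated maximum with the nearest experimental one, reporting the
#' signed offset (simulated minus experimental, cm\eqn{^{-1}}) — e.g., a
#' systematic red shift of the synthesized band shows up as a negative
#' offset.
#'
#' @param sim,exp [spectrum_ir()] objects with overlapping grids
#' @param window optional c(lo, hi) restricting the comparison
#' @return data.frame with simulated position, matched experimental
#'   position, and offset; zero rows (with a warning) when no peaks are
#'   found
#' @export
compare_peaks <- function(sim, exp, window = NULL) {
  stopifnot(inherits(sim, "spectrum_ir"), inherits(exp, "spectrum_ir"))
  shared <- c(max(min(sim$wavenumbers), min(exp$wavenumbers)),
              min(max(sim$wavenumbers), max(exp$wavenumbers)))
  if (shared[1] >= shared[2]) stop("spectra do not share a window")
  if (!is.null(window)) shared <- c(max(shared[1], window[1]),
                                    min(shared[2], window[2]))
  if (shared[1] >= shared[2]) stop("requested window outside the shared range")
  ps <- baseline_and_peaks(sim, shared)$maxima
  pe <- baseline_and_peaks(exp, shared)$maxima
  if (!length(ps) || !length(pe)) {
    warning("no peaks found in one or both traces")
    return(data.frame(sim = numeric(0), exp = numeric(0),
                      offset = numeric(0)))
  }
  matched <- vapply(ps, function(p) pe[which.min(abs(pe - p))], numeric(1))
  data.frame(sim = ps, exp = matched, offset = ps - matched)
}
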