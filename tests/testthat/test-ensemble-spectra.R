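test_that("Boltzmann populations are normalized, shift-invariant, monotone", {
  dG <- c(-12, -3, 0, 4.5)
  p <- boltzmann_populations(dG)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # adding any constant leaves populations unchanged
  expect_equal(boltzmann_populations(dG + 37.2), p, tolerance = 1e-12)
  # equal energies split evenly
  expect_equal(boltzmann_populations(c(-5, -5)), c(0.5, 0.5))
  # lower dG never yields lower population
  expect_true(all(diff(p[order(dG)]) <= 0))
  expect_error(boltzmann_populations(numeric(0)), "non-empty")
  # shift stability at extreme magnitudes (would overflow naively)
  expect_equal(sum(boltzmann_populations(c(-5000, -4990))), 1)
})

test_that("low-coverage reference Gibbs energies give the published populations", {
  p <- boltzmann_populations(c(-13.3, 8.6, -9.6, -21.3, -19.3), T = 298.15)
  expect_equal(round_half_up(p, 2), c(0.03, 0.00, 0.01, 0.67, 0.30))
})

test_that("high-coverage reference Gibbs energies give the published populations", {
  p <- boltzmann_populations(c(-1.7, -6.3, -17.9, 7.2, -12.0, 2.3, -1.5),
                             T = 298.15)
  expect_equal(round_half_up(p, 2), c(0.00, 0.01, 0.91, 0.00, 0.08, 0.00, 0.00))
})

test_that("ensembles reject mixed coverage and order mode sets by name", {
  en <- data.frame(name = c("A", "B"), coverage = c("LC", "HC"),
                   topology = "monomer", dE_c = -50, dE_disp = -20,
                   dH_c = -45, dG_c = c(-10, -12))
  expect_error(adduct_ensemble(en), "mixed coverage")
})

test_that("single-mode spectra realize the FWHM definition", {
  ms <- mode_set(1700, intensities = 10, scaled_frequencies = 1700)
  params <- synthesis_params(fwhm = 20, grid = c(1600, 1800, 0.5))
  sp <- adduct_spectrum(ms, params)
  i_max <- which.max(sp$absorbance)
  expect_equal(sp$wavenumbers[i_max], 1700)
  expect_equal(sp$absorbance[i_max], 10, tolerance = 1e-9)   # height convention
  # half-maximum crossings at 1690 / 1710 within a grid step
  half <- sp$absorbance >= 5
  expect_equal(sp$wavenumbers[range(which(half))], c(1690, 1710),
               tolerance = 0.5)
  # area convention integrates to the intensity
  spa <- adduct_spectrum(ms, synthesis_params(20, c(1500, 1900, 0.5), "area"))
  area <- sum(spa$absorbance) * 0.5
  expect_equal(area, 10, tolerance = 1e-6)
})

test_that("overlapping-mode spectra equal the direct Gaussian evaluation", {
  ms <- mode_set(c(1695, 1710), intensities = c(7, 7),
                 scaled_frequencies = c(1695, 1710))
  sp <- adduct_spectrum(ms, synthesis_params(20, c(1600, 1800, 0.5)))
  w <- sp$wavenumbers
  direct <- gaussian_trace(w, 1695, 7) + gaussian_trace(w, 1710, 7)
  expect_equal(sp$absorbance, direct, tolerance = 1e-12)
  # two equal modes 15 apart with FWHM 20 merge into a single maximum
  expect_equal(sum(diff(sign(diff(sp$absorbance))) == -2), 1)
})

test_that("degenerate spectrum-synthesis inputs behave", {
  ms_empty <- mode_set(numeric(0), intensities = numeric(0),
                       scaled_frequencies = numeric(0))
  sp <- adduct_spectrum(ms_empty, synthesis_params())
  expect_true(all(sp$absorbance == 0))
  ms_out <- mode_set(900, intensities = 5, scaled_frequencies = 900)
  expect_warning(adduct_spectrum(ms_out, synthesis_params(20, c(1500, 1800, 0.5))),
                 "zero spectrum")
})

test_that("ensemble spectra are population-linear and conserve area", {
  mk <- function(nu) mode_set(nu, intensities = 100, scaled_frequencies = nu)
  en <- data.frame(name = c("a", "b", "c"), coverage = "LC",
                   topology = "monomer", dE_c = NA, dE_disp = NA, dH_c = NA,
                   dG_c = c(-20, -18, -15))
  e <- adduct_ensemble(en, list(mk(1650), mk(1690), mk(1730)))
  params <- synthesis_params(20, c(1500, 1900, 0.5), "area")
  sp <- ensemble_spectrum(e, params)
  # total integrated area equals sum_i p_i * (sum of intensities)
  expect_equal(sum(sp$absorbance) * 0.5, sum(e$populations * 100),
               tolerance = 1e-6)
  # single-member ensemble equals its adduct spectrum
  e1 <- adduct_ensemble(en[1, ], list(mk(1650)))
  expect_equal(ensemble_spectrum(e1, params)$absorbance,
               adduct_spectrum(mk(1650), params)$absorbance, tolerance = 1e-12)
  # populations (1, 0): second member does not contribute
  en2 <- en[1:2, ]; en2$dG_c <- c(-200, 0)
  e2 <- adduct_ensemble(en2, list(mk(1650), mk(1730)))
  expect_equal(ensemble_spectrum(e2, params)$absorbance,
               adduct_spectrum(mk(1650), params)$absorbance, tolerance = 1e-10)
  # a member above the population threshold must carry modes
  e3 <- adduct_ensemble(en, list(mk(1650), NULL, mk(1730)))
  expect_error(ensemble_spectrum(e3, params), "no mode set")
})

test_that("normalization to a reference maximum is exact and idempotent", {
  w <- seq(1600, 1800, 0.5)
  sim <- spectrum_ir(w, gaussian_trace(w, 1700, 2), kind = "simulated")
  exp_sp <- spectrum_ir(w, gaussian_trace(w, 1695, 0.5), kind = "experimental")
  ns <- normalize_to_reference(sim, exp_sp, c(1650, 1750))
  expect_equal(max(ns$absorbance), 0.5, tolerance = 1e-12)
  expect_equal(ns$absorbance, sim$absorbance * 0.25, tolerance = 1e-12)
  # idempotent
  ns2 <- normalize_to_reference(ns, exp_sp, c(1650, 1750))
  expect_equal(ns2$absorbance, ns$absorbance, tolerance = 1e-12)
  # zero simulated maximum cannot be normalized
  zero <- spectrum_ir(w, rep(0, length(w)), kind = "simulated")
  expect_error(normalize_to_reference(zero, exp_sp), "cannot normalize")
})

test_that("baseline subtraction flattens a ramp and finds no spurious peaks", {
  w <- seq(1600, 1800, 0.5)
  sp <- spectrum_ir(w, 0.01 * (w - 1600) + 0.3, kind = "experimental")
  bp <- baseline_and_peaks(sp, c(1640, 1770))
  expect_lt(max(abs(bp$corrected$absorbance)), 1e-10)
  expect_length(bp$maxima, 0)
  expect_length(bp$shoulders, 0)
  expect_error(baseline_and_peaks(sp, c(1700, 1701)), "5 grid points")
})

test_that("an overlapped weak component reads as maximum plus shoulder", {
  w <- seq(1600, 1800, 0.5)
  y <- gaussian_trace(w, 1695, 1) + gaussian_trace(w, 1710, 0.5) +
    0.001 * (w - 1600) + 0.02
  bp <- baseline_and_peaks(spectrum_ir(w, y, kind = "experimental"),
                           c(1640, 1770))
  expect_length(bp$maxima, 1)
  expect_lt(abs(bp$maxima - 1695), 2.1)
  expect_true(any(abs(bp$shoulders - 1710) <= 2))
  # a single Gaussian: one maximum at its center, no shoulder
  bp1 <- baseline_and_peaks(spectrum_ir(w, gaussian_trace(w, 1700, 1)),
                            c(1640, 1770))
  expect_equal(bp1$maxima, 1700, tolerance = 0.5)
  expect_length(bp1$shoulders, 0)
})
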