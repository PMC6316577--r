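Package: adsorbIR
Title: Adsorption Thermochemistry and Ensemble IR Spectra of Surface Adducts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to interpret infrared spectra of molecules adsorbed on
    oxide surfaces from harmonic calculations on competing surface adducts:
    partial (reduced) Hessian vibrational analysis with IR intensities and
    mode-class frequency scaling, rigid-rotor harmonic-oscillator
    thermochemistry with counterpoise correction, Grimme D2 pairwise
    dispersion for molecular and 2D-periodic systems, Boltzmann populations
    of adduct ensembles, and population-weighted Gaussian-broadened spectrum
    synthesis with baseline subtraction and peak/shoulder picking for
    comparison with experimental traces. Includes synthetic-data generators
    so the full pipeline runs with no external electronic-structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
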