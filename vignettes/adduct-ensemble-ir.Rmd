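---
title: "From adduct energetics to ensemble IR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From adduct energetics to ensemble IR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsorbIR)
```

## The problem this package addresses

When a small molecule adsorbs on a heterogeneous oxide surface, the measured
infrared spectrum is rarely the spectrum of a single binding geometry. A
silica surface exposing hydroxyl (silanol) groups offers several docking
sites and orientations, each an *adduct* with its own interaction energy and
its own slightly shifted vibrational bands. The observable spectrum is the
thermal average over these adducts. Interpreting it therefore needs four
ingredients, which are exactly the four computational stages of this
package:

1. **Per-adduct harmonic vibrations** of the adsorbate and the surface
   hydroxyls it binds to, from a partial (reduced) Hessian.
2. **Interaction thermochemistry** — counterpoise-corrected interaction
   energies, harmonic enthalpies and Gibbs energies, with the pairwise
   dispersion contribution separated out.
3. **Boltzmann populations** of the competing adducts from their Gibbs
   energies.
4. **Spectrum synthesis**: population-weighted sums of Gaussian bands,
   normalized against and compared to an experimental trace.

The worked system shipped with the package is formamide (HCONH₂) on a
low-hydroxylation amorphous silica slab: the carbonyl stretch sits at
1754 cm⁻¹ in the gas phase and red-shifts to roughly 1690–1710 cm⁻¹ when
the C=O accepts a hydrogen bond from a silanol, while the NH₂ bend stays
near 1600 cm⁻¹. Two coverage regimes are distinguished throughout — LC
(one molecule per surface cell) and HC (two molecules, as two separate
monomers or as an adsorbed dimer) — and they are always treated as separate
ensembles, because their members compete for different adsorption states.

## Partial-Hessian vibrational analysis

The vibrational stage diagonalizes the mass-weighted matrix
$M^{-1/2} H M^{-1/2}$, where $H$ is the Cartesian second-derivative block of
a chosen *fragment* (the adsorbate plus the silanol groups). Environment
atoms are removed by **deleting their rows and columns**, not by projecting:
this is the fixed-environment convention of partial Hessian vibrational
analysis, matching a slab model whose far side is frozen. Consequently no
translational/rotational projection is applied — all $3N$ fragment degrees
of freedom are genuine vibrations against the fixed surroundings, and
free-molecule zero modes arise only in deliberately uncoupled test systems.

Units: Hessians are exchanged in kJ mol⁻¹ Å⁻², masses in amu, and
eigenvalues are converted to wavenumbers by
$\tilde\nu = \sqrt{\lambda}/(2\pi c)$. Negative eigenvalues (imaginary
modes) are encoded as negative wavenumbers; they are excluded from
thermochemistry with a warning rather than silently dropped, the
least-surprising convention when a fragment geometry is not a strict
minimum.

IR intensities follow the double-harmonic expression
$I_i \propto |\partial\mu/\partial Q_i|^2$, with a single conversion
constant, 42.2561 km mol⁻¹ per (D Å⁻¹ amu⁻¹ᐟ²)², fixed in the package's
constants table and verified in the test suite against a dimensional
analysis from SI constants ($N_A\pi/3c^2$ with the Debye and amu unpacked).

**Frequency scaling.** Harmonic frequencies carry systematic errors that
differ by mode type. The package applies mode-class scaling: the carbonyl
stretch class uses factor 0.9972 and the NH₂ bend class 1.0102, each the
experimental/calculated ratio for the free molecule. Because the assignment
is by mode type while the implementation needs a selection rule, classes
are realized as wavenumber windows — CO stretch (1600, 1800) cm⁻¹, NH₂
bend (1500, 1600) cm⁻¹, half-open at the shared boundary so touching
windows stay unambiguous, and overridable in the run configuration.
Overlapping windows are rejected rather than resolved by precedence.

## Thermochemistry

Adsorbed species get **vibration-only** state functions: a bound, immobile
adsorbate has no meaningful translational or rotational partition function
in the fixed-environment scheme, and no PV term ($H = U$). Gas-phase
species (the free molecule and its dimer, the reference states of the
adsorption reactions) use the full RRHO treatment: Sackur–Tetrode
translation, classical rigid rotor with symmetry number, harmonic
vibrations, and $H = U + RT$. Reaction quantities are plain bookkeeping,
$\Delta X = X_{products} - X_{reactants}$ for $X = E, H, G$, so bound
adducts come out negative; the test suite checks that the stepwise
first-plus-second adsorption deltas compose to the direct two-molecule
delta (path independence), which is also why stepwise and direct Gibbs
energies give the same Boltzmann populations.

The counterpoise correction is
$\Delta E^{CP} = E_{AB} - E_A^{ghost} - E_B^{ghost} + (E_A^{own} -
E_A^{relaxed}) + (E_B^{own} - E_B^{relaxed})$. The deformation terms in
parentheses are **included by default** with a switch to disable — both
conventions circulate, and the ledger type makes the choice explicit
instead of burying it. A ghost-basis fragment energy above its own-basis
energy violates the variational bound and is rejected as a data error.

Physical constants are CODATA (R = 8.314462618 J mol⁻¹ K⁻¹) and live in
one exported table, `phys_const`, so that population roundings are
reproducible to the last digit.

## D2 dispersion

The pairwise dispersion energy is
$E = -s_6\, C_6^{ij} r^{-6} f_{dmp}(r)$ with
$f_{dmp}(r) = (1 + e^{-d(r/R_r-1)})^{-1}$, $C_6^{ij} = \sqrt{C_6^i C_6^j}$
and $R_r$ the **sum** of the two elemental van der Waals radii. The
published coefficient set for H, C, N, O, Si with the PBE $s_6 = 0.75$ and
$d = 20$ ships as a versioned JSON file; tests use synthetic parameters so
they exercise the functional form, not the data file. For 2D-periodic
slabs the sum runs over lattice translations inside a real-space cutoff
(default 30 Å); the $r^{-6}$ tail makes the truncation error decay as
cutoff⁻⁴, and a convergence check belongs to the test suite rather than to
run time.

The decomposition $\Delta E_{disp} = E_{disp}(AB) - E_{disp}(A) -
E_{disp}(B)$ at the frozen complex geometry is computed **twice** — by that
subtraction and as the direct inter-fragment pair sum — and the two routes
are asserted equal on every call. This dual route costs little and catches
fragment/complex bookkeeping errors (missing atoms, duplicated atoms,
inconsistent cells) that a single route would silently absorb.

Note the scope boundary: the reference interaction energies shipped with
the package (below) are electronic-structure results that **cannot** be
re-derived here — the optimized geometries were never deposited. The
dispersion module computes dispersion for structures you supply; for the
reference adducts, $\Delta E_{disp}$ is ingestion data.

## Populations and spectrum synthesis

Populations are $p_i = e^{-\Delta G_i/RT}/\sum_j e^{-\Delta G_j/RT}$,
computed after subtracting the minimum $\Delta G$ (shift invariance makes
this exact, not approximate, and avoids overflow). Printed population
tables round **half-up** to two decimals; base R's `round()` rounds half
to even, so the package exports `round_half_up()` and uses it for all
table comparisons — the difference is visible for borderline populations
like 0.006.

Per-adduct spectra are sums of Gaussians at the scaled mode frequencies
with a common FWHM, default 20 cm⁻¹ — a band-shape convention, not a
physical linewidth. The default amplitude convention is **height** (peak
height equals mode intensity), because band synthesis from "maximum
position and intensity" most naturally maps intensity to height; the
**area** convention (each Gaussian integrates to the intensity) is
available, and conservation tests use it since total integrated intensity
is then exactly $\sum_i p_i \sum_k I_{ik}$. The default grid is 1500–1800
cm⁻¹ in 0.5 cm⁻¹ steps, covering the carbonyl-stretch and NH₂-bend
region at well below the 2 cm⁻¹ resolution of a typical FTIR experiment.
Ensemble members with populations below 0.005 may omit their mode sets
(nil components); a member above that threshold without modes is an error,
not a silent gap.

Simulated spectra are normalized so their maximum inside a chosen window
equals the experimental maximum there — a display convention that makes
band positions, not absolute intensities, the object of comparison.

**Peak and shoulder reading.** Experimental traces get a linear baseline
through the window endpoints. Maxima are local maxima of a cubic
Savitzky–Golay-smoothed trace above a prominence fraction (default 5%) of
the tallest signal. Shoulders are found on the smoothed second derivative:
an unresolved component pulls the curvature down locally even when the
trace has no separate maximum. Because such a dip rides on the flank of
the main band's much deeper curvature well, a symmetric depth test fails
to see it; instead each candidate dip must have *persistence* — the
second derivative must rise by a threshold on both sides before a deeper
minimum occurs — and must lie farther than an exclusion radius (5 cm⁻¹)
from any located maximum. The derivative uses a narrower filter window
than the smoothing (half of it), since a 20 cm⁻¹-FWHM shoulder 15 cm⁻¹
from a strong band does not survive a 12 cm⁻¹ derivative window. These
defaults were set on noiseless constructed traces with known centers and
are kept fixed across the test suite.

## The synthetic-data generator

No vibrational output of the underlying electronic-structure study was
deposited, so the pipeline's upstream inputs are emulated by generators
whose ground truth is known by construction:

- `make_fragment()` builds a mass-weighted Hessian $L\Lambda L^T$ from
  prescribed wavenumbers and a seeded random orthonormal $L$ (QR with sign
  fixing), un-mass-weights it, and constructs Cartesian dipole derivatives
  whose per-mode projections reproduce prescribed intensities exactly. The
  default prescription places modes at 250–1754 cm⁻¹ with a dominant
  400 km mol⁻¹ carbonyl stretch.
- `make_adduct_ensemble()` emulates the two coverage regimes: five LC and
  seven HC adducts (three double monomers, four dimers) carrying the
  reference Gibbs energies, each with a carbonyl mode red-shifted from
  1754 cm⁻¹ by a uniform draw of 44–64 cm⁻¹ (landing in the observed
  1690–1710 cm⁻¹ H-bonded window) and an NH₂ mode at 1600 ± 5 cm⁻¹.
- `make_experimental_spectrum()` adds a linear baseline (offset 0.02,
  slope 10⁻⁴ per cm⁻¹ relative to unit peak height) and Gaussian noise
  (σ = 1% of the maximum), emulating a well-measured transmission FTIR
  trace after atmospheric correction.

All draws flow from one integer seed; the generators save and restore the
global RNG state so they never perturb a caller's random stream. What the
synthetic data does **not** emulate: anharmonicity, mode mixing between
adsorbate and framework, coverage-dependent band shifts, detector
nonlinearity, and baseline curvature. Passing the closure tests therefore
demonstrates that the analysis chain is self-consistent and
numerically correct — not that the harmonic/Gaussian model is adequate
for any particular real surface.

## What is reproduced, and at what problem size

Running `scripts/acceptance.R` recomputes, from the packaged reference
energy ledgers (five LC and seven HC adducts), the Boltzmann populations
at 298.15 K. These close exactly on the reference values (LC: 0.03, 0.00,
0.01, 0.67, 0.30; HC: 0.00, 0.01, 0.91, 0.00, 0.08, 0.00, 0.00; the two
most stable LC adducts jointly 0.97). The test suite's property checks run
on deliberately small systems — 2–3-atom fragments (6–9 modes), 3–6-atom
dispersion clusters, single-atom periodic cells, 401–801-point spectral
grids — chosen so each oracle (closed form, brute-force pair sum,
construction certificate) is itself beyond doubt; the full suite runs in a
few seconds.

Not reproducible at this level, and deliberately treated as ingestion
data: the reference $\Delta E^c/\Delta H^c/\Delta G^c$ values themselves,
the −18 kJ mol⁻¹ gas-phase dimerization Gibbs energy, and the absolute
positions of the simulated high-coverage band — all of these depend on
periodic DFT calculations on undeposited geometries.

## Worked example

```{r example}
lc_csv <- system.file("extdata", "adducts_low_coverage.csv",
                      package = "adsorbIR")
report <- run_pipeline(run_config(coverage = "LC"), energy_table = lc_csv)
report$populations
```

```{r example-synth}
spec <- synthetic_spec(seed = 7)
fr <- make_fragment(spec)
ms <- apply_scaling(ir_intensities(fr$fh, normal_modes(fr$fh)))
as.data.frame(ms)
```

## Known limitations

- Harmonic, double-harmonic (intensities), and Gaussian band-shape
  approximations throughout; two scalar scale factors are the only
  anharmonic information.
- The fixed-environment fragment scheme has no way to describe adsorbate
  translational entropy; weakly bound, mobile adsorbates will have their
  Gibbs energies of adsorption overestimated in magnitude.
- Shoulder detection is a heuristic on the second derivative; heavily
  smoothed or very noisy traces can hide genuine shoulders or flag
  spurious ones, and the persistence threshold trades one risk against
  the other.
- The JCAMP-DX reader covers the plain AFFN XYDATA/XYPOINTS forms it
  writes; compressed (DIF/DUP) encodings are out of scope.
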