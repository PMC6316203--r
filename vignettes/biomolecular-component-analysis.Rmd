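---
title: "Biomolecular component analysis of single-organelle Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomolecular component analysis of single-organelle Raman spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanbca)
```

This vignette documents the science and the design choices behind
`ramanbca`: the mixing model and its assumptions, the calibration
convention, how background subtraction and quality control are defined,
how the lipid saturation ratio is measured, and what the bundled
synthetic generator does and does not emulate.

## The linear mixing model

A Raman spectrum measured at a single point inside a cell is, to good
approximation over the fingerprint region, a linear superposition of the
spectra of its molecular constituents. After the non-cellular signal is
removed, we model the background-free spectrum as

$$S(\nu) \;\approx\; \sum_{i} w_i \, C_i(\nu), \qquad w_i \ge 0,$$

over five component classes: proteins, DNA, RNA, lipids, and glycogen.
The weights are estimated by nonnegative least squares (NNLS). The
nonnegativity constraint is physical — negative concentrations are
meaningless — and materially changes the estimator near zero
(see *Detection limits* below).

Assumptions worth stating explicitly:

* **Linearity in concentration.** Valid for spontaneous Raman scattering
  at constant excitation and collection geometry; self-absorption and
  optical-trapping effects are ignored.
* **Fixed band shapes.** Each class is represented by one profile per
  measurement context. Real spectra vary continuously (most visibly the
  lipid 1665 cm⁻¹ C=C band with unsaturation); the pipeline handles this
  by extracting the *sample's* lipid spectrum rather than trusting the
  library's shape (below).
* **No wavenumber alignment.** The solver is linear in the weights only;
  calibration drift of the axis must be corrected upstream. The peak
  reader tolerates a few cm⁻¹ of drift via its ±15 cm⁻¹ search window.

## Calibration: weights are concentrations

Each stored profile is normalized so that *unit fit weight corresponds
exactly to its calibration concentration*: 100 mg/mL for protein, 20
mg/mL for the other classes (the concentrations of the aqueous standards
used to calibrate the instrument response). Concentrations are then
`c_i = w_i × calibration_i`, a single multiplication. Because the model
is linear, this convention is preserved under `calibrate_profile()`
(rescaling a measured standard spectrum) and is testable: fitting a pure
scaled profile `k·C_i` must return `k × calibration_i` exactly, which the
test suite asserts for `k ∈ {0.1, 0.5, 1, 2}`.

## Background subtraction

Spectra acquired on glass-bottom dishes carry substrate (glass), medium
(water), optional stain, and broadband fluorescence contributions that
dwarf weak cellular bands. We fit one joint constrained least-squares
problem whose design matrix stacks

1. the normalized background basis spectra (nonnegative coefficients),
2. a Chebyshev polynomial basis up to order 5 (sign-free coefficients —
   fluorescence decay can need signed terms), and
3. the five biomolecular profiles (nonnegative).

Only (1) + (2) constitute the returned background. Fitting everything
jointly is the standard defence against *band-stealing*: fitted
separately, a flexible baseline absorbs parts of broad real bands. The
suite checks this directly (weights of a synthetic background + mixture
spectrum recovered within 2%), along with annihilation of pure-background
spectra and idempotence of subtraction. Chebyshev polynomials are used
instead of raw monomials purely for numerical conditioning; sign-free
columns are implemented inside the NNLS solver by splitting each free
column into a ±pair.

## Quality control

The quality gate compares residual intensities over the significant
range (600–1800 cm⁻¹, covering every diagnostic band while avoiding the
noisy grid edges) with the instrument's reproducibility band of ±3
counts per second; a fit whose residual exceeds it is rejected but keeps
all of its numbers.

One design decision needs justification. The strictest reading of the
rule — the raw maximum of |residual| — interacts badly with pointwise
noise: the maximum of ~1200 independent Gaussian samples of SD 1 cps
exceeds 3 cps with high probability, so *every* correct fit at realistic
noise would be rejected. We therefore evaluate the metric on a lightly
Savitzky–Golay-smoothed residual (window 11, order 3; `smooth_window = 1`
disables). Smoothing suppresses single-pixel noise extremes while
leaving band-shaped systematic model errors — the signature of a wrong
profile variant — essentially intact; the suite demonstrates both sides
(correct models pass at noise SD 1 cps; a wrong protein variant fails
the gate by an order of magnitude). A mean-absolute metric is available
via `qc_policy(metric = "mean_abs")`.

## The organellar lipid spectrum and the saturation ratio

Subtracting the weighted protein, DNA, RNA, and glycogen profiles from
the background-free spectrum leaves `w_lipid · C_lipid + residual` — the
sample's actual lipid spectrum, retaining its true band shape rather
than the library's. The 1665/1440 cm⁻¹ peak-intensity ratio measured on
it tracks phospholipid unsaturation (0.58 for monounsaturated oleic
acid). Measuring on the extracted spectrum, not the raw one, keeps the
protein CH₂/amide-I contributions at 1440–1665 cm⁻¹ out of the ratio.

The peak reader takes the maximum over a ±15 cm⁻¹ window of the value
above a local linear baseline — the chord joining the medians of the
outermost 4 cm⁻¹ of points on each side (five points per side on the
default 1 cm⁻¹ grid). Defining the edge regions in wavenumber rather
than in points keeps the estimator consistent across sampling steps.
Two further choices control estimator bias:

* The ratio is computed after Savitzky–Golay smoothing of the lipid
  spectrum: a max-picking estimator on raw noise is biased upward by
  noise extremes, and the bias does not cancel between a strong 1440 and
  a weaker 1665 band.
* In the bundled synthetic library the 1440 and 1665 bands share one
  width, so the fraction of band height removed by the chord baseline is
  identical for both and cancels exactly in the ratio.

When the 1440 peak does not clear the noise floor (3× the residual SD by
default) the ratio is reported missing — the behaviour expected for
sparse-lipid fixed nuclei.

## Profile variants and the reference library

`resolve_profiles()` maps a measurement context (organelle × fixation
state) to exactly five profiles:

* **RNA** — cytoplasmic variant (stronger 815 cm⁻¹ O–P–O symmetric
  stretch) for mitochondrion, ER, Golgi, and mitotic cytoplasm; nuclear
  variant for nucleus, nucleolus, and mitotic chromosome.
* **Protein** — an ethanol-fixed variant when applicable (ethanol
  visibly reshapes protein spectra), otherwise a compartment variant
  (cytoplasmic proteins carry the 717 cm⁻¹ peak), falling back to the
  generic profile with a warning so the pipeline remains usable before
  all context variants exist.
* **Lipid** — a per-context variant whose 1665/1440 ratio equals the
  context's mean, when one exists, else generic. This emulates a library
  matured by feedback refinement: with a single global lipid profile,
  contexts whose typical saturation differs strongly from it would see
  systematic 1665 cm⁻¹ model error, biasing the protein estimate (whose
  amide I band overlaps) and inflating QC rejections.
* **DNA, glycogen** — generic.

Ethanol fixation of ER or Golgi is flagged unsupported (no such
measurements exist); the CLI refuses the combination unless forced.

The bundled profiles are analytic pseudo-Voigt band models — synthetic
stand-ins built from standard cellular Raman assignments, not measured
standards — and every profile records its provenance. Libraries persist
as per-profile CSV spectra plus a `manifest.csv`.

### Feedback refinement

`refine_profile_feedback()` implements the library-maturation step: each
accepted fit yields a per-spectrum estimate of one class's profile,
`(S − Σ_{j≠i} w_j C_j) / w_i`; estimates are averaged pointwise, negative
excursions clipped, and the result rescaled to best reproduce the
average at unit weight. Simple pointwise averaging was chosen over
weighted schemes for transparency; fits with class weight below 0.05 are
excluded to avoid division blow-up. The procedure is exactly
fixed-point on noise-free fits generated from the library — the testable
core of an otherwise loosely specified iterative practice — and
averaging provably beats any single noisy estimate, which the suite
verifies by Monte Carlo.

## The synthetic generator

`simulate_spectrum()` is the package's test and validation substrate.
Per draw it samples component concentrations from zero-truncated normal
distributions (`max(N(μ, σ), 0)`), samples a lipid saturation ratio and
rebuilds the lipid component's 1665 band to match, and composes

```
raw = Σ wᵢ Cᵢ + background_scale × (glass + 0.45·medium + 0.08·stain) + ε,
```

with `ε ~ N(0, noise_sd²)` i.i.d. per grid point. Identical
`(preset, seed)` pairs replay bit-identically.

Study conditions (the preset table, `inst/extdata/organelle_presets.csv`):

* Concentration means and SDs for protein, DNA, RNA, and lipid per
  organelle and fixation state mirror measured per-organelle tables;
  saturation-ratio cells that were unmeasurable are `NA` (the generator
  then uses the library lipid unchanged, and the pipeline reports the
  ratio missing at these lipid levels).
* **Glycogen** is not tabulated in those data; presets use a trace
  2.0 ± 1.5 mg/mL everywhere — a realistic background level for cells
  that are not glycogen-storing — chosen once.
* **Noise** defaults to 1 cps, placing the ±3 cps QC gate at 3σ.
  Gaussian additive noise (constant SD in cps) is used because the
  instrument error is quantified in cps; detector shot noise is not
  separately modelled.
* **Background scale** defaults to 120 cps, set so that a simulated
  homogeneous 100 mg/mL protein medium has a median raw intensity near
  100 cps over the significant range — the regime in which a 3 cps
  noise SD reproduces the observed ≈3% relative spectral SD.
* **Truncation at zero** is the minimal physical fix for cells whose SD
  exceeds the mean (e.g. nuclear lipids); it shifts the realized mean of
  such cells upward, which is why recovery tests compare against the
  generated ground-truth means, not the nominal table means.

Two subtleties in the lipid draw. First, the per-draw lipid profile is
rescaled so that its projection onto the library lipid component equals
unit weight per 20 mg/mL: the ground-truth concentration is defined
*operationally* (what a calibrated instrument reports for that
material), so shape variation flows into the extracted lipid spectrum
and the measured ratio rather than appearing as a spurious concentration
bias. Second, the drawn ratio is applied as a band-height ratio; because
the two diagnostic bands share one width, the measured peak-height ratio
matches it to within the estimator's tolerance.

What the generator deliberately does **not** emulate: cosmic-ray spikes,
detector etaloning, focus drift and cell movement, wavenumber
calibration drift, shot-noise scaling with intensity, and between-class
covariance of concentrations (components are drawn independently).
Passing the simulation-based tests therefore demonstrates correctness of
the decomposition machinery under the stated noise model — not
robustness to every artefact of real acquisitions.

## Detection limits and recovery testing

NNLS clips negative estimates to zero, so for a component whose true
concentration is near zero the fitted value has a positive floor of
order `0.4 × σ_c`, where `σ_c` is the noise-induced concentration SD.
The acceptance suite therefore computes a per-component detection limit
as 3× the SD of blank (background-only) fits, and for preset cells whose
nominal mean lies below it requires agreement within the detection limit
instead of the 2-standard-error criterion used everywhere else — a mean
below detection is not recoverable to 2 SE by construction.

Problem sizes used by the test and acceptance suites: the unit suite
runs on a 400–1900 cm⁻¹ grid at 2 cm⁻¹; whole-pipeline validation uses
the full 50–1900 cm⁻¹ instrument grid at 1 cm⁻¹ with 200 simulated
spectra per organelle preset and 100-instance solver cross-checks
against an independent NNLS implementation.

## Numerical choices

* **Grid**: 50–1900 cm⁻¹ at 1 cm⁻¹ — twice-oversampled relative to the
  2 cm⁻¹ FWHM optical resolution. The native sampling step of the
  instrument class is not standardized; 1 cm⁻¹ is this package's choice.
* **Interpolation**: linear, since band shapes are broad relative to the
  step and splines risk ringing near sharp artefacts; grid points
  outside a spectrum's support are zero-filled and flagged rather than
  erroring, because library and sample ranges rarely match exactly.
* **NNLS**: Lawson–Hanson active set, QR solves on the passive set, dual
  tolerance scaled to the design; solutions satisfy the KKT conditions
  to 1e-8 of the design scale and match an independent solver to 1e-6.
* **Collinearity guards**: the component design must have condition
  number below 1e8 (normalized columns); duplicate background components
  are rejected.
* **Degenerate inputs**: an all-zero spectrum yields a valid all-zero
  fit; fits retain their numbers when rejected; aggregation marks SD
  unavailable for groups with fewer than two accepted fits.
* **Ties**: `which.max` takes the first grid point on exact peak ties.

## Known limitations

* The mixing model is linear in the weights; any nonlinearity of the
  original instrument chain (e.g. axis shift/stretch refinement during
  fitting) is out of scope here.
* No water/solvent displacement correction is applied to the reported
  concentrations.
* Five fixed classes: other Raman-active species (carotenoids,
  cytochromes) will be expressed through the residual and can trip QC —
  by design, but worth knowing.
* The bundled library is synthetic; quantitative work on real spectra
  requires profiles calibrated on the actual instrument
  (`calibrate_profile()`, `refine_profile_feedback()`).
* Single spectra only; no imaging/mapping support.
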