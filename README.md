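# ramanbca

Quantitative **biomolecular component analysis (BCA)** of single-organelle
Raman microspectra. Confocal Raman spectra measured inside living or fixed
cells on glass-bottom dishes are decomposed into the contributions of the
five major biomolecular classes — proteins, DNA, RNA, lipids, and glycogen
— and, because the reference profiles are concentration-calibrated, the
result is reported in absolute units (mg/mL). The package is aimed at
cell biologists and spectroscopists who want per-organelle concentration
tables and lipid-saturation readouts from raw single-point Raman spectra.

## The model

A background-free cellular spectrum is modelled as a linear sum of
calibrated component profiles,

```
S(ν) ≈ Σᵢ wᵢ Cᵢ(ν),   wᵢ ≥ 0,   i ∈ {protein, DNA, RNA, lipid, glycogen}
```

with the weights estimated by nonnegative least squares (a Lawson–Hanson
active-set solver written for this package). Each stored profile is scaled
so that unit weight corresponds to its calibration concentration — 100
mg/mL for proteins, 20 mg/mL for the other classes — so concentrations are
simply `cᵢ = wᵢ × calibrationᵢ`.

Around that core the pipeline provides:

* **Automatic background subtraction** — glass, medium, and stain basis
  spectra plus a Chebyshev baseline are fitted *jointly* with the five
  biomolecular profiles in one constrained least-squares problem, so the
  baseline cannot absorb real bands; only the background part is
  subtracted.
* **Residual-based quality control** — a fit is rejected when the
  (lightly smoothed) residual exceeds the instrument's ±3 cps
  reproducibility band anywhere in the significant range
  (600–1800 cm⁻¹).
* **Organellar lipid spectrum and saturation ratio** — subtracting the
  four non-lipid weighted profiles leaves the sample's own lipid
  spectrum, from which the 1665/1440 cm⁻¹ peak-intensity ratio is read as
  a proxy for phospholipid unsaturation (0.58 for monounsaturated oleic
  acid).
* **Context-aware profile variants** — nuclear vs cytoplasmic RNA
  (815 cm⁻¹ O–P–O band), compartment- and fixation-specific protein
  profiles, per-context lipid ratios.
* **A synthetic-spectrum generator** with per-organelle concentration
  presets (mean ± SD), used throughout the test suite: every simulated
  spectrum carries its ground truth.

File I/O covers two-column CSV and JCAMP-DX spectra; results come back as
tibbles (`tidy()`, `glance()`, `aggregate_fits()`) and ggplot2 figures
(`autoplot()`).

## Worked example

Simulate one endoplasmic-reticulum spectrum, run the full pipeline, and
inspect the result:

```r
library(ramanbca)

lib <- default_library()
bg  <- default_background(lib$grid)
ctx <- measurement_context("er", "live")

sim      <- simulate_spectrum(get_preset("er_live"), lib, bg, seed = 42)
profiles <- resolve_profiles(lib, ctx)
bg_free  <- subtract_background(sim$spectrum, bg, profiles)
fit      <- fit_bca(bg_free, profiles, context = ctx)

fit
#> <bca_fit: protein 104.8, dna 0.1, rna 10.3, lipid 26.7, glycogen 2.6 mg/mL;
#>  qc pass (1.51 cps); 1665/1440 0.48>

tidy(fit)
#> # A tibble: 5 × 5
#>   component variant      weight calibration concentration
#>   <chr>     <chr>         <dbl>       <dbl>         <dbl>
#> 1 protein   cytoplasmic 1.05            100      105.
#> 2 dna       generic     0.00272          20        0.0543
#> 3 rna       cytoplasmic 0.516            20       10.3
#> 4 lipid     er_live     1.34             20       26.7
#> 5 glycogen  generic     0.129            20        2.58
```

The fitted concentrations sit within the instrument noise of this draw's
ground truth (protein 104.5, RNA 10.3, lipid 27.2 mg/mL; saturation ratio
0.534), the residual stays inside the ±3 cps gate (`qc_pass = TRUE`), and
the 1665/1440 ratio is read off the extracted lipid spectrum.
`aggregate_fits()` turns a batch of such fits into the per-organelle
mean ± SD table, and `autoplot(fit)` shows the spectrum, model, and
residual with the QC band.

A command-line interface wrapping the same functions ships at
`inst/cli/ramanbca` (`fit`, `simulate`, `report`, `calibrate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ramanbca", package = "ramanbca"))')" \
    simulate --preset nucleolus_live --n 5 --seed 1 --out sims
```

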