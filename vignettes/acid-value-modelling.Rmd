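---
title: "Predicting oil acid value from hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oil acid value from hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleospec)
```

## The problem

Acid value (AV, mg KOH per g oil) measures the free fatty acid content of
an edible oil and is the standard indicator of hydrolytic rancidity. The
reference determination is a titration, `AV = 56.1 C V / m` (56.1 g/mol is
the molar mass of KOH; `C` the titrant molarity in mol/L, `V` its consumed
volume in mL, `m` the oil mass in g). Titration is accurate but slow,
destructive and reagent-hungry. Near-infrared hyperspectral imaging offers
a non-contact alternative: an NIR cube of an oil-filled dish carries both
a reflectance spectrum (chemistry) and an image at every band (physical
texture of the oil film), and a calibration model can map these to AV.

`oleospec` implements the full calibration workflow in three tiers of
increasing refinement:

1. **Full wavelengths** — PCR and PLSR on all 512 bands (870–1720 nm),
   under a panel of spectral pretreatments;
2. **Characteristic wavelengths** — the same models on a handful of bands
   chosen by SPA or CARS;
3. **Fused features** — selected spectral features concatenated with GLCM
   texture features extracted from the band images at the selected
   wavelengths.

Because no public oil-cohort dataset accompanies this problem, the package
ships a synthetic-scene generator that emulates a 153-sample study, so the
entire pipeline is testable end to end and every claim in this vignette is
recomputed by the test suite or the acceptance script.

## The synthetic cohort: what it emulates

`generate_cohort()` draws, per sample:

* an acid value from a Beta(2, 5) distribution rescaled to 0.32–1.59 mg/g.
  The right-skewed shape gives a cohort mean near 0.70 mg/g with a thin
  high-AV tail — the profile of a mostly fresh oil collection with a few
  aged samples.
* a reflectance spectrum built in absorbance space: a smooth rising
  baseline plus Gaussian bands at 1115 nm (C–H stretch), 1330 nm (C–H
  bend), 1520 nm (O–H bend) and 1590 nm. The 1330 and 1520 nm amplitudes
  grow linearly with AV, because those vibrations respond to free-fatty-acid
  chemistry; reflectance is `10^(-A)`, a bounded Beer–Lambert-style
  surrogate rather than a radiative-transfer claim. Local reflectance
  minima sit at all four band positions across the whole AV range.
* a nuisance structure chosen to reproduce the working regime of a bench
  NIR imaging study:
  * per-sample multiplicative jitter (sd 4.5%) on the AV-coupled
    amplitudes — chemistry is not perfectly collinear with AV, which caps
    what any spectral model can achieve;
  * additive offset, linear tilt and multiplicative gain in absorbance,
    plus mild reflectance-space scatter (gain sd 2%, stray-light offset
    sd 0.015) — the low-rank effects pretreatments remove;
  * seven interferent bands (other constituents: water, triglyceride
    overtones) at 920–1700 nm whose amplitudes *and centre positions* vary
    per sample (amplitude sd 0.05 absorbance, shift sd 8 nm). Shifted
    narrow bands are a high-rank, nonlinear variance source that
    full-spectrum models waste latent components on, while models on
    selected acid-sensitive bands never see them — this is precisely why
    characteristic-wavelength selection pays off in practice;
  * a per-sample smooth random baseline (sd 0.006 absorbance, 50 nm
    correlation length) and white band noise (sd 1e-4 reflectance).
* a dish scene: a disk-shaped oil region over a dark background, each oil
  pixel carrying the sample spectrum times a spatially correlated
  multiplicative texture field (relative sd 12%, mean exactly 1 over the
  disk). The field's correlation length shrinks with AV,
  `ell = 6 / (1 + 3.5 * texture_coupling * av)` pixels, emulating the finer
  surface micro-texture of more degraded oil films; `texture_coupling = 0`
  severs the texture–AV link entirely, which the tests use as a negative
  control. Cohort scenes are stored compactly (texture field, pixel-noise
  field, mask) and any band image is reconstructed on demand with
  `render_band()`; full 512-band cubes for single samples come from
  `generate_hypercube()`.

These magnitudes were fixed once, so that a 153-sample cohort lands where
such a study operates: second-derivative full-spectrum PLSR around
Rp² ≈ 0.94, selected-wavelength models slightly better, fused models best.
With them frozen, the package's headline property — the tier ordering
*fused ≥ selected ≥ full*, as a median over cohort seeds — is an outcome,
not an input.

What the generator does **not** emulate: instrument line-spread and stray
light, real oil chemistry beyond band positions, spatial AV gradients
within a dish, and detector nonlinearity. Passing tests therefore show
that the pipeline recovers structure *of the kind the model class
assumes*; they do not certify accuracy on any particular real instrument.
The pixel-noise field of a stored scene is reused across bands (band noise
on the aggregate spectrum is drawn independently); this only matters to
the GLCM stage, where noise is negligible against the texture field.

## Pipeline stages and the choices behind them

### Reflectance extraction

ENVI cubes (BSQ/BIL/BIP, float32/uint16, little-endian) round-trip
bit-exactly through `write_envi()`/`read_envi()`. Calibration is the
standard two-reference form `R = (raw − dark)/(white − dark)`, clipped to
[0, 1.05]; references are averaged over repeated frames first
(`average_frames()`). The ROI is segmented on a band-window mean image by
Otsu's threshold, keeping the largest connected component — the method is
unstated in comparable studies and Otsu is the conventional
parameter-free default. The per-sample spectrum is the pixel mean over the
ROI, averaged over replicate acquisitions.

### Pretreatments

All seven pretreatments are per-spectrum maps (nothing is learned from the
calibration set): Savitzky–Golay smoothing and 1st/2nd derivatives
(window 11, polynomial order 2 — the common NIR default; derivatives are
per nm so magnitudes are grid-independent; edges are handled by the
window polynomial so 512 columns stay 512), SNV, min-max normalization,
and linear baseline correction. "Baseline" is read as a least-squares
linear detrend; plain offset subtraction is the special case with zero
slope and is also what the detrend removes first.

### Partitioning

Kennard–Stone maximin splitting at a 3:2 ratio (`ceiling(0.6 n)`;
153 → 92/61), computed on the second-derivative spectra — the
representation the downstream modelling tiers use — and shared by every
model so tiers are comparable. Ties break toward the lowest sample index
for reproducibility. Outlier screening (`remove_outliers()`) flags samples
by Mahalanobis distance in the score space of the principal components
explaining 95% of variance, at a chi-square 99% radius; it is available
ahead of the pipeline for cohorts that need it (the synthetic generator
produces clean cohorts, so `run_experiment()` does not screen by default).

### Wavelength selection

**SPA** builds, from every start column, a chain of minimally collinear
columns by repeated orthogonal projection, then scores each chain prefix
by multiple-linear-regression RMSE on an inner Kennard–Stone 70/30 split
of the calibration set (the outer prediction set is never touched, to
avoid selection leakage). The chain length is chosen by minimum validation
RMSE. A one-standard-error parsimony rule is available (`rule = "1se"`)
but is not the default: with ~28 inner validation samples the SE is so
large that the rule routinely collapsed chains to a single band,
destabilising the selected tier; the minimum rule keeps 2–10 bands and is
stable.

**CARS** runs 50 Monte-Carlo iterations: fit PLSR on a random 80% of
calibration samples over the surviving variables, rank by |coefficient|,
enforce the exponentially decreasing retention schedule
(`edf_ratio()`: from all `p` variables at run 1 down to 2 at run `N`),
then prune further by adaptive reweighted sampling (weighted draws with
replacement). Each run's survivor set is scored by 5-fold PLS RMSECV and
the minimiser wins. All constants (50 runs, 80% sampling, 10-component
cap, 5 folds) are the method's conventional defaults, exposed as
arguments.

On second-derivative spectra, SPA lands on the *side lobes* of the
acid-sensitive bands rather than their centres: the second derivative of a
Gaussian band peaks at the centre but carries equally strong lobes at
±σ√3 (≈30–50 nm for these band widths), and chains assembled for minimal
collinearity prefer one point per lobe. The acceptance suite asserts
proximity at the side-lobe span (±50 nm) accordingly.

### Texture features

The GLCM at offset distance `d = 1` and directions 0°, 45°, 90°, 135° is
computed on the reflectance image at each selected wavelength (not on
derivative images — texture is a property of the scene, not of a spectral
transform), after linear quantization of the ROI pixels to `k = 64` gray
levels. `k = 64`, `d = 1`, symmetric counting is the conventional Haralick
setup; all three are arguments. Four statistics summarise each matrix:
inverse difference moment f1, angular second moment f2, entropy f3
(natural log; the base only rescales f3), and correlation f4 (defined as 0
when a marginal variance vanishes, so constant ROIs stay finite). Per
sample this yields 16 values per wavelength, fused wavelength-major as
`w<nm>_t<deg>_f<1-4>`; all four directions are fused rather than
direction-averaged, keeping orientation information and matching the
16-features-per-wavelength accounting.

### Calibration models

PCR: SVD of the centred predictor matrix, OLS of the response on the
leading scores. PLSR: univariate-response NIPALS — weights `w ∝ X'y`,
scores `t = Xw`, rank-one deflation — chosen as the most literal
"regress on the components" formulation; the test suite cross-checks its
coefficients against an independently written SIMPLS to 1e-8, and both
models against OLS at full rank. Component counts are chosen by 5-fold
cross-validated RMSE with a one-standard-error rule toward fewer
components (stable at these fold sizes, unlike the SPA inner split). The
experiment-level cap is 20 components: on derivative spectra with shifted
interferent bands, the AV-relevant direction can sit beyond the first ten
principal components, and a tighter cap silently cripples PCR.

Spectral-only models are mean-centred; fused spectral + texture models are
autoscaled (unit column variance) because the blocks differ by orders of
magnitude.

### Metrics and comparisons

Rc²/Rp² are squared Pearson correlations between measured and predicted AV
on the calibration/prediction set — always in [0, 1]; a
coefficient-of-determination mode (`r2_mode = "q2"`) is available, and
RMSEC/RMSEP (mg/g) are reported alongside since a squared correlation
alone does not penalise calibration bias. Model-to-model improvements are
reported under *both* conventions in circulation — relative change
`(new − old)/old × 100` and absolute percentage points
`(new − old) × 100` — because published comparisons mix them; reporting
both side by side removes the ambiguity.

## Problem sizes used by the tests and the acceptance script

The validation suite runs entirely on synthetic data at the study's own
scale: ten cohorts of 153 samples (64 × 64 scenes) for the tier-ordering
property, asserted on medians across seeds (any single cohort can invert
a tier gap of ~0.01); twenty replicates of a 60 × 80 planted-variable
problem with 5 informative columns for selector recovery; and small
randomized problems (8 × 8 rasters, 20 × 10 regressions) for the
brute-force oracle equivalences. These sizes keep the full suite under
two minutes while leaving the stochastic assertions comfortable margins.

## Known limitations

* The texture–AV link is a single mechanism (correlation length); real
  film texture depends on viscosity, temperature and pouring history, so
  the fused tier's gain here is an existence proof, not an effect-size
  estimate.
* Squared-Pearson Rc² ignores calibration bias by construction; always
  read it with RMSEC.
* SPA scoring uses one deterministic inner split; a repeated or
  cross-validated scoring would be less variable but proportionally
  slower, and the chain construction itself is deterministic.
* CARS subset sizes vary widely across cohort seeds (its RMSECV surface
  is flat when many correlated bands are informative); the SPA tier is the
  stable one and is what the fusion tier builds on.
* `remove_outliers()` assumes approximately elliptical score clouds;
  grossly non-Gaussian cohorts need a different screen.
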