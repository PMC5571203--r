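---
title: "Methods: hyperspectral calibration and pixel-wise pectin mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral calibration and pixel-wise pectin mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pectinmap)
```

`pectinmap` links reflectance hypercubes of fruit-flesh cross-sections to
pectin contents (mg/g) via chemometric calibration, and applies the
calibrated model pixel by pixel to produce distribution maps. This
vignette documents the model, its assumptions, the tunable parameters, the
numerical choices, and — importantly — what the synthetic validation scene
does and does not demonstrate about real fruit data.

## The measurement model

A line-scan hyperspectral system records, per pixel, a reflectance
spectrum over either 380–1030 nm (silicon detector, 512 bands, "set I") or
874–1734 nm (InGaAs detector, 256 bands, "set II"). Raw counts are
converted to relative reflectance per element with white and dark
reference frames,

$$R = \frac{raw - dark}{white - dark},$$

(`reflectance_correct()`; values above 1 from specular pixels are kept and
left to masking). Flesh pixels are separated from background by
thresholding a high-contrast band and retaining the largest 4-connected
component (`threshold_segment()`). The slice-level characteristic spectrum
is the arithmetic mean over the ROI pixels (`mean_spectrum()`).

### Why calibration uses absorbance

`build_calibration_table()` converts each pixel spectrum to absorbance
$A(\lambda) = \log_{10}(1/R)$ *before* spatial averaging (a
`scale = "reflectance"` option averages raw reflectance instead). The
reason is structural: under a Beer–Lambert-type forward model the
log-reflectance of a pixel is linear in its constituent concentrations, so
the spatial mean of pixel absorbances is linear in the spatial mean
concentration — exactly the quantity the wet-chemistry reference assay
measures for the slice. Averaging reflectance instead mixes exponentials
and breaks that linearity for heterogeneous slices. On noiseless synthetic
scenes this choice makes the slice-level calibration problem exactly
linear, which is what lets the test suite demand essentially exact
recovery (RMSECV below 1e-6 mg/g) rather than merely "good" fits.

## Calibration models

Two families are fitted and compared (`fit_plsr()`, `fit_lssvm()`):

* **PLSR** by sequential NIPALS with deflation. Predictors and response
  are mean-centred only — no autoscaling, since per-spectrum scale is the
  preprocessing stage's job. Coefficients are mapped back to band space
  for every component count, so one fit prices all model sizes.
* **LS-SVM** with RBF kernel. Note the convention:
  $K_{ij} = \exp(-\lVert x_i - x_j\rVert^2 / \sigma^2)$ — `sigma2` divides
  the *squared* distance directly. This σ vs σ² ambiguity is a classic
  source of silent drift between implementations, hence it is fixed and
  stated here and in the function documentation.

**Evaluation** is full leave-one-out cross-validation by explicit refits
(`loo_cv()`): no hat-matrix shortcut for the model families, so PLSR and
LS-SVM share one code path and the n ≈ 64 refits stay cheap. Each model is
summarized (`compute_metrics()`) by RMSEC, RMSECV, the two Pearson
correlations, RPD = sd(y)/RMSECV (sample sd, n−1; reported as `Inf` when
RMSECV is exactly zero) and the robustness indicator
AB_RMSE = |RMSEC − RMSECV|.

**Hyperparameter tuning** (`tune_hyperparameters()`) minimizes LOO RMSECV:
component counts 1..min(20, n−1) for PLSR; a log₁₀ grid
$10^{-1}..10^{6} \times 10^{-1}..10^{6}$ for (γ, σ²). Ties, and near-ties
within float precision of the minimum, resolve toward the simplest model
(fewest components; smallest γ then σ²). Tuning reuses the same LOO split
as the reported evaluation — a deliberately non-nested protocol matching
how such studies typically report "RMSECV of the tuned model". The
resulting optimism is small at these grid sizes but real; anyone needing
unbiased error estimates should wrap an outer validation loop around
`calibrate_model()`.

## Preprocessing

Two pretreatments are provided (`preprocess_spec()`), applied row-wise:

* **SNV**: per-spectrum centring/scaling to mean 0, sample sd 1 (n−1
  denominator — the dominant convention; both moments are asserted in the
  tests so the convention cannot drift silently).
* **Savitzky–Golay** smoothing: local least-squares polynomial fits,
  default window 7, order 2, derivative 0. The leading/trailing
  (window−1)/2 points come from evaluating the terminal windows' fits
  off-centre, so polynomials up to the fit order are reproduced exactly
  everywhere. Window/order defaults are common chemometrics practice (no
  canonical values exist for this application) and are exposed as
  configuration.

When both steps are requested the fixed order is SG then SNV — smooth
first, then remove per-spectrum scatter. The pipeline's "with
preprocessing" arm is exactly this configured pair; the "raw" arm is the
identity.

## Wavelength selection

All four selectors operate on the preprocessed spectra (the fixed pipeline
order is preprocess → select → calibrate) and return reproducible,
seed-deterministic index sets:

* **SPA** grows, from every candidate start column, a chain that
  repeatedly adds the band with the largest norm after projection onto the
  orthogonal complement of the chain — so exactly collinear bands can
  never co-occur. Candidate sets (chain prefixes, sizes k_min..k_max) are
  scored by the leave-one-out RMSE of a plain multiple linear regression,
  computed through the exact PRESS identity (algebraically identical to
  explicit refits; the test oracle does the refits explicitly). Ties
  prefer fewer bands, then the smaller start index.
* **UVE** appends one artificial noise column per real band (uniform,
  scaled to 1e-10 of the spectral magnitude), jackknifes PLSR coefficients
  over the LOO folds, and computes stabilities
  $c_j = \mathrm{mean}(b_j)/\mathrm{sd}(b_j)$. The cutoff is
  `cutoff_factor` (default 1) times the largest |c| among the noise
  columns; by construction no noise column survives its own cutoff.
* **UVE–SPA** runs SPA restricted to the UVE survivors; diagnostics from
  both stages are retained.
* **CARS** performs N = 50 Monte-Carlo runs (sample fraction 0.8): PLSR on
  a random sample subset weights the retained bands by normalized |b|; the
  enforced exponentially decreasing schedule keeps the top
  $\lceil r_i p \rceil$ bands with $r_i = a e^{-ki}$,
  $a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$ (so $r_1 = 1$,
  $r_N = 2/p$), followed by adaptive reweighted sampling (weighted
  sampling with replacement, deduplicated, draw count $\lceil r_i p
  \rceil$). Each run's subset is scored by LOO RMSECV on the full sample
  set; the earliest minimal run wins. If the retained set drops below two
  bands the loop stops early and the best run so far is returned.

Selector parameter values (SPA k range, UVE noise count and latent rank,
CARS run count and fraction) have no canonical published values for this
application; the defaults above follow the original selector literature
and are all exposed as configuration.

## The model grid and its summaries

`run_model_grid()` evaluates spectral set × {full, SPA, UVE, UVE–SPA,
CARS} × {PLSR, LS-SVM} × {raw, preprocessed} — 40 cells per pectin target
when both sets are enabled, 20 per calibration method. Selection is re-run
once per (set, preprocessing arm) and shared by both calibration methods.
The best cell maximizes RPD; ties prefer fewer bands, then PLSR. A failing
cell records its error and the grid completes. `summarize_grid()` adds
per-axis marginal means of RPD/RMSECV, mean selected-band percentages, and
the between-set mean-RMSECV percentage ratio.

## Distribution maps

`predict_map()` replays the calibrated bundle's exact pipeline (recorded
spectral scale, preprocessing steps, selected bands, model) on every ROI
pixel. Negative predictions are clipped to 0 — contents are physical
concentrations — with the raw values kept in a debug channel and the clip
count reported. `render_pseudocolor()` maps values linearly onto a fixed
blue→cyan→green→yellow→red ramp over a *fixed* default display range of
[1, 6] mg/g (protopectin), so different slices are directly comparable;
per-slice autoscaling is available by passing explicit `vmin`/`vmax`. The
histogram bin width defaults to 0.25 mg/g. Maps describe only the exposed
cut surface — no depth extrapolation is attempted.

## The synthetic scene: what it does and does not emulate

`scene_config()` encodes the simulated study: two spectral sets, 64 slices
per set, elliptical slice masks with a central pit (real slice outlines
are irregular, but only the flesh/background separation matters
downstream), and per-slice concentration fields built as blurred white
noise rescaled to a target mean and sd then clipped at 0 — the simplest
smooth random field with controllable moments. Defaults:

| parameter | default | rationale |
|---|---|---|
| slice-mean protopectin | uniform on [1, 6] mg/g | span of a ripening series across storage conditions |
| slice-mean water-soluble pectin | uniform on [0.5, 3] mg/g | plausible ripening span; no published range exists |
| within-slice sd | 0.67 mg/g | heterogeneity of a typical example slice |
| field smoothness | 6 px blur | fields vary on a tissue, not pixel, scale |
| baseline reflectance | 0.6 | bright cut flesh |
| absorption bands | Gaussians near 760/980/1460 nm (O–H overtones) and 1200 nm (C–H) | places component signatures in both camera ranges |
| scatter | slope sd 0.05, offset sd 0.01 | gives SNV something real to remove |
| sensor noise | sd 0.003 reflectance | typical line-scan camera noise |

Reflectance follows
$R(\lambda) = slope \cdot baseline \cdot e^{-\sum_k c_k A_k(\lambda)} +
offset + noise$, so log-reflectance is exactly linear in the
concentrations when scatter and noise vanish; total pectin equals
protopectin + water-soluble pectin at every pixel and slice by
construction. One master seed drives everything; per-slice sub-seeds are
derived by fixed mixing, so generation is deterministic and slices are
independent of how many are generated.

**Limitations.** The scene deliberately omits: reference-assay error (the
wet-chemistry values are triplicate measurements with real variance),
model mismatch (real tissue optics are not single-path Beer–Lambert;
scattering is wavelength-dependent), pericarp, irregular slice geometry,
and inter-fruit biological covariance. Consequently the slice-mean signal
in synthetic tables is far cleaner than in real data, and RPD values from
synthetic runs (often in the hundreds) must not be read as attainable
instrument performance — on real fruit data this class of model typically
achieves RPD around 2 for the best-predicted component. What the passing
tests *do* establish is the correctness of every computational stage:
exact recovery where the mathematics says recovery should be exact, metric
identities, selector behaviour on planted supports, and end-to-end
determinism.

## Numerical choices

* NIPALS extraction stops when the residual covariance or score norm falls
  below 1e-14 (relative to the first component) — a relative, not
  absolute, floor, so genuinely small but real components on
  near-noiseless data are kept while float-noise components are not.
* LS-SVM systems are solved directly; the KKT residual is stored on the
  model and asserted < 1e-8 in the tests. A singular system raises a
  classed `numerical_failure` error with a condition estimate.
* Absorbance uses a reflectance floor of 1e-6 so noisy near-zero pixels
  cannot produce infinities.
* All tie-breaks (tuning, SPA, CARS winning run, grid best cell) are
  deterministic and documented above, so repeated runs are bit-identical.
* Errors are classed conditions (`pectinmap_invalid_argument`,
  `pectinmap_empty_roi`, `pectinmap_corrupt_file`, ...) so pipelines can
  dispatch on failure kind; stage wrappers prepend the failing stage and
  fold/row index.

## Problem sizes used in the shipped validation

The test suite exercises the full simulated study size — 64 slices per
set, 512 and 256 bands — for the parameter-recovery and grid checks, with
64 × 64-pixel slices (pixel count only affects the spatial averaging, not
the slice-level statistics, so a moderate image size is used). Smaller
scenes (10–20 slices, 16–48 bands) back the per-module unit and property
tests. `scripts/acceptance.R` re-runs the full-size computations from
scratch and writes the resulting quantities as JSON.
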