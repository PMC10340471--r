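---
title: "Models and methods behind mushspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mushspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mushspec)
```

mushspec implements the analysis chain of a portable visible-range
diffuse-reflectance sensor for white button mushrooms: spectra on a fixed
450–760 nm grid at 1 nm (311 bands) feed two quality endpoints, wet-basis
moisture content and colorimetric whiteness. This vignette explains the
models, the parameters that matter, the synthetic data the package is
validated on, and the numerical choices a user auditing results should know
about.

## The measurement model

A measured spectrum is treated as

$$ s_i^{obs}(\lambda) \;=\; a_i + b_i\, s_i(\lambda) + \varepsilon_i(\lambda), $$

where $s_i$ is the sample's true diffuse reflectance, $a_i$ and $b_i$ are
per-sample additive and multiplicative scatter (path-length and surface
geometry effects), and $\varepsilon_i$ is band-wise measurement noise. Two
instruments viewing the same sample are assumed to differ by a fixed
per-wavelength offset; `fit_offset()` estimates it as the mean of the
per-sample differences and `apply_offset()` adds it back. Note the
calibration model is offset-only — no gain term — so it can remove a
systematic spectral bias but not a sensitivity difference. The default sign
convention averages *reference − device*, which makes the correction
converge to the reference; the literal *device − reference* convention is
kept only for comparison, since adding that offset moves spectra away from
the reference.

Scatter is removed per spectrum before modeling. Four standard transforms
are available: Savitzky–Golay smoothing, min–max normalization, SNV, and
MSC. Defaults worth knowing:

* **SG** window 7 bands, polynomial order 2. Terminal half-windows are
  filled by evaluating the polynomial fitted to the first/last full window
  at the edge positions, so the band count never changes. Window shrinkage
  at the edges was rejected because it silently changes the effective
  smoothing bandwidth there.
* **Normalization** is min–max to [0, 1] per spectrum; a unit-norm variant
  sits behind `method = "unit_norm"`.
* **SNV** uses the population (1/N) standard deviation, so its output
  moments are exactly 0 and 1 and tests can assert them at 1e-12.
* **MSC** regresses each spectrum on a reference and inverts the fit. The
  reference should be the *training-set* mean, computed once and reused for
  test spectra (as `run_moisture()` does); re-estimating it on test data
  would leak information.

## Wavelength selection and dimension reduction

`spa_select()` implements the successive projections algorithm: starting
from a candidate band, it repeatedly admits the band whose column has the
largest norm after projecting out the span of the bands already selected,
which minimizes collinearity by construction. Chains are grown from every
possible start, every prefix is scored by the RMSE of a multiple linear
regression of the response on those bands under 5-fold cross-validation,
and the global RMSE minimum decides both the subset and its size. Folds are
assigned round-robin in sample order — a deliberate simplification that
makes selection deterministic without consuming a random stream; with
shuffled samples (as all pipeline callers have) it is equivalent to an
arbitrary fixed partition. Ties in projection norm go to the lowest band
index, ties in RMSE to the earliest start and smallest size.

`pca_fit()` is principal components on mean-centered, unscaled
reflectances (chemometric convention: bands share a physical scale, so
variance scaling would inflate noisy bands). `pca_select()` retains the
smallest number of leading components whose cumulative contribution rate
reaches a threshold, 0.95 by default.

## Regression models

**PLS1** (`plsr_fit()`): standard iterative deflation, factors chosen by
5-fold cross-validated RMSE. Prediction through the collapsed coefficient
vector and through the factor path agree to 1e-8, which is asserted in
tests.

**BP network** (`bp_train()`): three layers, tansig hidden units (5–10),
linear output. Inputs are mapped feature-wise to [−1, 1] and the response
is standardized; the stored mappings are inverted at prediction. Training
is Levenberg–Marquardt on the full Jacobian: damping ×0.1 after an accepted
step, ×10 after a rejected one, stopping at the MSE goal (0.001 on the
standardized scale), 100 epochs, a vanishing gradient, or damping overflow
at 1e10. When the network has more weights than there are training samples
(full-spectrum inputs: 311·h + 2h + 1 weights), the step is computed through
the n×n dual system $\delta = J^\top (JJ^\top + \mu I)^{-1} r$, identical in
exact arithmetic and dramatically cheaper. The learning rate 0.1 is stored
for the gradient-descent fallback (`algorithm = "gd"`); LM does not use it.
`bp_scan_hidden()` trains one network per hidden size on an internal 4:1
split, picks the best validation R², then refits that size on all supplied
samples — refitting uses all the data the caller allotted to training and is
what the reported training metrics describe.

**Sparrow search** (`ssa_optimize()`): canonical producer / scrounger /
scout rules with the settings population 10, 20 iterations, 70% producers,
20% scouts, alert threshold 0.6. `ssa_bp_train()` searches the network's
packed initial weight vector in [−1, 1]^p: each candidate gets a 20-epoch
LM refinement on an inner 4:1 split and is scored by validation MSE — the
standard construction for metaheuristic-initialized networks, since the
final trained loss is what one actually cares about. The winning
initialization then seeds a full 1000-epoch run (plain networks use 100
epochs; the longer budget belongs to the refinement context). With
`n_iter = 0` the wrapper reduces exactly to plain training from the seeded
initialization. Elitism guarantees the reported best-so-far fitness history
is monotone. The search covers initial weights only, not hidden-layer size;
combine with `bp_scan_hidden()` when the size is also open.

## Whiteness colorimetry

Tristimulus values use the equal-interval wavelength method over
450–760 nm with the CIE 1964 10° observer and a D65-like illuminant:
$X_{10} = K \sum \delta(\lambda) R(\lambda) \bar{x}_{10}(\lambda)
\Delta\lambda$, with $K = 100 / \sum R(\lambda) \bar{y}_{10}(\lambda)
\Delta\lambda$ so a perfect reflector scores exactly $Y_{10} = 100$.
Numerical points:

* The summation uses trapezoidal end weights (half weight at 450 and
  760 nm). The integration range truncates where $\bar{z}_{10}$ and
  $\bar{x}_{10}$ are still far from zero, and plain rectangle sums would
  disagree with any honest quadrature of the same integrand by more than
  0.1% there.
* An alternative normalization that folds the sample reflectance into $K$
  is available (`k_convention = "sample"`); it forces $Y_{10} \equiv 100$
  for every sample and therefore cannot rank samples — it exists for
  comparison only.
* The observer functions are computed from the published multi-lobe
  Gaussian analytic approximations, and the illuminant is a Planckian
  radiator at 6504 K normalized to 100 at 560 nm — smooth approximations,
  not the official CIE tables, accurate to a few percent locally. Every
  downstream constant (normalization, whiteboard white point) derives from
  the same functions, so whiteness values are internally consistent; pass
  externally tabulated data to `tristimulus()` / `whiteness_pipeline()`
  when strict table fidelity matters.
* The whiteboard reference defaults to the illuminant white point (a
  perfect diffuser's chromaticity), which makes $W_{10} = 100$ for the
  perfect reflector by construction.

Ganz whiteness is the printed affine form
$W_{10} = Y_{10} + 800(x_n - x_{10}) + 1700(y_n - y_{10})$, unclamped.
Grading uses the four calibrated whiteness bands [61.05, 81.84],
[34.23, 49.7], [25.08, 34.66], [13.15, 22.81] with thresholds at the
midpoints of adjacent band edges: 55.375, 34.445, 23.945. Bands 2 and 3
overlap on [34.23, 34.66]; inside the overlap the midpoint threshold
decides and no flag is raised. Values between bands are graded by the same
thresholds but flagged `"gap"`; values beyond [13.15, 81.84] map to the
nearest extreme flagged `"out_of_calibration"`.

## The synthetic-spectra generator

`generate_spectra()` emulates the statistical structure the analysis
assumes, not mushroom tissue optics. A clean spectrum is

$$ s(\lambda) = \mathrm{base}(\lambda)\,\big(1 - d_g\, e^{-(\lambda-450)/110}\big)
   \;-\; \sum_{k=1}^{6} c_k(M)\, g_k(\lambda), $$

a smooth high-reflectance base curve, a browning dip that multiplies it and
grows toward short wavelengths (browning pigments absorb blue), and six
Gaussian absorption bands centered at 475, 490, 650, 690, 730 and 740 nm
whose depths are affine in moisture $M$. The affine moisture map is the
simplest structure under which both linear and network models should
succeed; a quadratic term can be switched on to break exact linearity.
Scatter and noise are then applied per the measurement model above.
Defaults, chosen once as the package's study conditions:

* `n_samples = 200`, `moisture_range = c(80, 95)` % — a plausible wet-basis
  range for fresh mushrooms; the true distribution of any field cohort is
  unknown, and these are stand-ins, not facts about real produce.
* `grade_mix = c(.25, .25, .25, .25)` for the population default;
  `run_moisture()` overrides to an all-grade-1 cohort because a moisture
  study is run on fresh, uniformly white mushrooms — with mixed grades the
  browning variance overlaps the moisture bands and dominates the signal.
* `scatter_slope_sd = 0.05` (log scale), `scatter_offset_sd = 0.02` —
  enough scatter that MSC/SNV visibly matter.
* `noise_sd = 0.005` reflectance units, the level at which the
  full-spectrum network generalizes at Rp² ≈ 0.8 and band selection has
  something to gain, mirroring the regime the method is designed for.
* Browning depths $d_g$ = 0.0222 / 0.2237 / 0.2909 / 0.3586 were calibrated
  once by bisection so that each grade's clean whiteness at mid-range
  moisture sits at the center of its grading band, and then frozen.

Ground truth (moisture, grade, clean spectra, scatter parameters) is
returned alongside, which is what lets tests make exact claims: MSC must
recover $(a_i, b_i)$ to 1e-8 at zero noise, and moisture must be exactly
recoverable from clean spectra by least squares on the six-band basis
(`moisture_from_clean()`).

What passing these tests does **not** show: real mushroom reflectance has
no reason to be affine in moisture, browning does not follow a single
exponential shape, instrument noise is not white, and the printed grading
bands came from sensory panels, not from this generator. Synthetic runs
validate the machinery and reproduce orderings (band selection beats the
full spectrum; search-initialized networks do not hurt; grade medians
separate), never field accuracy.

## Problem sizes and reproducibility

The shipped workflows use the study-scale conditions throughout: 200
moisture samples split 160/40 and 4 × 40 whiteness samples split 128/32,
sizes at which the full pipeline (including the 311-start SPA scan and the
sparrow search) completes in well under a minute. Every stochastic step —
generation, splitting, initialization, search — takes an explicit integer
seed and restores the caller's RNG state, so identical calls are bitwise
reproducible; `run_moisture()` and `run_whiteness()` return a manifest of
the settings that produced them. `scripts/acceptance.R --seed N --out f`
re-derives the headline numbers from scratch.

## Known limitations

* Offset-only calibration cannot correct gain differences between
  instruments.
* The colorimetric tables are analytic approximations (above); absolute
  tristimulus values can deviate a few percent from official-table values,
  though whiteness comparisons between samples are consistent.
* SPA's cross-validated scoring is the only guard against selecting noise
  bands; at high noise it can still pick spurious wavelengths, which is
  visible in the synthetic runs as degraded SPA-model test metrics.
* Levenberg–Marquardt training is exact but dense: networks far larger
  than the 5–10 hidden units used here would need a different optimizer.
* The grading thresholds interpolate printed band edges; between-band and
  out-of-band values are flagged rather than refused.
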