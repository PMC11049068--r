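---
title: "NIR calibration with PLS and competitive wavelength selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR calibration with PLS and competitive wavelength selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Near-infrared (NIR) absorbance spectra of dried, powdered plant material are
cheap to acquire but hard to read: the 1000–2500 nm region is dominated by
broad, heavily overlapping –OH, –NH and –CH overtone and combination bands,
plus baseline drift and particle-size scatter that have nothing to do with
composition. Quantifying a metabolite (here: concentrations in g kg⁻¹ of
quality markers such as total saponins, mannitol or naringenin) therefore
requires a multivariate calibration chain: scatter-corrective pretreatment,
outlier screening, a representative calibration/prediction split, a
latent-variable regression, and — because most of the ~1500 channels carry
redundant or irrelevant information — wavelength selection.

`nirquant` implements that chain end to end, with every stage exposed as a
data-frame-in / tibble-out function, and ships a synthetic spectra generator
with known ground truth so that each stage, and the chain as a whole, is
testable without access to proprietary spectra.

# The model chain

## Spectral pretreatment

Five composable operators act row-wise on the n × p absorbance matrix:

* **Moving-window smoothing** (`sg_smooth()`): at channel k the value becomes
  $\frac{1}{H}\sum_{i=-w}^{w} x_{k+i} h_i$, $H = \sum h_i$, with uniform
  default weights. Near the edges the window shrinks symmetrically rather
  than padding invented data.
* **Gap derivatives** (`gap_derivative()`): first order
  $(x_{k+g}-x_{k-g})/g$, second order $(x_{k+g}-2x_k+x_{k-g})/g^2$. The
  first-order divisor is `g`; the conventional central-difference divisor
  `2g` is available via `divisor = "conventional"`, which changes only the
  overall scale. The g channels at each edge are trimmed and the wavelength
  axis is trimmed with them, so downstream channel indices stay aligned.
* **MSC** (`msc_fit()` / `msc_transform()`): models each spectrum as an
  affine distortion $x = m_i \bar X + b_i$ of the calibration-mean spectrum
  and inverts it, $(x - b_i)/m_i$. The reference $\bar X$ is always frozen
  on the calibration partition: recomputing it on prediction samples would
  leak information across the split.
* **SNV** (`snv()`): per-spectrum centering and scaling by the per-spectrum
  standard deviation (n − 1 denominator). Exactly removes any per-sample
  affine distortion, which is why the generator's scatter model is affine.

Defaults `window = 7` and `gap = 5` channels are conventional mid-range
values for ~1500-channel NIR spectra; both are exposed everywhere. The
"d1_sg" / "d2_sg" methods smooth first, then differentiate — the standard
composition, since differentiation amplifies channel noise.

## Outlier screening and partitioning

Spectra matrices have p ≫ n, so the full-space covariance is singular;
`mahalanobis_screen()` computes Mahalanobis distances in a k-dimensional PCA
score space (default k = 5) and flags samples beyond
mean + 3 sd of the distances. Both knobs are configurable; the defaults are
ordinary practice, not derived quantities.

`kennard_stone()` partitions deterministically by the max–min rule: seed
with the two most distant spectra, then repeatedly add the candidate whose
minimum distance to the selected set is largest. Ties break toward the lower
sample index, making the partition reproducible to the byte. With n = 120
and an 80% calibration fraction this reproduces the familiar 96/24 split
(94/23 after three outliers from 117).

A note on coverage: an 80/20 max–min split makes the calibration
concentration ranges *almost* cover the prediction ranges, but cannot
guarantee strict coverage of every marginal extreme — reference studies
report small overhangs (~1–2% of the calibration range), and the package's
tests assert exactly that near-coverage property rather than strict
containment.

## PLS1 and cross-validation

`pls_fit()` is NIPALS PLS1 with mean-centering only (no autoscaling — the
dominant convention in NIR work, where all channels share units). The fit
stores regression coefficient vectors for *every* component count up to the
requested A, so `pls_cv()` obtains the whole RMSECV-versus-components curve
from one fit per fold. Cross-validation is leave-one-out by default, with
deterministic k-fold (assigned by sample order) available where speed
matters. The component count is the RMSECV argmin; near-ties within a
relative 1e−8 of the minimum resolve to the smaller A, so that on noiseless
data — where every A at or above the true rank is equivalent up to float
noise — the parsimonious model wins. `ncomp_max` defaults to 18, the upper
end of what ~96-sample NIR calibrations support.

At the saturated component count, PLS1 predictions coincide with ordinary
least squares; the test suite checks this against an explicit
pseudoinverse solve on small seeded matrices.

## Wavelength selection

**UVE** (`uve_select()`) appends p artificial uniform-noise channels
(amplitude 1e−10 × max|X|: too small to perturb the fit, nonzero so
coefficients are defined), collects regression coefficients over
leave-one-out refits, and scores every channel by the stability ratio
h = mean(β)/sd(β). Real channels whose |h| does not exceed the largest |h|
among the noise channels are discarded. A quantile variant of the threshold
is available. UVE always uses leave-one-out folds for β resampling — with
k-fold there are too few coefficient draws for a stable ratio.

**CARS** (`cars_select()`) runs N Monte-Carlo sampling runs (default 100).
Each run draws 80% of the calibration samples, fits PLS on the surviving
channels, and prunes in two stages: a forced exponential retention keeping
the top $\lceil r_i p\rceil$ channels by |β| weight, where
$r_i = a e^{-k i}$ with a and k fixed by "run 1 keeps all p, run N keeps 2";
then adaptive reweighted sampling — that many draws with replacement with
probability proportional to weight, keeping the distinct channels drawn.
Each run's surviving subset is scored by cross-validated RMSECV on the full
calibration set with the component count re-optimized, and the best-scoring
subset wins. Channels eliminated once never return; if the subset collapses
below two channels the algorithm stops early at the last valid run with a
warning. The Monte-Carlo weight fit uses A = min(ncomp_max, n_mc − 1,
|subset|) components; the canonical formulation leaves this open, and the
recorded per-run RMSECV re-optimizes A anyway.

## Evaluation

`evaluate_model()` reports calibration and prediction R², RMSEC/RMSEP
(plain-count divisor), RMSECV recomputed on the final channel subset at the
final component count, and the residual predictive deviation
RPD = sd(reference values)/RMSEP with the customary bands (> 2 exceptional,
1.4–2 general, < 1.4 poor; sd uses the n − 1 denominator). Two R²
conventions are provided: the classical one (total sum of squares centered
on the measured mean) for calibration, and a prediction-set variant centered
on the *predicted* mean, kept for fidelity with common NIR reporting; they
coincide exactly when the two means agree, and both are exposed.
`compare_models()` assembles the three-way full/UVE/CARS table and appends
the percent RMSEP reduction of CARS over the full spectrum,
$100\,(RMSEP_{full} - RMSEP_{cars})/RMSEP_{full}$.

# The synthetic generator

`generate_nir()` draws concentrations uniformly and independently per
analyte (ranges default to those of a three-marker plant-powder study:
0.79–5.79, 1.57–5.91 and 0.0038–0.0369 g kg⁻¹) and builds each spectrum as

$$s_i = m_i\Big(\textstyle\sum_c c_{ic}\,\text{pure}_c + \text{baseline}_i\Big) + b_i + \varepsilon_i$$

with Gaussian-band pure-component spectra, a per-sample random quadratic
baseline, per-sample affine scatter ($m_i$ lognormal with log-sd 0.05,
$b_i$ Gaussian with sd 0.02) and white noise (sd 5e−4 absorbance). The
default axis is 1000–2500 nm in 1557 uniform channels. Band positions echo
real assignments (–OH near 1450/1940 nm, saponin-like bands near 1505/2150
nm, aromatic –CH near 1680/2315 nm); heights are scaled so absorbance sits
in the 0.1–1 range typical of powdered-sample FT-NIR, and the trace analyte
gets proportionally taller per-unit bands. Noise and scatter magnitudes are
ordinary instrument-and-sampling values chosen once when the generator was
designed. The answer key records, per component, the channels where the
pure spectrum exceeds 1% of its maximum — the target set for selection
tests.

The scatter model is deliberately the affine distortion that MSC inverts
and SNV annihilates, so scatter-correction correctness is analytically
checkable. What the generator does *not* emulate: nonlinear detector
response, wavelength-dependent scatter (the real particle-size effect is
only approximately affine), correlated (pink) noise, instrument line-shape,
and band shifts with matrix composition. Passing tests therefore show the
algorithms are implemented correctly and behave as designed on data obeying
their assumptions — not that any given real instrument will achieve the
same figures.

One consequence deserves emphasis. Because the synthetic data are *exactly*
low-rank linear, a full-spectrum PLS model with two or three components is
already near-optimal on them, and wavelength selection — which discards the
noise-averaging benefit of redundant channels — typically *worsens*
out-of-sample RMSEP on band-structured synthetic data even while it lowers
RMSECV (its own selection criterion). The prediction benefit of CARS
materializes in the regime its rationale describes: many channels carrying
no analyte information at all. On planted-channel data (two informative
channels among dozens of pure-noise ones) CARS reduces out-of-sample RMSEP
by ~96% relative to the full spectrum and recovers the true channels with
recall 1.0. Both regimes are exercised in the tests and reported by the
acceptance script; real NIR spectra sit between them, which is why
published CARS gains on real data are positive but modest.

# The experiment driver

`run_full_experiment()` executes screen → split → pretreatment sweep →
{full, UVE, CARS} → evaluation from one `pipeline_config()`. The sweep
fits a full-spectrum model per candidate pretreatment and picks the winner
by prediction-set R² (ties: lower RMSEP) — this mirrors the common
reporting practice of choosing the pretreatment on the test grid, and is
the one place the prediction set is consulted before final evaluation;
wavelength selection and every cross-validation see calibration samples
only, which a dedicated test enforces by scrambling prediction-set
concentrations and demanding identical selections. One master seed derives
per-stage seeds, making the whole experiment reproducible to the byte; the
manifest records counts, winners, subset sizes and per-stage timings, and
all artifacts are plain text.

# Numerical choices and degenerate inputs

* Constant spectra (SNV) and zero MSC slopes are errors naming the sample.
* A singular covariance in the Mahalanobis score space errors with advice
  to lower k.
* NIPALS stops early if no covariance with y remains; coefficients for
  higher component counts then repeat the last computed ones.
* EDF budgets are `ceiling(ratio * p)` and never drop below 2; CARS stops
  early (with a warning) if adaptive resampling leaves fewer than 2
  distinct channels.
* Zero-variance y and out-of-range component counts are validation errors.

# Problem sizes used in the checks

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as the package's own test design: selection-recovery suites at
n = 60–80, p = 40–50 over 20 seeded replicates; the end-to-end experiment
at 120 × 300 with a 100-run CARS schedule and 5-fold RMSECV; determinism
checks at the full 120 × 1557 with a 50-run schedule. These sizes keep the
whole suite in tens of seconds while leaving every algorithmic path
exercised at full fidelity.

# Known limitations

* PLS1 only — one analyte per model; multi-response PLS2 is out of scope.
* True Savitzky–Golay polynomial filters, orthogonal signal correction and
  detrending are not implemented; smoothing is the weighted moving average
  defined above.
* The Mahalanobis screen is purely spectral; concentration-augmented
  screening would require joining the reference table into the distance
  space and is left to the caller.
* Wavelength axes are nm-only; cm⁻¹ users should convert (the mapping is
  monotone, so channel selection is unaffected).
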