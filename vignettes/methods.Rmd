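---
title: "Voxel-to-whole-brain intrinsic activity analysis: models and design choices"
author: "restiba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-to-whole-brain intrinsic activity analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restiba)
```

# Overview

`restiba` implements a complete resting-state fMRI intrinsic-activity
analysis from single-voxel time series up to whole-brain group inference:

1. **Temporal preprocessing** — initial-volume discard, per-voxel linear
   detrending, nuisance regression (Friston-24 motion expansion plus mean
   white-matter and cerebrospinal-fluid signals), and an ideal
   frequency-domain band-pass filter (0.01–0.08 Hz).
2. **Five intrinsic-activity metrics** — ALFF, fALFF, PerAF, ReHo
   (Kendall's coefficient of concordance over a voxel's neighbourhood) and
   degree centrality (DC), followed by global-mean standardization and
   Gaussian smoothing, in that order.
3. **Group inference** — a voxelwise two-sample GLM (group, mean framewise
   displacement, site), with cluster-level correction by Gaussian random
   field (GRF) theory.
4. **Behavioral statistics** — demographic two-sample t and chi-square
   tests, MCI-reverter classification from logical-memory and MMSE
   trajectories, partial correlations between cluster metric values and
   cognitive scores, and Benjamini–Hochberg FDR control.
5. **A synthetic cohort generator** that plants known amplitude, synchrony
   and hub effects in two-group BOLD data, so that every downstream stage
   can be validated against ground truth.

This vignette records the models, the tunable parameters, and the design
decisions taken where a published analysis description leaves the
implementation genuinely open.

# The synthetic cohort generator

## Signal model

Each voxel's BOLD series is

$$X_v(t) = \mu_0 + o_s + \sum_{i=1}^{m} a_{vi}\cos(2\pi f_i t\,\mathrm{TR} + \phi_{vi}) + \varepsilon_v(t),$$

with baseline intensity $\mu_0$ (default 1000, arbitrary units), a
site-specific additive offset $o_s$, $m \in \{3,\dots,8\}$ low-frequency
sinusoids, and white Gaussian noise
$\varepsilon_v(t) \sim N(0, (\sigma \cdot c_s)^2)$ whose SD is the product
of the baseline noise level $\sigma$ (default 10) and a site noise-scale
multiplier $c_s$. The sum of sinusoids plus white noise is deliberately the
simplest model for which the amplitude metrics have near-closed-form
behaviour.

Three generator choices matter for testability:

* **Frequencies are drawn uniformly in the 0.01–0.08 Hz band and snapped
  to DFT bins of the series.** On exact bins the in-band mean spectral
  amplitude of a noiseless voxel is proportional to its total oscillation
  amplitude, independent of the random phases, so planted amplitude ratios
  are recovered *exactly* by a DFT oracle on the generated series.
* **Per-voxel weights are normalised so every voxel carries the same total
  amplitude** (`ampTotal`, default 20). A planted `amplitude` region
  multiplies this total by `group_ratio` in the reverter-like group,
  giving an exactly known effect size.
* **All randomness flows from one root seed through named substreams**
  (`bold`, `motion`, `scores`, per-subject indices), so any component can
  be regenerated bit-identically in isolation.

`synchrony` regions mix each member voxel's own oscillation with one
shared latent course (mixing weight 0.55, scaled by `group_ratio` in group
1 and capped at 0.95), raising within-neighbourhood rank concordance.
`hub` regions mix with a latent course shared with a fixed 15% "satellite"
subset of distant voxels (hub coupling 0.6 × ratio, satellites 0.4),
raising suprathreshold correlation counts. The mixing constants are fixed
design values chosen to give clearly separated but not degenerate effects;
they are not calibrated to any empirical dataset, because the emulated
study reports no effect sizes for its group differences.

## What the generator does and does not emulate

It emulates: two groups over multiple sites with additive intensity and
multiplicative noise site effects; in-band oscillatory signal embedded in
white noise; random-walk rigid-body motion traces (6 parameters, SPM
`rp_*.txt` dialect — translations in mm, rotations in radians); the two
acquisition presets of interest (TR 3.0 s / 197 volumes and TR 0.607 s /
976 volumes, with a desk-scale default of a 24³ grid and 120 volumes at
TR 3 s); and behavioral scores linearly tied to a per-subject effect
magnitude.

It does **not** emulate haemodynamic-response convolution, physiological
(cardiac/respiratory) noise, scanner drift beyond a linear trend, spatial
autocorrelation of the raw noise, or anatomically realistic geometry
(the brain mask is a box interior; WM/CSF masks are small cubes used only
to supply nuisance courses). Passing tests on this cohort therefore
demonstrate correctness of the computational pipeline under a known
signal model — not robustness to the full complexity of acquired fMRI.

# Temporal preprocessing

Stage order is fixed and enforced through provenance flags on the
`BoldSeries` object: discard → detrend → nuisance regression → band-pass.
Calling a stage out of order raises an error naming the missing stage, and
a flag, once set, is never unset.

* **Volume discard** (`nDiscard`, default 10): drops the initial
  scanner-stabilisation volumes and records each voxel's raw-scale mean
  over the retained volumes — the μ that PerAF needs later.
* **Detrending**: per-voxel OLS line removal; residuals have exactly zero
  mean and slope.
* **Nuisance regression**: intercept + 24 Friston motion columns
  ($p, p^2, p_{t-1}, p_{t-1}^2$ for each of the 6 parameters, lag row
  zero-padded at $t=1$) + mean WM and CSF courses. Collinear columns are
  dropped with a warning; a design that saturates the available time
  points is refused outright rather than silently annihilating the data.
  The WM/CSF masks are caller-supplied: the package takes no position on
  subject-specific versus template tissue masks.
* **Band-pass** (0.01–0.08 Hz): an ideal DFT boxcar in the REST/DPABI
  convention — bins with $f_{low} \le f \le f_{high}$ (inclusive) are
  kept, everything else including the DC bin is zeroed. The inclusive-edge
  rule makes bin-exact tests well defined, and the filter is a projection
  (idempotent, never energy-increasing). A band reaching the Nyquist
  frequency $1/(2\,\mathrm{TR})$ is rejected.
* **Framewise displacement**: Power-style
  $FD(t) = \sum|\Delta d| + r\sum|\Delta \theta|$ with head radius
  $r = 50$ mm (configurable); FD(1) = 0 by convention.
* **Motion QC**: exclude if any |translation| > 3 mm **or** any
  |rotation| > 3°, strict inequalities (exactly 3 mm is retained).
  Rotations live in radians on disk and are converted to degrees only for
  this rule.

Slice-timing correction and spatial preprocessing (realignment,
normalization) are out of scope: the synthetic data need neither, and both
belong to the upstream toolchain when real data are used. Volume censoring
("scrubbing") is likewise not performed — mean FD enters the group model
as a covariate instead.

**The unfiltered branch.** ALFF and fALFF are defined on the
*unfiltered* (but otherwise fully preprocessed) series, because their own
definitions restrict to the band — ALFF's spectral averaging *is* the
filter, and fALFF needs the whole-spectrum denominator. `preprocessSubject`
therefore returns both branches, and the metric functions enforce the
contract: `computeALFF`/`computeFALFF` reject a filtered input, while
`computePerAF`/`computeReHo`/`computeDC` require one.

# The five metrics

With $n$ time points and single-sided amplitude spectrum
$A_k = 2|F_k|/n$ at bin frequencies $f_k = k/(n\,\mathrm{TR})$:

* **ALFF** = mean of $A_k$ over in-band bins (the averaged square root of
  the power spectrum across the band).
* **fALFF** = (sum of in-band $A_k$) / (sum of all positive-frequency
  $A_k$). The 0 Hz bin is excluded from the denominator — mean intensity
  is not "fluctuation" — which makes fALFF of a mean-zero purely in-band
  signal exactly 1; 0/0 is defined as 0.
* **PerAF** $= \frac{1}{n}\sum_i \frac{|X_i - \mu|}{\mu} \times 100\%$.
  Band-passing removes μ, so the filtered residuals are re-centred by
  adding back the voxel's stored raw-scale mean before applying the
  formula. Voxels with non-positive restored mean are set to 0 and
  counted in a reported attribute.
* **ReHo**: Kendall's W of the voxel's neighbourhood over time,
  $$W = \frac{\sum_i R_i^2 - n\bar R^2}{\frac{1}{12}K^2(n^3-n)},$$
  with $R_i$ the across-series rank sum at time $i$ (average ranks on
  ties), $K \in \{7, 19, 27\}$ (default 27: the voxel and its 26
  neighbours). At mask edges only in-mask neighbours participate and $K$
  becomes the actual member count — a documented divergence from the
  fixed-$K$ formula that avoids edge artifacts; interior voxels use the
  full $K$. W is clipped into [0, 1] (ties can push the uncorrected
  formula marginally outside).
* **DC**: binarized DC of voxel $i$ counts voxels $j \ne i$ with Pearson
  $r_{ij} > r_0$ (default 0.25, strict inequality, positive correlations
  only — the formula is literal about $r > 0.25$, so anticorrelations
  never contribute); weighted mode sums those $r_{ij}$. Correlations are
  computed block-wise so the full voxel × voxel matrix is never held in
  memory, with results independent of block size (tested). Correlations
  involving a zero-variance voxel are defined as 0 and logged. Only the
  self-correlation is excluded; within-neighbourhood correlations count.

**Standardization** follows the m-map convention: each voxel is divided by
the global in-mask mean, so the standardized map has in-mask mean exactly
1. The wording "subtracting the value from each voxel, and divided by the
global mean value" admits two readings; division is the dominant
convention for mALFF/mReHo maps and is the default here, with a z-mode
(subtract mean, divide SD) available and tested. Which mask defines
"global" is the caller's choice — the mask is an explicit argument
throughout.

**Smoothing** (4 mm FWHM default) happens *after* metric calculation —
smoothing first would inflate the local correlations that ReHo and DC
measure. The kernel is a separable Gaussian with
$\sigma_{vox} = \mathrm{FWHM}/(2\sqrt{2\ln 2}\cdot\mathrm{voxel\ size})$,
truncated at 4σ, unit-normalised, applied over the full grid with
zero-padded edges and then re-masked (the volumetric-toolbox behaviour).
Smoothing twice is an error; FWHM 0 is the identity. Both the
standardized and the unstandardized PerAF branch are carried through
smoothing, mirroring the sensitivity analysis in which the two branches
can disagree at the group level.

# Group inference

The design matrix holds intercept, group indicator (reverter-like = 1),
mean-centred mean FD, and $k-1$ site dummies. Continuous covariates are
centred (the analysed contrast is invariant to this, but centring keeps
the intercept interpretable); every site must contain both groups —
enforced with an error that points to `matchFilterCohort`, which applies
motion-QC and site-coverage exclusions and keeps a Figure-1-style
accounting log.

Per voxel, the OLS t statistic for the group contrast is formed, and the
subject-by-voxel residual matrix is retained. Smoothness is estimated from
the unit-normalised residuals: per axis, the mean squared difference λ
between adjacent in-mask voxels gives
$\mathrm{FWHM} = \sqrt{4\ln 2/\lambda}$ voxels (the standard
derivative-variance estimator). Resel counts use a cube of equivalent
volume as the search-region approximation —
$R_3 = V/\prod \mathrm{FWHM}_{vox}$, with the lower-dimensional terms from
the box formulas. On white noise smoothed with a known 6 mm kernel the
estimator recovers the FWHM within a few percent (tested at 20%
tolerance on a 48³ grid with 20 volumes — a desk-scale choice of problem
size); on unsmoothed white noise it returns a value on the voxel scale.

Cluster-level correction follows the classical Gaussian-random-field
formulas at a Gaussianized threshold: the t map is thresholded at the
t quantile of the per-tail voxel p (p/2 per tail when two-tailed, the
DPABI reading of "two-tailed voxel p < 0.05"), clusters are formed with
26-connectivity (configurable to 18/6), and each cluster of size $k$
receives

$$p_{corr} = 1 - \exp\!\big(-E_m \, e^{-\beta k^{2/3}}\big), \qquad
\beta = \Big(\Gamma(5/2)\,\frac{E_m}{E_N}\Big)^{2/3},$$

with $E_N = S\,\Phi(-u)$ expected suprathreshold voxels and $E_m$ the
expected cluster count from the full expected-Euler-characteristic
expansion $\sum_d R_d\,\rho_d(u)$ over resel dimensions 0–3. Including
the lower-dimensional (boundary) terms measurably improves null
calibration on desk-scale masks compared with the 3D term alone; with
them, the family-wise rate of ≥1 surviving cluster on null cohorts sits
in the lower half of the nominal band (the correction is conservative at
liberal cluster-forming thresholds and ~1.5-voxel smoothness, a
well-known property of random-field theory in this regime). Positive and
negative excursion sets are processed separately and reported with their
sign, as signed cluster tables. Peak coordinates are reported both on the
grid (1-based) and in signed mm via the diagonal affine with origin at
the grid centre.

Permutation/TFCE inference, voxelwise FDR maps, anatomical labelling and
the splitting of mixed-sign clusters beyond sign separation are
deliberately out of scope.

# Behavioral statistics

* `pooledTwoSampleT` accepts raw vectors or (n, mean, SD) summaries —
  printed demographic tables are usable directly — and uses the pooled
  (not Welch) variance, which is the convention that reproduces published
  demographic p values from rounded summaries.
* `chiSquareIndependence` is Pearson's chi-square *without* Yates
  continuity correction, again the convention matching published 2×2
  sex-distribution p values.
* `partialCorrelation` correlates OLS residuals (factors expanded to
  dummies), $df = n - 2 - \#\mathrm{covariates}$; it reduces to Pearson r
  with no covariates and matches the closed-form recursion (tested to
  1e-10).
* `bhFdr` is Benjamini–Hochberg step-up (via `p.adjust`), validated
  against a brute-force maximal-k oracle.
* `classifyReverter` implements the reversion rule: first-visit LM below
  the education-stratified cutoff, some later visit with LM at/above the
  cutoff **and** MMSE strictly greater than 24, earliest qualifying visit
  returned, missing-score visits skipped and counted. The LM cutoffs are
  deliberately *required configuration*: the education-adjusted values
  are external convention, not printed in the analysis this package
  models, and hard-coding a guess would be worse than demanding one.
* `clusterScoreCorrelations` pairs each surviving cluster with each score
  column using the *mean* of the (standardized, smoothed) metric inside
  the cluster mask — mean rather than peak, configurable by supplying a
  different summary upstream; missing scores are dropped pairwise. The
  default covariate set is site; age/sex/education can be added for the
  extended sensitivity analysis.

The behavioral-score generator ties scores linearly to a per-subject
effect magnitude. Two magnitudes are meaningful: the *planted* multiplier
(ground truth; useful for slope-0 null checks) and the *measured*
cluster-mean metric (what the correlation stage actually sees). With zero
score noise the partial correlation against the measured cluster mean is
exactly 1 — the property the pipeline's correlate stage is tested
against.

# Numerical choices and degenerate inputs

* Ideal filter edges are inclusive; the DC bin is always removed.
* `glmTwoSampleT` defines t = 0 where the standard error is exactly zero
  (identical maps in both groups), keeping the map finite.
* Zero-variance voxels in DC correlate with nothing and receive DC 0.
* ReHo W is clipped into [0, 1] at floating tolerance.
* The smoothness estimator refuses constant residual fields; cluster
  inference returns an *empty table* (not an error) when nothing is
  suprathreshold.
* All seeds derive from one root via `substreamSeed` (31-based string
  hash modulo 2³¹−1), keeping every derived seed a valid R integer.

# Problem sizes used by the test and acceptance runs

Desk-scale sizes keep the whole suite fast while preserving the regimes
that matter: metric oracles on a 6×6×6×40 volume; null calibration on 200
cohorts of 10+10 subjects, 16³ grid, 60 volumes; planted-effect recovery
on 20 cohorts of 15+15 subjects, 18³ grid, 90 volumes, amplitude ratio
1.5, noise SD 10 (the generator's default "moderate" level); smoothness
recovery on a 48³ grid. The full acquisition presets (197 and 976
volumes) remain available through `cohortSpec`.

# Known limitations

* GRF cluster p values are approximate at liberal cluster-forming
  thresholds and low smoothness; the implementation reproduces the
  classical formulas (the convention of the volumetric toolboxes) rather
  than attempting exact small-sample inference, and its measured
  family-wise rate on null cohorts is conservative within the nominal
  band.
* The box-equivalent resel approximation ignores the true mask shape's
  surface geometry; for the near-box masks used here the effect is small.
* Smoothness is estimated from the same residuals the GLM produces — an
  approximation shared with standard practice.
* The synthetic cohort's noise is spatially white; real fMRI noise is
  spatially autocorrelated and non-Gaussian, so calibration results here
  validate the implementation, not the method's behaviour on acquired
  data.
* PerAF's mean-restoration convention assumes the upstream intensity
  scale is positive; data already mean-removed by an external tool would
  need the mean supplied separately.
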