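---
title: "Models and methods behind lamina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lamina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lamina)
```

`lamina` packages the analysis chain used to ask how emotional-valence
signals reach primary visual cortex: block-design fMRI of face viewing in
three expression conditions (fearful, neutral, happy), residual inter-area
correlation analysis to locate the source of the valence effect,
cerebral-blood-volume (VASO) imaging to resolve it across cortical depth,
and a Bayesian multilevel model to quantify evidence per region, depth, or
eccentricity bin. Because the raw human data live in an external archive,
the package ships a seeded synthetic generator that reproduces the
statistical structure each stage assumes, so the full chain is exercised
and tested end to end on data whose ground truth is known.

## The synthetic study

`make_block_design()` reproduces the three protocols: 20 s face blocks with
10 s fixations at 3T (run length 280 s, TR 2 s), 18 s/9 s at 7T (252 s,
TR 1.5 s), and 19.3 s/9.65 s for 7T VASO. Condition order is a seeded
permutation of the fixed per-condition block counts; the randomization
scheme is our choice since only the counts and durations are fixed by the
protocol. For the VASO variant the block arithmetic gives
18 × 19.3 + 19 × 9.65 = 530.75 s, which is exactly 110 interleaved pairs at
the effective volume TR of 4.825 s (2.088 s blood-nulled + 2.737 s
not-nulled readouts); we use this value throughout.

`simulate_bold_runs()` treats each ROI as a shift-invariant linear system:
condition boxcars convolved with a canonical double-gamma HRF (peak near
5 s, undershoot near 15 s, 1:6 undershoot ratio, unit net area), scaled by
per-(ROI, condition) amplitudes in percent signal change. Intrinsic
fluctuations are modelled as (i) a unit-variance AR(1) latent process per
condition, *gated to the epochs of that condition* (each face block plus
its following fixation block) and loaded onto ROIs with configurable
couplings, and (ii) independent AR(1) noise per ROI with innovation
standard deviation `noise_sd` (marginal variance `noise_sd^2/(1-phi^2)`).
The epoch gating mirrors exactly the epochs on which the correlation
analysis operates; two ROIs with loadings `c1, c2` then share a planted
epoch correlation `c1*c2 / sqrt((c1^2+v)(c2^2+v))` with `v` the noise
variance — the closed form the tests check. Defaults plant the study's
qualitative structure: every area responds to faces (weaker in the
amygdala), expressive faces respond more than neutral, and a
fearful-specific shared fluctuation links the amygdala with cortex.

`simulate_vaso_run()` generates the interleaved pair on a cortical slab:
the not-nulled series carries a multiplicative BOLD-like response
`b(t) = 1 + a * r(t)` (default `a` = 1%), the nulled series is
`b(t) * (1 - v(x, t))` with `v` the CBV response whose depth profile is set
by band tables: by default a 2% mid-depth (0.35–0.65) peak for all
conditions — the stimulus-driven response — plus a superficial-only
(depth > 2/3) increment of 0.8% for fearful and 0.4% for happy faces, the
feedback signature. Frame times are staggered within each pair as in the
acquisition. What the generator deliberately omits: draining-vein
biophysics, physiological noise, motion, inversion-recovery physics.
Passing tests therefore demonstrate the *analysis code* recovers what it
assumes, not that real tissue obeys those assumptions.

`make_ribbon_and_eccentricity()` builds a flat slab (WM boundary row, gray
tiers, CSF boundary row) and a monotone eccentricity map from 0.5 out to
88 degrees; real cortical folding and retinotopy are out of scope, which is
why the depth operations are checked against brute-force distance oracles
rather than against anatomy.

## GLM and deconvolution

`build_design_matrix()` offers the canonical basis (one HRF-convolved
regressor per condition) and an FIR basis (one delta regressor per
condition and lag). Nuisance terms are a constant and a linear drift only;
high-pass filtering belongs to preprocessing, which is outside the package
scope. The FIR window for deconvolution defaults to the design's
block period (face block plus fixation: 30 s at 3T, 27 s at 7T) and is
configurable; on strictly periodic timing a longer window makes the FIR
system structurally unidentifiable (every frame would be explained by
two overlapping lag regressors plus the nuisance terms), and such
systems are rejected rather than silently fitted. With the short
fixation blocks of these protocols, responses deliberately overlap
between blocks and the least-squares inversion of the full FIR system is
what disentangles them. `fit_glm()` is plain OLS via QR with exact
`y = yhat + residual` bookkeeping; rank deficiency is an error, not a
silent drop. Residuals from `deconvolve_evoked()` are the inputs to the
correlation analysis, which makes those correlations invariant (to
numerical precision) to any design-spanned evoked component — a property
the tests assert directly.

## VASO processing

The interleaved series is split by parity (`split_interleaved()`, with a
`nulled_first` flag), each group cubic-spline interpolated onto a common
uniform grid at half the effective TR, and two frames trimmed at each end
(`align_and_trim()`). The upsampling target is our choice — the procedure
is stated as "upsampled" without a factor — and half the effective TR is
the coarsest grid that represents both groups without aliasing their
stagger. `bold_correct()` divides nulled by not-nulled frame-wise,
cancelling any multiplicative BOLD component exactly, flips the sign so
CBV increases are positive, and expresses the result as percent change
against the fixation-epoch baseline (the baseline definition is ours; the
fixation epochs are the only frames without a planted response).
Nonpositive not-nulled values abort rather than clip: silent clipping
would corrupt exactly the depth profiles the analysis is about. The
"VASO anatomy" (T1-EPI) contrast is `(1/sd)/mean` per voxel across all
frames of both groups; because the source phrasing admits a second
reading, the tSNR-style `mean/sd` is available behind a switch rather
than silently chosen.

## Layering

Depths are grown with the *equidistant* metric: per gray-matter voxel, the
Euclidean distances (within the axial slice) to the nearest WM and CSF
boundary voxels give `depth_fraction = d_wm/(d_wm + d_csf)`, binned into
K = 21 half-open bins (last bin closed). No curvature (equivolume)
correction is applied; the synthetic slabs are flat, and the metric is a
config point for anyone replacing the stand-in ribbons with real
segmentations. K = 21 oversamples the cortical thickness deliberately: the
bins are a visualization grid, not independent measurements, which is why
cross-layer inference goes through the spline stage. Profile extraction
follows the peak-R² convention: the axial slice with the highest mean R² in
the ROI, plus the slice above and below, averaged per bin.
`smooth_profile()` fits a thin-plate regression spline (via `mgcv`, which
is also what the original analysis used for this step) with weights
proportional to `1/SE²` and REML smoothness selection; the band is ±1
standard error of the fitted curve.

## Residual correlations and their tests

Per condition, residual samples from each face block through the end of
its following fixation block are concatenated across blocks and runs
(15 samples per block at 3T, 18 at 7T), correlated pairwise across ROIs
(Pearson by default, Spearman by flag), and averaged across sessions as
plain correlations (Fisher-z behind a flag, since the source describes
plain averaging). Baseline matrices are tested cell-wise against zero with
one-sided Wilcoxon signed-rank tests (zeros discarded); contrasts
(fearful − neutral, happy − neutral) with two-tailed one-sample t tests.
Bonferroni correction defaults to the number of tested cells — the stated
family ("number of ROIs") is ambiguous between ROIs and ROI pairs, so both
are supported and the stricter, more natural family is the default.

## The Bayesian multilevel model

Per response `y_crs` (condition c, region r, subject s — GLM betas in
percent signal change, or percent CBV per depth bin, or per eccentricity
bin):

    y_crs ~ T(b_c + xi_cs + eta_cr + gam_rs, nu, sigma^2)
    (xi_1s, ..., xi_Cs)' ~ N(0, Theta),  (eta_1r, ..., eta_Cr)' ~ N(0, Omega),
    gam_rs ~ N(0, lambda^2)

with priors: flat on `b_c`; jointly uniform (LKJ shape 1) on the
correlation parts of Theta and Omega; half-t(3, 0, 1) on `lambda` and on
the Theta/Omega standard deviations (the source states half-t(3,0,1) for
`lambda`; we adopt the same weakly-informative form for the other scale
parameters); Gamma(2, 0.1) on `nu`; half-Cauchy with scale `sd(y)` on
`sigma`. The same machinery serves C = 3 conditions × 15 regions and
C = 2 × 5 eccentricity bins. Inputs are betas only; a measurement-error
variant weighting by t-statistics is out of scope.

### Why a purpose-built sampler

The crossed varying-intercept structure has flat translation directions:
`b_c` trades off against the means of `xi_c.`, `eta_c.` and `gam..`.
Off-the-shelf single-site Gibbs samplers random-walk along these ridges
and, at the study's budget of 4 chains × 1000 iterations, fail the very
convergence bounds the analysis reports (we measured split R-hat of 2–3 on
`b_c` under both naive and hierarchically-centered formulations in JAGS,
the only general MCMC engine available to the package). `fit_bml()`
therefore uses a blocked Gibbs sampler written for this model:

* Student-t likelihood through its normal scale-mixture (per-observation
  Gamma weights), giving conjugate Gaussian draws for `b`, `xi`, `eta`,
  `gam` in blocks;
* exact recentering ("sweep") moves: the translation `b -> b + delta`,
  `xi -> xi - delta` leaves the likelihood invariant, and with a flat
  prior on `b` the conditional for `delta` is Gaussian
  (`N(mean_s(xi), Theta/S)`), so the flat direction is resampled exactly
  each sweep (similarly for `eta` and `gam`);
* partially collapsed slice updates: `nu` and `sigma` are updated against
  the *marginal* Student-t likelihood with the mixture weights integrated
  out, and `lambda` against the marginal with `gam` integrated out
  (rank-one Gaussian identities per cell), removing the remaining slow
  couplings; the collapsed latents are redrawn immediately afterwards,
  keeping the kernel exact;
* the LKJ(1) prior is realized exactly by the C-vine construction:
  canonical partial correlations with Beta(a, a) priors on (−1, 1),
  `a = 1 + (C − 1 − k)/2` at vine level k, updated by slice sampling on
  the atanh scale.

With these moves the population effects mix essentially independently
(effective sample sizes near the draw count), and the published bounds
(split R-hat < 1.05, ESS > 200) hold with a wide margin at 4 × 1000
iterations. "1000 iterations" is read as total per chain with the first
half discarded as warmup, since the warmup split is not stated in the
source; the choice is a documented default of `fit_bml()`. Chains are
seeded deterministically from the user seed, so fits are bit-reproducible.
An independent cross-check against a long JAGS run of the same model on a
small dataset is part of the test suite; JAGS is used there only as an
oracle, never as the fitting engine.

Convergence is always assessed — split R-hat and a Geyer-truncated
multi-chain effective sample size per parameter, over *all* sampled
parameters including the varying effects — and a violation warns loudly
while still returning the fit.

Derived quantities: `P+` is the fraction of draws strictly positive; the
valence modulation index is `(C1 − C2)/(|C1| + |C2|)` per draw, bounded in
[−1, 1], with the 0/0 case defined as 0 and counted. Posterior predictive
checks simulate replicate datasets from the posterior draws (varying
effects included) and locate the observed per-condition means within the
replicate distribution, plus per-observation predictive tail probabilities
for outlier flagging.

## ROI construction

R² thresholding is strict (`> 0.1` by default). Group-overlap masks keep
voxels present in at least `ceil(fraction × n)` subjects (one third by
default). Eccentricity bins are half-open with a closed outer edge at
88 degrees. The five-bin edges used by default,
`{0.5, 2, 2.5, 6, 20, 88}`, extend the published stimulus (0.5–2 deg) and
penumbra (2.5–6 deg) groups with a three-way split of the far periphery;
the exact five edges are not printed in the source and this default is an
assumption recorded in the configuration, not a reproduction. The central
V1 ROI cuts at 2 deg (the representation of a 4 × 6 deg foveal face), and
the peripheral ROI starts beyond a 0.5 deg guard band.

## Pipeline, problem sizes, and reproducibility

`run_end_to_end()` chains the stages and writes every table plus a JSON
index. The default problem sizes are deliberately small — 8 subjects × 2
runs for BOLD, 4 VASO subjects on an 8 × 12 × 5 slab upsampled ×4, 2
chains × 400 iterations for the in-pipeline multilevel fits — chosen so a
complete run takes about a minute while still recovering the planted
signatures; the test suite runs the diagnostics-critical fit at the full
4 × 1000 budget and the calibration study at 20 replicates. A single
global seed fans out to per-stage seeds through a counter scheme, so any
stage can be re-run in isolation without consuming another stage's random
stream, and re-running a config reproduces every output byte-for-byte,
MCMC included.

## Known limitations

* The synthetic data are far smoother than real laminar fMRI: no vascular
  bias gradient, no motion, no physiological noise. Recovery of the
  planted superficial effect shows correctness of the layering and
  contrast code, not robustness to those artifacts.
* The equidistant depth metric ignores curvature; on curved cortex an
  equivolume metric would reassign bins near crowns and fundi.
* The sampler is specialized to C ∈ {2, 3} crossed designs with one
  observation per cell; unbalanced or missing-cell designs are rejected
  rather than approximated.
* Session-level correlation averaging uses plain r by default to match the
  described procedure; Fisher-z averaging is available and preferable when
  correlations are large.
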