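# lamina

Laminar fMRI analysis of emotional-valence modulation in human visual
cortex.

Viewing emotionally expressive faces (fearful or happy, versus neutral)
enhances fMRI responses throughout visual cortex, including primary
visual cortex (V1) — the *valence effect*. Whether that modulation
reaches V1 through cortico-cortical feedback or through direct,
retinotopically diffuse projections from the amygdala has distinct
signatures: feedback from higher visual areas terminates in superficial
*and* deep layers and favors the fovea, while amygdala afferents
terminate only in superficial layers and are spread across the entire
retinotopic map. `lamina` implements the analysis chain that separates
these hypotheses, for researchers working with block-design BOLD and
VASO (vascular-space-occupancy, cerebral-blood-volume-weighted) fMRI:

* **Synthetic study generator** — seeded block designs for the three
  protocols (20 s/10 s blocks at 3T, 18 s/9 s at 7T BOLD, 19.3 s/9.65 s
  interleaved VASO), ROI time series that obey a shift-invariant linear
  response model with condition-gated shared latent fluctuations and
  AR(1) noise, interleaved blood-nulled/not-nulled voxel series on a
  cortical slab, and monotone eccentricity maps out to 88°.
* **GLM / deconvolution** — canonical double-gamma HRF regression and
  FIR deconvolution of mean evoked responses (overlapping blocks are
  inverted exactly), residual series, R².
* **Residual connectivity** — per-condition epoch extraction (each face
  block plus its following fixation), ROI×ROI correlation matrices,
  fearful−neutral / happy−neutral contrasts, Wilcoxon and one-sample
  t tests with Bonferroni correction.
* **VASO** — interleaved splitting, cubic temporal alignment, BOLD
  contamination removal by frame-wise division (×−1 sign convention),
  and the T1-EPI "VASO anatomy" contrast.
* **Laminar profiling** — in-plane ×4 upsampling, 21 equidistant
  cortical depths between the WM and CSF boundaries, depth profiles
  around the peak-R² slice, uncertainty-weighted thin-plate-spline
  smoothing.
* **Bayesian multilevel model (BML)** — the region-based model

      y_crs ~ T(b_c + ξ_cs + η_cr + γ_rs, ν, σ²)
      (ξ_1s,…,ξ_Cs)′ ~ N(0, Θ),  (η_1r,…,η_Cr)′ ~ N(0, Ω),  γ_rs ~ N(0, λ²)

  with LKJ(1) correlation priors, half-t(3,0,1) scales, Gamma(2, 0.1)
  on ν and a data-scaled half-Cauchy on σ, fitted by a purpose-built
  blocked Gibbs sampler with exact recentering moves (see the methods
  vignette for why off-the-shelf Gibbs fails this crossed design at the
  standard 4 × 1000 iteration budget). Outputs: posterior draws, split
  R-hat and effective sample size per parameter, P+, the valence
  modulation index (C1−C2)/(|C1|+|C2|), and posterior predictive checks.
* **ROI tools** — R² thresholding, group-overlap masks, eccentricity
  binning, stimulus-representation and peripheral-V1 ROIs.
* **Pipeline** — `run_end_to_end()` chains everything on synthetic data
  and writes the report tables plus a JSON index.

## Worked example

Fit the multilevel model to data simulated from itself at the benchmark
size (3 conditions × 15 regions × 15 subjects):

```r
library(lamina)
dat <- simulate_bml_data(C = 3, R = 15, S = 15, b = c(0.2, 0.5, 0.8),
                         lambda = 0.05, nu = 30, sigma = 0.1, seed = 11)
fit <- fit_bml(dat, chains = 4, iterations = 1000, seed = 3)
fit
#> <bml_fit> C=3 conditions, R=15 regions, S=15 subjects; 4 chains x 500 kept draws (29.6 s)
#>   max split R-hat 1.007, min ESS 356 (over 333 parameters)
```

The two diagnostic numbers are the study's convergence gates: split
R-hat below 1.05 and effective sample size above 200 for every sampled
parameter; here both hold with a wide margin, and the posterior means of
`b` recover the planted (0.2, 0.5, 0.8).

Run the whole pipeline on a small synthetic cohort:

```r
cfg <- pipeline_config(seed = 2, out_dir = "out", n_subjects = 4,
                       n_runs = 1, n_vaso_subjects = 2,
                       bml_chains = 2, bml_iterations = 300)
rep <- run_end_to_end(cfg)
rep$eccentricity_contrast
#>   region      mean      q2.5     q97.5    p_plus        contrast
#> 1   ecc1 0.2530113 0.1449433 0.3465342 0.9933333 fearful-neutral
#> 2   ecc2 0.2474897 0.1427595 0.3328922 0.9933333 fearful-neutral
#> 3   ecc3 0.2527421 0.1415068 0.3495125 0.9933333 fearful-neutral
#> 4   ecc4 0.2583635 0.1442365 0.3457193 0.9933333 fearful-neutral
#> 5   ecc5 0.2544213 0.1453455 0.3432160 0.9933333 fearful-neutral
```

The fearful−neutral contrast is credibly positive (P+ ≈ 0.99) and *flat*
across all five eccentricity bins — the planted additive,
retinotopically diffuse valence effect. The generator had planted a
0.25% additive increment at every eccentricity, and every bin's
posterior mean sits on it. Likewise `rep$depth_contrast` shows the
fearful−neutral CBV contrast confined to superficial depth bins (the
planted 0.8% increment at depth fraction > 2/3), and
`rep$correlation_tests` shows the fearful−neutral correlation contrast
concentrated in the amygdala cells.

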