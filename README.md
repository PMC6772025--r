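# cortexdti

Radial diffusivity analysis of the cerebral cortex from diffusion-tensor
MRI.

Cortical grey matter is built around a radial unit — the minicolumn, a
vertical string of neurons with its associated myelinated axon bundles —
and diffusion in the cortex is correspondingly biased toward the radial
axis. `cortexdti` turns that observation into quantitative per-region
markers. It is aimed at neuroimaging researchers who want
cytoarchitecture-sensitive cortical diffusion measures (for example to
track demyelinating or neurodegenerative change) and need a fully tested,
phantom-validated reference implementation of the estimator chain.

## What it computes

Per voxel, from the diffusion tensor eigensystem
(λ₁ ≥ λ₂ ≥ λ₃, principal diffusion direction **e₁**) and the local cortical
radial direction **r**:

- **AngleR** θ_R = arccos |**e₁** · **r**| ∈ [0, π/2] — the radiality
  angle (0 = perfectly radial diffusion);
- **ParlPD** = λ₁ cos θ_R and **PerpPD** = λ₁ sin θ_R — projections of the
  principal diffusion component onto the radial axis and onto the
  tangential plane (ParlPD² + PerpPD² = λ₁²);
- **FA** and **MD**, the standard tensor summaries.

The radial direction is the normalised gradient of a Laplace potential
solved between the white-matter and pial boundaries of the cortical
ribbon; metrics are averaged along cortical profiles (streamlines of that
field, mimicking the columnar organisation) and then over ROI profiles,
excluding each ROI's terminal slices. A cohort layer provides Spearman
correlation screens with joint step-up FDR adjustment, partial
correlations controlling for age, paired t tests, and split-plot
repeated-measures ANOVA (diagnosis × region). A synthetic phantom module —
slab or spherical-annulus cortex, Watson-dispersed radial tensor fields,
Rician noise, planted-correlation cohorts — supplies ground truth for
every stage.

## Worked example

Simulate a slab phantom with moderate orientation dispersion (Watson
κ = 10) at the postmortem acquisition's SNR, run the full chain, and
summarise the cortex ROI:

```r
library(cortexdti)

spec <- phantom_spec(geometry = "flat_slab", grid_shape = c(24, 24, 20),
                     cortex_thickness = 8, dispersion_kappa = 10,
                     snr = 66.9, seed = 7)
ph  <- make_phantom(spec)
dwi <- synthesize_dwi(ph$tensors, default_scheme(), s0 = 1000,
                      snr = spec$snr, seed = 7)
fit <- fit_tensor_loglinear(dwi)
eig <- eigendecompose(fit)
pot <- solve_cortical_potential(ph$truth$labels, ph$tensors$affine)
fld <- radial_field(pot, ph$truth$labels)
prof <- trace_profiles(fld, pot, ph$truth$labels)
met <- compute_cortical_metrics(eig, fld)
roi <- roi_definition(ph$tensors$mask, "slab", axis = 2)
roi_summarize(met, prof, roi, subject = "phantom01")
#>     subject region angleR_rad perpPD parlPD    FA     MD n_profiles n_voxels
#> 1 phantom01   slab     0.3051  0.236 0.7515 0.706 0.3998        528     4224

watson_mean_angle(10)   # analytic expectation for kappa = 10
#> [1] 0.299
```

The recovered ROI mean AngleR (0.305 rad) sits on the analytic Watson
expectation for the planted dispersion; diffusivities are reported in
10⁻³ mm²/s (MD 0.4 = the phantom's mean eigenvalue), and FA matches the
planted (0.8, 0.2, 0.2)×10⁻³ eigenvalue triple. `run_pipeline()` wraps the
same chain with NIfTI/CSV outputs, config snapshots and seed logging, and
`inst/cli/cortexdti` exposes `simulate` / `stats` / `run-all` subcommands.

For cohort statistics, a bundled 90-test reference screen (five diffusion
metrics × six histology measures × three regions from a postmortem
multiple-sclerosis cortex study) provides the worked example for the FDR
arithmetic:

```r
scr <- reference_screen()
adj <- fdr_adjust(scr$p)
head(cbind(scr[, 1:3], p = scr$p, p_fdr = round(adj, 4)), 4)
#>   region metric           histology     p p_fdr
#> 1    BA9 AngleR    minicolumn_width 0.001 0.030
#> 2    BA9 AngleR    neuropil_spacing 0.024 0.240
#> 3    BA9 AngleR          core_width 0.002 0.045
#> 4    BA9 AngleR microsegment_number 0.056 0.336
```

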