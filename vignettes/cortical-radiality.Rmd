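---
title: "Radial diffusivity analysis of the cortex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial diffusivity analysis of the cortex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexdti)
```

## The model

The cerebral cortex is organised radially: minicolumns — vertical strings of
neurons with their dendrites and descending myelinated axon bundles — run
from the white-matter boundary toward the pial surface. Water diffusion in
cortical grey matter is weakly anisotropic, and its principal direction
tends to align with this radial axis. `cortexdti` quantifies that alignment
from a diffusion tensor fit, so that disruptions of columnar organisation
(as in multiple sclerosis and other disorders) can be read out from MRI.

Per voxel, with diffusion tensor eigensystem
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ and principal diffusion direction
(PDD) $\mathbf{e}_1$, and with $\mathbf{r}$ the local radial unit vector:

* **AngleR** $\theta_R = \arccos\,|\mathbf{e}_1 \cdot \mathbf{r}| \in
  [0, \pi/2]$ — the radiality angle. Both $\mathbf{e}_1$ and $\mathbf{r}$
  are axes (defined up to sign), so the absolute value makes every quantity
  antipodally invariant; this is asserted bit-exactly in the tests.
* **ParlPD** $= \lambda_1 \cos\theta_R$ and **PerpPD**
  $= \lambda_1 \sin\theta_R$ — projections of the principal diffusion
  component $\lambda_1 \mathbf{e}_1$ onto the radial axis and the tangential
  plane. By construction $\mathrm{ParlPD}^2 + \mathrm{PerpPD}^2 =
  \lambda_1^2$.
* **FA** and **MD** — the standard eigenvalue summaries.

Voxel metrics are averaged along *cortical profiles* — streamlines following
the radial direction across the ribbon, mimicking the columnar geometry —
and then over profiles within a region-of-interest (ROI), excluding the
first and last slice of the ROI's slice range where coverage is partial.
Diffusivities are reported in units of $10^{-3}\,\mathrm{mm^2/s}$; angles in
radians.

## Radial geometry via the Laplace equation

The radial direction field is defined as the normalised gradient of a
harmonic potential: $\nabla^2 \varphi = 0$ on cortex voxels, with
$\varphi = 0$ on the white-matter interface and $\varphi = 1$ on the pial
interface. This is the standard curvature-respecting construction for
"lines within the cortex in a radial direction"; its level sets interpolate
smoothly between the two boundary surfaces however the ribbon bends.

Numerical choices:

* 6-connected discrete Laplacian, Gauss–Seidel relaxation, stopping when the
  largest per-sweep update falls below `tol` (default `1e-6`, `max_iter`
  `1e4`). Non-convergence is an error, never a silent result.
* Dirichlet conditions sit on the **voxel faces** between cortex and
  boundary tissue, folded in as ghost values. On a flat slab this yields the
  exact linear solution $\varphi(z) = z/T$; on a spherical annulus with
  inner radius $a$ and outer radius $b$ it reproduces
  $\varphi(r) = (1/a - 1/r)/(1/a - 1/b)$ without any effective-radius
  offset.
* A voxelised (staircase) sphere cannot represent the smooth boundary
  surface: whatever the discretisation, the local solution in the one or two
  voxel shells adjacent to each boundary deviates from the analytic one by
  up to a few times $10^{-2}$ in potential and several degrees in direction
  at 1 mm resolution (the staircase displaces the boundary by up to half a
  voxel against a total potential drop spread over the ~10-voxel thickness).
  Accuracy statements are therefore made on the **ribbon interior** (cortex
  voxels at least two voxels from both boundaries), where the measured
  deviation on the 48³ annulus phantom is below $10^{-2}$ in potential and
  below 2° in direction. The boundary shells are retained in the maps; they
  enter profile averages as a minority of samples and do not bias ROI means
  appreciably (the end-to-end zero-dispersion phantom yields ROI AngleR
  below 0.02 rad including them).
* Profiles are seeded at every cortex voxel with a white-matter 6-neighbour
  and integrated by fixed-step Euler (step = ¼ voxel) through the
  trilinearly interpolated field, terminating on leaving the cortex, on
  non-increasing potential, or at a maximum length of four nominal
  thicknesses (thickness estimated as the median of $1/|\nabla\varphi|$
  over the ribbon interior). Profiles shorter than two samples are
  discarded and counted.
* Metric sampling along profiles is nearest-voxel by default — each metric
  is defined per voxel, and each sampled voxel contributes its computed
  value — with trilinear interpolation available. Profile means are
  unweighted arithmetic means; ROI means are unweighted means over profiles.

## Tensor model

The tensor is fitted by ordinary log-linear least squares,
$\log S = \log S_0 - b\, \mathbf{g}^\top D \mathbf{g}$, solved per voxel for
the seven unknowns. The fit is deterministic and recovers noiseless
single-tensor signals to relative error below $10^{-8}$ (tested); a
weighted or robust fit is deliberately out of scope at these SNR levels.
Non-positive diffusion-weighted signals are floored at
$10^{-6} \cdot S_0$ and flagged; fitted tensors that are not positive
definite are flagged but never repaired — transparency over silent
clipping. Voxels with $\lambda_1 \approx \lambda_2$ (relative gap below
$10^{-6}$) have an undefined PDD and are excluded from angle averages.

## The synthetic phantom

Because the analysis was developed for postmortem MRI with destructive
histology — data that cannot be redistributed — validation rests on a
synthetic phantom whose ground truth is analytic:

* **Geometry**: a flat slab (radial axis = slab normal) or a spherical
  annulus (radial axis = outward radius), defaulting to a 48³ grid at 1 mm
  isotropic resolution (the acquisition's 0.94 mm rounded) with a 10 mm
  cortical ribbon.
* **Orientations**: per-voxel principal axes drawn from a Watson-type axial
  distribution about the true radial direction, density
  $\propto \exp(\kappa (\boldsymbol{\mu} \cdot \mathbf{u})^2)$, sampled by
  rejection (exact for all $\kappa \ge 0$). $\kappa = \infty$ gives perfect
  radial alignment; $\kappa = 0$ gives uniformly random axes, for which the
  expected AngleR is exactly 1 radian
  ($\int_0^1 \arccos(c)\,dc = 1$) — a closed-form oracle used in the
  acceptance tests. `watson_mean_angle()` gives the expectation for any
  $\kappa$ by quadrature.
* **Tangential layer**: an optional fractional-depth band whose orientations
  are exactly tangential, emulating a mid-depth myelinated stria such as the
  stria of Gennari in primary visual cortex (true AngleR = $\pi/2$ there).
* **Signal**: $S = S_0 \exp(-b\,\mathbf{g}^\top D \mathbf{g})$ under a
  deterministic 54-direction $b = 4500\,\mathrm{s/mm^2}$ shell with six
  $b = 0$ volumes (golden-angle sphere covering), with Rician noise — the
  magnitude of the complex signal after adding Gaussian noise of
  sd $= S_0/\mathrm{snr}$ to both channels. The default SNR of 66.9 matches
  the $b=0$ signal-to-noise of a long postmortem acquisition. Default
  eigenvalues $(0.8, 0.2, 0.2)\times 10^{-3}\,\mathrm{mm^2/s}$ give MD
  $0.4\times10^{-3}$, in the fixed-tissue range.
* Seeds are explicit fields of every specification object and are recorded
  in run logs; no function touches the caller's RNG state.

What the phantom does **not** emulate: gyral folding beyond slab/annulus,
partial-volume and CSF contamination, spatially varying $S_0$ or
eigenvalues, fixation gradients, and histological images themselves. Passing
tests therefore demonstrate correctness of the estimator chain under the
stated geometric and noise model, not robustness to every property of real
postmortem data.

## The synthetic cohort

The cohort generator plants a known monotone structure so the statistical
stage can be validated end to end: each subject carries one dispersion
parameter $\kappa$ drawn from a per-group normal model (cases lower —
more orientation scatter), and each histology measure is a linear function
of $\kappa$ plus Gaussian noise. `noise_sd_for_spearman()` converts a
target population Spearman correlation into the required noise level via
the Gaussian rank-correlation relation $\rho_P = 2\sin(\pi\rho_S/6)$.
`add_planted_diffusion()` derives region-wise diffusion metrics from each
subject's $\kappa$ through `watson_mean_angle()`, so the 90-test
correlation screen runs without imaging every subject. Default group sizes
are 9 cases and 6 controls — the study scale — with ages near 72 and
disease duration (cases only) increasing with age.

## Statistics

* **Spearman correlations** use average ranks and the two-sided
  $t$-approximation on $n-2$ degrees of freedom ($|r| = 1 \Rightarrow
  p = 0$); exact permutation p-values are not attempted at these $n$.
* **The correlation screen** runs 5 diffusion metrics × 6 histology measures
  × 3 regions = 90 tests with a **single joint step-up FDR adjustment**
  (Benjamini–Hochberg: rank, scale by $n/\mathrm{rank}$, cumulative minimum
  from the largest rank, cap at 1). A published 90-test screen is bundled
  (`reference_screen()`) as a worked example; the step-up adjustment
  reproduces its printed adjusted column at 89 of 90 entries to within
  5×10⁻⁴, and the tests document that the one remaining printed entry is
  internally inconsistent (it equals $n \cdot p/\mathrm{rank}$ without the
  monotonicity step and is non-monotone against neighbouring entries).
* **Partial correlations** controlling a single covariate (age) use the
  first-order recursion formula with $t$ on $n-3$ df; Pearson-based by
  default with a Spearman option, since the convention differs between
  software packages.
* **Group × region comparisons** use the split-plot repeated-measures
  ANOVA: diagnosis tested against subjects-within-group
  ($\mathrm{df} = (g-1,\, N-g)$; (1, 13) at 9+6 subjects), region and the
  interaction against the region × subject residual
  ($(r-1,\,(r-1)(N-g))$; (2, 26) at 3 regions). No sphericity correction is
  applied by default — matching the uncorrected dfs convention — with
  Greenhouse–Geisser available as an option.
* Zero-variance inputs (constant vectors, all-equal designs, paired
  differences that are a pure constant shift) raise errors rather than
  returning infinite statistics.

## Problem sizes and determinism

Validation runs use desk-scale problems chosen to make every oracle sharp:
48³ annulus and 24×24×20–36×36×24 slab phantoms (≥10⁴ cortical voxels where
the uniform-axis closed form is asserted), 500 replicates for sign recovery
of a planted $\rho_S = 0.9$ at $n = 9$, and 200 replicates for the ANOVA
type-I rate, which is checked against the band [0.03, 0.07] at
$\alpha = 0.05$. That band spans roughly ±1.3 binomial standard deviations
at 200 replicates, so it is a coarse screen rather than a sharp test; the
split-plot F statistic is exactly F-distributed under the null, and the
textbook sums-of-squares oracle is asserted to 10⁻¹⁰ separately. Every
pipeline run writes a config snapshot, seeds, solver iteration counts and
per-stage profile counts to its log, and reruns with identical
configuration are bit-identical.

## Known limitations

* Radial accuracy degrades in the boundary voxel shells (see above); at
  much coarser resolution or thinner ribbons (< ~5 voxels) the interior
  margin disappears and profile averages inherit boundary noise.
* The log-linear fit is unweighted; at very low SNR its noise floor differs
  from weighted estimators.
* Profiles are averaged without arc-length weighting; depth-resolved
  (laminar) output is not produced.
* The empirical correlation values and group means of the original
  postmortem study depend on unpublished specimen data and are not
  reproduced here; the analytic and planted-truth oracles above substitute
  for them.
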