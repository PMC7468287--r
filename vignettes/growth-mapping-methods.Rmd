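---
title: "Deformation-based mapping of perisylvian cortical growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based mapping of perisylvian cortical growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific problem

During the second and third trimesters the frontal, parietal and temporal
opercula overgrow the insula and close over it, forming the Sylvian
fissure. Two complementary observations characterize this process:

1. **Morphometry.** Week-to-week diffeomorphic registration of a
   longitudinal fetal brain atlas yields displacement fields whose Jacobian
   determinants localize the highest rates of organized growth to the
   opercula, while the insula itself grows least — the opercula close over
   a relatively static insular floor.
2. **Transcriptomics.** In prenatal laser-microdissection microarray data,
   ranking genes by opercular-versus-insular fold change within each
   transient cortical layer (subpial granular zone SG, marginal zone MZ,
   cortical plate CP, subplate SP) and keeping the 99.9th percentile
   isolates a small set of strongly overexpressed genes per layer.

`morphogrowth` implements both arms end to end, with a synthetic phantom
generator and a planted-signal expression generator providing ground truth
that the real data cannot: every estimate the package produces can be
scored against a known answer.

## Morphometry arm

### Deformation model and direction convention

For a displacement field $u$ the transformation is $\varphi(x) = x + u(x)$
and the local volume-change factor is the Jacobian determinant

$$ J(x) = \det\!\left( I + \frac{\partial u}{\partial x} \right), $$

computed with central finite differences in physical millimetres
(one-sided at the grid boundary; boundary voxels are excluded from all
summary statistics). We register the **later** week (moving) onto the
**earlier** week (fixed), so the recovered field maps week-$k$ coordinates
forward to week $k{+}1$ and growth reads directly as $J > 1$. Working in
physical coordinates makes $J$ invariant to voxel anisotropy.

### Normalization and absolute growth

Raw $J$ confounds local shape change with global volume increase. We
divide by a scalar global ratio $R$:

* `normalization = "mask_volume"` (default): $R$ is the target/source
  object-mask volume ratio in mm³;
* `normalization = "jacobian_mean"`: $R$ is the mean raw $J$ over the
  source mask — a useful cross-check, since the two agree on a perfectly
  estimated field (volume conservation of the Jacobian).

A normalized Jacobian below 1 does **not** mean shrinkage: with global
growth fraction $g$, the absolute local growth percentage is

$$ \big( J_{\text{norm}} \, (1+g) - 1 \big) \times 100 . $$

For example $J_{\text{norm}} = 0.95$ under 9 % global growth is still
$+3.5\%$ absolute growth. `absolute_growth()` implements this, snapping
the percentage to 12 significant digits before decimal rounding: the
subtraction amplifies binary floating-point representation noise (3.55
computes as 3.5500000000000009), which would otherwise flip exact decimal
ties upward when reporting at one decimal.

### Registration

`diffeo_register()` is a stationary-velocity log-demons method:

* **Force.** Classic demons intensity force from the warped-moving image
  gradient, $\delta = r \, G / (\lVert G\rVert^2 + r^2/\kappa^2)$ with
  residual $r$ and $\kappa$ the mean voxel size.
* **Regularization.** The update is smoothed with a Gaussian
  ($\sigma_{\text{update}} = 2.5$ voxels), accumulated into the velocity,
  and the velocity is smoothed again ($\sigma_{\text{velocity}} = 1.5$
  voxels). A monotone accept/halve step rule makes the per-level MSE trace
  non-increasing by construction.
* **Diffeomorphy.** The velocity is exponentiated by scaling and squaring
  (≥ 6 squarings, more if the maximum step demands it); the returned field
  is rejected with an error if its Jacobian is anywhere non-positive.
* **Pyramid.** Coarse-to-fine with ×2 anti-aliased downsampling and a
  16-voxel floor per axis: on the phantom, a 12³ level actively *degraded*
  recovery (too few voxels span the opercular features), so very coarse
  levels are never built.
* **Symmetry.** The decisive quality choice: the velocity is estimated in
  both directions and antisymmetrized, $v = (v_{\text{fwd}} -
  v_{\text{bwd}})/2$, in the spirit of symmetric normalization (SyN).
  On the default phantom this raised the Jacobian correlation with ground
  truth from ≈ 0.80 to ≈ 0.88.

The defaults (iterations 200/100/60, tolerance $10^{-7}$) were calibrated
against the phantom's ground-truth field, not against any particular
test threshold: with narrower update smoothing ($\sigma_{\text{update}} =
1$ voxel) and shorter schedules the recovered Jacobian correlated only
0.70 with the truth, which is below what a method claiming to map growth
patterns should deliver. Measured at defaults on the 48³ phantom pair:
Jacobian correlation 0.88–0.89, MSE reduction ≈ 86 %, macro Dice ≈ 0.94.

An affine pre-alignment stage (`affine_register()`, 12 parameters, BFGS
with analytic gradients on the same pyramid) is available for inputs that
are not already in a common space; the phantom weeks share a grid, so the
pipeline default is `run_affine = FALSE`. When enabled, the Jacobian
measures only the residual nonlinear shape change.

### Validation

`validate_registration()` warps the later week's segmentation back through
the recovered field (nearest-neighbour) and scores it against the earlier
week's with multiclass Dice. The macro score is the unweighted mean over
foreground labels present in either input; background is excluded because
its overlap would inflate scores meaninglessly. A voxel-weighted variant
is reported alongside.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds an ellipsoidal hemisphere with a lateral wedge
indentation (the open Sylvian fissure), insula at the wedge floor, and
frontal/parietal/temporal opercular shell regions. Week-to-week change is
an **analytic stationary velocity field** composed of

* uniform radial expansion calibrated so one week of flow multiplies
  volume by $1 + g$ (default $g = 0.06$/week): $a = \log(1+g)/3$;
* excess opercular expansion (default +3 %/week) confined to the shell by
  smooth sigmoidal weights; and
* a convergence term that moves opercular lips toward the fissure plane,
  $-A\,\mathrm{sign}(\delta z)\, (s/s_0) e^{1 - s/s_0}$ with $s_0 = 4$ mm,
  emulating opercularization.

Week $k$ is rendered by evaluating the analytic week-0 intensity and label
functions at $\exp(-k v)$-mapped points — there is **no cumulative
resampling**, so every week is sampled directly from the continuous model
and the pairwise ground-truth field $\exp(v)$ is exact to the grid. The
intensity model has soft (~1.5 mm, partial-volume-like) boundaries, a
bright cortical ribbon, and a fixed smooth sinusoidal texture
(wavelength ≈ 8 mm) that moves with the anatomy.

Two generator choices deserve explanation because they were revised during
development, both calibrated against the **ground-truth field as oracle**
(never against the registration output):

* **Texture and soft edges.** An early draft had hard binary edges and a
  flat interior; even warping with the *true* field then left ~45 % of the
  MSE (interpolation residuals at the step edge), and a registration has
  no interior evidence to recover growth from. The intensity model exists
  to give registration gradients, so it must carry information where the
  deformation acts.
* **Noise level.** `noise_sd = 0.002`. The emulated inputs are multi-
  subject average atlas templates, which are essentially noise-free; the
  term exists to avoid degenerate exact-arithmetic behaviour, not to model
  scanner noise. At `noise_sd = 0.02` the ground-truth field itself could
  only explain 55 % of the MSE — i.e. the generator, not the method, would
  make an 80 % reduction unattainable.

The phantom is **not** a folding simulation: no gyrification, no
differential-tension mechanics, no realistic cortical geometry. It plants
exactly the properties the analysis claims to measure — known global
growth, known regional ordering (opercula > insula), a known closing
fissure — so that estimates can be scored.

Weeks are indexed abstractly (0 … n_weeks−1); mapping to gestational
weeks is metadata the user supplies.

## Transcriptome arm

`generate_expression()` emulates a two-specimen LMD microarray profile:
35,000 genes × 2 specimens × 11 structures (9 opercular targets, 2 insular
contrasts) × 4 layers, log-normal baselines with per-sample log-noise, and
40 planted genes per layer whose target-region values are multiplied by a
fold drawn from [15, 40].

The contrast (`contrast_report()`) proceeds per layer:

1. **Aggregation**: unweighted arithmetic mean on the linear intensity
   scale across specimens and constituent structures, separately for the
   target and contrast sets. (Microarray pipelines differ in how they pool
   replicates; the linear mean is the simplest auditable choice and is a
   named pipeline setting.)
2. **Fold change**: $(\bar t + \varepsilon)/(\bar c + \varepsilon)$ with
   pseudocount $\varepsilon = 0.5$ guarding against zero contrast means.
3. **Selection**: *rank-based* percentile semantics — the 99.9th
   percentile of $G$ genes keeps the $\max(1, \mathrm{round}(G \times
   0.001))$ largest folds, which for 35,000 genes is exactly the top 35.
   Boundary ties break lexicographically by gene id (deterministic);
   reported ranks are dense in the fold value.

Published per-layer cutoff magnitudes and gene identities depend on the
source database's own normalization and are not reproducible from
synthetic data; what the package tests instead is the *machinery*: exact
selection counts, planted-signal recovery (≥ 90 % of selected SG genes are
planted at default settings; in practice 100 %), and null behaviour
(no planted signal ⇒ median fold ≈ 1).

## Pipeline and reproducibility

`run_growth_pipeline()` and `run_contrast_pipeline()` drive both arms from
one `pipeline_config()` (or YAML file via `read_pipeline_config()`). Every
convention the analysis depends on but for which no single community
standard exists is an explicit, logged config key: normalization mode,
field direction, pseudocount,
percentile rule, tie-break. Each run writes a JSON manifest listing every
artifact with its MD5 checksum; logs carry no timestamps, and reruns of
the same config and seed are bit-identical (verified down to the rendered
PNG). A failing stage halts with the stage name and pair index, keeping
partial outputs for inspection.

Problem sizes in the test suite (24³–48³ grids, 2,000–35,000 genes) are
the package's own choices, made so the full suite runs on one CPU in
minutes. The atlas-scale analyses the method is modelled on — voxelwise
growth maps of a real 81-subject fetal atlas, published gene lists and
fold values — require data and parameter settings that are not available
at desk scale; the phantom and planted-expression properties substitute
for them by construction.
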