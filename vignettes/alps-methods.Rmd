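---
title: "Methods: the DTI-ALPS pipeline, its phantoms and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS pipeline, its phantoms and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The model

Diffusion-tensor image analysis along the perivascular space (DTI-ALPS)
exploits a geometric accident of the periventricular white matter at the
level of the lateral-ventricle body: projection fibers run
inferior–superior (z), association fibers run anterior–posterior (y), and
the medullary veins — with their surrounding perivascular spaces — run
left–right (x), orthogonal to both fiber populations. Water diffusivity
measured along x in these two fiber bundles therefore carries a
perivascular (glymphatic) component that neither fiber direction explains,
and the ratio

$$\mathrm{ALPS} = \frac{\overline{D_{xx}}^{\,proj} + \overline{D_{xx}}^{\,assoc}}
                      {\overline{D_{yy}}^{\,proj} + \overline{D_{zz}}^{\,assoc}}$$

is approximately 1 when x-diffusivity is unremarkable and rises above 1
when diffusion along the perivascular axis is facilitated. The four means
are taken over 5 mm spheres, one pair (projection, association) per
hemisphere; `alps_r` and `alps_l` are computed separately and
`alps_comb` is their mean. When one hemisphere is undefined (an ROI off
the grid), `alps_comb` is reported missing rather than silently collapsing
to the surviving side.

The pipeline stages are: diffusion tensor fit → axis diffusivity + color-FA
maps → spherical-ROI extraction and the ALPS ratio → WMH-in-ROI
quantification with an exclusion rule → cohort statistics.

## Tensor fitting and maps

Tensors are fitted per voxel by unweighted log-linear least squares on
$\ln S = \ln S_0 - b\, g^\top D g$, all weighted shells entering one fit
(two-shell clinical acquisitions are handled without per-shell weighting).
The fit method is a deliberate choice: it is deterministic, exact on
noise-free data (the round-trip phantom test demands recovery to
1e-9 mm²/s), and is the reference implementation in every major DTI
toolchain. Voxels with any non-positive signal are masked invalid.

Axis diffusivities `dxx`, `dyy`, `dzz` are the tensor diagonals *after
rotation into the world RAS frame* (the orthogonal part of the affine, via
polar decomposition), so the maps always mean right–left,
anterior–posterior, inferior–superior regardless of storage orientation; a
reflection in the affine flips the tensor frame rather than being promoted
to a rotation. FA uses eigenvalues clamped to 1e-12 — but the ALPS ratio
averages raw diagonals, never eigenvalues, so the clamp cannot bias the
index. Eigenvalues come from the closed-form trigonometric solution for
symmetric 3×3 matrices, vectorised over the volume and verified against
`eigen()` in the tests.

## ROI geometry

A voxel belongs to a sphere when its world-space centre lies within the
radius, boundary inclusive. This voxel-centre rule is the simplest
reproducible reading of "5 mm spherical masks"; distances run through the
affine, so anisotropic voxels are handled in mm. ROI centres are consumed
as explicit world coordinates (JSON): the originating analyses drew ROIs
manually on color-FA maps, and automated placement is out of scope. On
phantoms, centres come from the generator's truth manifest.

## WMH quantification and the exclusion rule

Lesion-probability maps (FLAIR space) are thresholded at 0.5, inclusive —
the convention of the lesion-segmentation tools that produce such maps;
the threshold is a parameter. ROI centres are mapped DTI→FLAIR through a
supplied 4×4 world transform (identity for co-registered synthetic data;
registration *estimation* is explicitly not performed) and spheres are
rebuilt in FLAIR geometry around the transformed centres — coordinates are
transformed, not masks, so no resampling artefacts enter the counts.
A subject is excluded from the main analyses when *any* of the four
spheres contains at least one binary lesion voxel; excluded subjects are
routed to a separate contamination analysis, mirroring the workflow the
package reimplements. "WMH count" outside the ROIs is the number of
26-connected components, a definition the source material leaves open;
26-connectivity is the permissive standard for 3-D lesion counting.
Volume conservation (inside + outside = total) holds exactly by voxel
arithmetic provided the four spheres are disjoint, which the standard
periventricular placement guarantees (centres ≥ 12 mm apart).

## The synthetic world

`generate_phantom()` builds the assumed geometry literally: per hemisphere
a projection slab (principal eigenvalue 1.7e-3 mm²/s along z) and an
association slab (along y), perpendicular eigenvalue 0.4e-3 mm²/s —
typical coherent white matter at 3 T — flanking a CSF ventricle
(3.0e-3 mm²/s) in an isotropic background (0.7e-3 mm²/s). One parameter,
`glymph_x`, multiplies the x-diagonal of both fiber tensors and nothing
else: the minimal realisation of the perivascular premise. With equal
perpendicular eigenvalues the ground-truth ALPS equals `glymph_x` exactly,
which makes recovery tests sharp. Defaults (64³ grid, 2 mm isotropic
voxels) match the DWI geometry of the cohorts being emulated.

DWI simulation is $S = S_0 e^{-b\,g^\top D g}$ plus Rician noise — the
magnitude of the complex signal with independent Gaussian perturbations of
scale σ on both channels. Two gradient schemes ship: a minimal
10-volume design (`default_gradients()`, used where exactness rather than
precision matters) and a clinical two-shell 70-volume design
(`reference_gradients()`: 10 b=0, 30 directions at b=700 and at
b=1000 s/mm², a deterministic Fibonacci-sphere layout) emulating the
multi-centre dementia protocol. Noise acceptance checks run at
s0/σ = 30 with the 70-volume scheme, since precision under noise is a
property of the acquisition, and the emulated cohorts acquired 48–108
volumes.

Lesions are ellipsoids that *replace* the tensor with an isotropic
`lesion_md`·I (default 1.2e-3 mm²/s), multiply FLAIR intensity and
max-combine into the probability map (hence idempotent and monotone).
Replacement rather than mixing was chosen because it yields the observed
contamination direction — measured ALPS is pulled toward 1 — with a single
interpretable parameter.

`generate_cohort()` draws true ALPS values from the two group
distributions (defaults: AD 1.217 ± 0.122, n = 16; controls
1.356 ± 0.139, n = 18 — the published summaries of the smallest emulated
cohort), hemispheric indices as symmetric ±offsets (SD 0.05) about the
combined value, and covariates from realistic marginals (age ≈ N(73, 6),
education ≈ N(14, 3), balanced sex). CDR and MMSE are generated
consistently with the group label (AD: CDR ∈ {0.5, 1}, MMSE ≈ 24; HC:
CDR = 0, MMSE ≈ 29). CSF Aβ42/40 ratios are in calibrated arbitrary units
(assay units are not part of the contract): a group baseline plus a
configurable positive slope on true ALPS plus noise, then clamped to the
amyloid side the group label implies. The clamp makes the
classification-consistency invariant (every generated row satisfies the
AD/HC predicate) hold by construction; only the association *direction*
between ALPS and amyloid is meaningful, never its magnitude.

Every stochastic operation takes an explicit seed, runs in its own PRNG
stream, and restores the caller's random state.

## Statistics

* Group contrast: linear model `outcome ~ group + age + sex` with a
  two-sided t test on the group coefficient (the published tables call
  this ANOVA/ANCOVA adjusted for age and sex); raw means ± SD and
  pooled-SD Cohen's d are reported alongside, computed on unadjusted
  values, because the reference tables print raw summaries next to d.
* Associations: outcome and continuous predictors are z-scored, binary
  covariates coded 0/1; the standardized β, its SE, p and adjusted R² are
  reported with listwise deletion and the n actually used. β values are
  treated as standardized (unitless) throughout — the convention the
  reference tables imply but never state.
* Mann–Whitney U: midranks for ties; exact two-sided p by complete
  enumeration when n ≤ 12 without ties, otherwise normal approximation
  with tie and continuity corrections.
* WMH volumes get `log10(v + 1)` before parametric modelling.
* Dichotomisation rules are boundary-exact: MMSE ≥ 27 is "high",
  CDR > 0 is "high".
* Amyloid positivity is boundary-inclusive (ratio ≤ cutoff), cutoffs 0.05
  or 0.08 depending on assay/cohort. No multiple-testing correction is
  applied (none was applied in the emulated analyses); α = 0.05 two-sided.

## What a green test establishes — and what it does not

The phantom world contains exactly the structure the index assumes:
perfectly coherent single-fiber slabs, axis-aligned anatomy, no crossing
fibers, no motion or eddy artefacts, no partial-volume mixture at region
borders beyond voxelisation, and lesions that are geometrically clean
ellipsoids. Green acceptance therefore establishes that the *pipeline*
is correct (formula, geometry, bookkeeping, statistics), that the index
responds monotonically to the simulated perivascular parameter, and that
ROI contamination biases it toward 1 with a negative ALPS–WMH association
— the methodological claims. It does not establish that real AD and
control brains differ, and the published cohort regression coefficients
are not reproducible here (restricted data); those numbers enter only as
distribution parameters and printed-summary inputs.

## Numerical choices and degenerate inputs

* Tensor fit: exact QR solution; rank-deficient designs raise an
  insufficient-design error rather than a pseudo-inverse guess.
* Non-positive signals: voxel masked invalid (log undefined).
* Negative fitted eigenvalues: clamped only for FA/color-FA.
* Empty sphere masks: a warning plus an `empty` attribute; downstream the
  side becomes missing, and a missing side makes `alps_comb` missing.
* ALPS with non-positive denominator: an undefined-index error.
* Zero pooled SD: undefined-d error. Constant design columns: design
  error. Near-collinearity (condition number > 1e8): warning.
* NIfTI I/O is implemented in-package (no NIfTI reader exists in the
  supported R stack): single-file NIfTI-1, float64 on write, sform
  affine, both endiannesses on read; cross-validated against nibabel in
  the test suite. Configuration files are JSON rather than YAML for the
  same dependency reason.

## Known limitations

Single-tensor model only (no crossing-fiber or multi-compartment models);
no eddy/motion correction (out of scope — inputs are assumed
preprocessed); automated ROI placement is not provided; conservation of
WMH volume assumes disjoint ROI spheres; the exact Mann–Whitney path
enumerates combinations and is intentionally restricted to n ≤ 12.
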