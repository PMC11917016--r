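# alpsdti

An R implementation of the **DTI-ALPS** (diffusion-tensor image analysis
along the perivascular space) pipeline: a non-invasive diffusion-MRI proxy
for glymphatic function, used in dementia research to ask whether
perivascular water movement is reduced in Alzheimer's disease and how white
matter hyperintensities (WMH) confound the measurement.

At the level of the lateral-ventricle body, projection fibers run along z,
association fibers along y, and the medullary veins (with their
perivascular spaces) along x. The index is

```
ALPS = (mean Dxx_proj + mean Dxx_assoc) / (mean Dyy_proj + mean Dzz_assoc)
```

with each mean taken over a 5 mm sphere on the axis-diffusivity maps,
per hemisphere; `ALPS_comb` is the mean of the two hemispheric indices.
Values near 1 mean no preferred x-axis diffusion; larger values indicate
facilitated diffusion along the perivascular axis.

The package provides, as tested building blocks and as one pipeline:

* log-linear diffusion tensor fitting from DWI + bvals/bvecs, axis
  diffusivity maps (world RAS frame), FA and color-FA;
* spherical-ROI extraction and the ALPS index (`sphere_mask`,
  `compute_alps`);
* WMH quantification inside/outside the ROI spheres from lesion-probability
  maps, DTI→FLAIR coordinate transforms, the any-lesion exclusion rule and
  the clean/contaminated cohort partition (`wmh_in_roi`,
  `partition_cohort`);
* cohort statistics: CDR + CSF-amyloid subject classification, ANCOVA with
  Cohen's d, standardized-β regression, exact/approximate Mann–Whitney U,
  `log10(v+1)` WMH transform (`ancova_group`, `linreg_standardized`,
  `mann_whitney_u`);
* a synthetic-data module — periventricular diffusion phantoms with known
  ground-truth ALPS, Rician-noise DWI simulation, injectable ellipsoidal
  lesions, and AD/control cohort tables with realistic covariate and
  biomarker structure (`generate_phantom`, `simulate_dwi`, `inject_wmh`,
  `generate_cohort`);
* minimal NIfTI-1 I/O (none exists in the supported R stack), FSL-style
  gradient tables, ROI JSON, and a CLI (`exec/alpsdti`).

## Worked example 1: phantom with known truth

```r
library(alpsdti)

cfg  <- phantom_config(grid_shape = c(32L, 32L, 32L), glymph_x = 1.35)
ph   <- generate_phantom(cfg)          # ground truth: ALPS = 1.35 exactly
grad <- reference_gradients()          # two-shell, 70-volume clinical scheme
dwi  <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs,
                     s0 = 1000, rician_sigma = 1000 / 30, seed = 1)
maps <- diffusivity_maps(fit_tensor(dwi))
res  <- compute_alps(maps, roi_set_from_centers(ph$truth$roi_centers_mm))
res
#> <alps_result> R 1.3367  L 1.3424  comb 1.3396
```

At SNR 30 the measured combined index (1.3396) sits within 1% of the
configured truth 1.35; with `rician_sigma = 0` recovery is exact to 1e-9.
The four regional means behind the right-side index
(`res$means$right`, mm²/s) show the expected structure — x-diffusivity
raised by the perivascular factor, y/z at the perpendicular eigenvalue:

```
x_proj 5.41e-4   x_assoc 5.31e-4   y_proj 4.01e-4   z_assoc 4.01e-4
```

## Worked example 2: synthetic cohort statistics

```r
tab <- generate_cohort(cohort_config(seed = 20L))  # 16 AD vs 18 HC
res <- ancova_group(tab, "alps_comb", "group", c("age", "sex"))
#> AD 1.178 +/- 0.140 (n=16) vs HC 1.356 +/- 0.145 (n=18),
#> p = 0.0008, d = -1.242
```

One seeded draw at the default parameters (group means 1.217 vs 1.356)
yields a significant age/sex-adjusted group difference with a large
negative effect size, as expected for those distributions at n = 34.

## Full pipeline

```r
man <- run_pipeline(run_config(mode = "synthetic", out_dir = "out",
                               seed = 11L, n_ad = 16L, n_hc = 18L,
                               n_contaminated = 2L))
```

writes `subjects.csv`, `alps.tsv`, `wmh.tsv`, `stats.json` and a
`manifest.json` with filter counts (classified / WMH-excluded / analyzed)
and file checksums; identical config + seed reproduces byte-identical
outputs. The same driver runs from files
(`mode = "files"`: NIfTI DWI, bvals/bvecs, lesion-probability NIfTI, ROI
JSON, 4×4 transform text). A CLI wraps the stages:

```sh
exec/alpsdti simulate phantom --config cfg.json --out dir --seed 3
exec/alpsdti tensor --dwi dwi.nii.gz --bvals bvals --bvecs bvecs --out maps/
exec/alpsdti run --config run.json
```

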