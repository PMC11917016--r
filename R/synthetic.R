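# Synthetic phantoms and cohorts with known ground truth.
#
# The phantom realizes the periventricular geometry the perivascular-space
# (ALPS) index assumes: projection-fiber slabs with principal diffusion along
# z and association-fiber slabs with principal diffusion along y, flanking a
# ventricle, per hemisphere. A single dimensionless parameter `glymph_x`
# multiplies the x-axis diffusivity of both fiber populations and plays the
# role of the perivascular water component; with equal perpendicular
# eigenvalues the ground-truth ALPS index equals `glymph_x` exactly.

run_seeded <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Phantom configuration
#'
#' Describes a two-hemisphere periventricular phantom on a regular RAS grid:
#' a central ventricle slab, and per hemisphere one projection-fiber slab
#' (principal eigenvector along z) and one association-fiber slab (along y),
#' all spans given as distances from the mid-sagittal plane.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size_mm Numeric length-3, mm per voxel.
#' @param base_eigenvalues Fiber tensor eigenvalues `c(parallel,
#'   perpendicular)` in mm^2/s. Defaults 1.7e-3 / 0.4e-3, typical coherent
#'   white matter at 3T.
#' @param glymph_x Multiplier on the x-axis diffusivity in both fiber slabs
#'   (the simulated perivascular component). With the default equal
#'   perpendicular eigenvalues, ground-truth ALPS = `glymph_x`.
#' @param region_layout List with `ventricle_halfwidth_mm`,
#'   `proj_offset_mm` (range from midline), `assoc_offset_mm`, `slab_frac`
#'   (fraction of the y/z extent the slabs span, centred).
#' @param md_background,md_csf Isotropic diffusivities (mm^2/s) outside the
#'   slabs and in the ventricle.
#' @param s0 Baseline (b=0) signal.
#' @param rician_sigma Noise scale for [simulate_dwi].
#' @param seed Integer seed used by downstream stochastic steps.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           voxel_size_mm = c(2, 2, 2),
                           base_eigenvalues = c(1.7e-3, 0.4e-3),
                           glymph_x = 1.35,
                           region_layout = list(
                             ventricle_halfwidth_mm = 4,
                             proj_offset_mm = c(6, 18),
                             assoc_offset_mm = c(20, 30),
                             slab_frac = 0.6),
                           md_background = 0.7e-3,
                           md_csf = 3.0e-3,
                           s0 = 1000,
                           rician_sigma = 0,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              base_eigenvalues = base_eigenvalues,
              glymph_x = glymph_x, region_layout = region_layout,
              md_background = md_background, md_csf = md_csf,
              s0 = s0, rician_sigma = rician_sigma, seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  rl <- cfg$region_layout
  if (any(cfg$grid_shape <= 0L) || any(cfg$voxel_size_mm <= 0))
    abort("grid_shape and voxel sizes must be positive",
          "alpsdti_invalid_config")
  if (any(cfg$base_eigenvalues <= 0) || cfg$glymph_x <= 0)
    abort("eigenvalues and glymph_x must be positive",
          "alpsdti_invalid_config")
  spans <- rbind(c(-rl$ventricle_halfwidth_mm, rl$ventricle_halfwidth_mm),
                 rl$proj_offset_mm, rl$assoc_offset_mm)
  if (any(spans[, 2] <= spans[, 1]))
    abort("region spans must have positive width", "alpsdti_invalid_config")
  # projection/association (and ventricle) slabs must be disjoint in |x|
  if (rl$proj_offset_mm[1] < rl$ventricle_halfwidth_mm ||
      rl$assoc_offset_mm[1] < rl$proj_offset_mm[2])
    abort("fiber regions overlap: projection and association slabs must be disjoint",
          "alpsdti_invalid_config")
  ext_x <- (cfg$grid_shape[1] - 1) * cfg$voxel_size_mm[1]
  if (ext_x / 2 < rl$assoc_offset_mm[2])
    abort("grid too small in x for the configured region layout",
          "alpsdti_invalid_config")
  invisible(cfg)
}

#' Tensor field constructor
#'
#' @param lower 4-D array `(x, y, z, 6)` of unique tensor components in
#'   NIfTI lower-triangular order: Dxx, Dxy, Dyy, Dxz, Dyz, Dzz (mm^2/s).
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask Logical 3-D validity mask (default all valid).
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(lower, affine = diag(4), mask = NULL) {
  if (length(dim(lower)) != 4L || dim(lower)[4] != 6L)
    abort("tensor field must be (x, y, z, 6)", "alpsdti_geometry_error")
  if (is.null(mask)) mask <- array(TRUE, dim(lower)[1:3])
  structure(list(lower = lower, affine = affine, mask = mask),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(dim(x$lower)[1:3], collapse = " x "),
      " voxels (", sum(x$mask), " valid)\n", sep = "")
  invisible(x)
}

#' Generate a periventricular diffusion phantom
#'
#' Builds the tensor field described by a [phantom_config] together with its
#' ground-truth manifest: the per-hemisphere axis diffusivities the four ALPS
#' ROIs should read, the true ALPS index, and the ROI centres (the slab
#' midpoints, mirrored about the mid-sagittal plane). Construction is fully
#' deterministic; randomness enters only at the DWI-simulation stage.
#'
#' @param config A [phantom_config].
#' @return List with `tensors` ([tensor_field]), `regions` (integer array:
#'   0 background, 1 ventricle, 2 projection, 3 association) and `truth`
#'   (diffusivities, `true_alps`, `roi_centers_mm`, lesion manifest).
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  gs <- config$grid_shape
  affine <- diag(c(config$voxel_size_mm, 1))
  co <- grid_world_coords(gs, affine)
  ext <- (gs - 1L) * config$voxel_size_mm
  mid <- ext / 2
  rl <- config$region_layout
  dx <- co[, 1] - mid[1]
  in_slab_yz <- abs(co[, 2] - mid[2]) <= rl$slab_frac * ext[2] / 2 &
    abs(co[, 3] - mid[3]) <= rl$slab_frac * ext[3] / 2

  regions <- integer(nrow(co))
  regions[abs(dx) <= rl$ventricle_halfwidth_mm & in_slab_yz] <- 1L
  proj <- abs(dx) >= rl$proj_offset_mm[1] & abs(dx) <= rl$proj_offset_mm[2] &
    in_slab_yz
  assoc <- abs(dx) >= rl$assoc_offset_mm[1] & abs(dx) <= rl$assoc_offset_mm[2] &
    in_slab_yz
  regions[proj] <- 2L
  regions[assoc] <- 3L

  lam_par <- config$base_eigenvalues[1]
  lam_perp <- config$base_eigenvalues[2]
  gx <- config$glymph_x

  nvox <- prod(gs)
  lower <- matrix(0, nvox, 6L) # Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
  bg <- regions == 0L
  lower[bg, c(1L, 3L, 6L)] <- config$md_background
  vent <- regions == 1L
  lower[vent, c(1L, 3L, 6L)] <- config$md_csf
  # projection fibers: principal along z; perivascular component along x
  lower[proj, 1L] <- gx * lam_perp
  lower[proj, 3L] <- lam_perp
  lower[proj, 6L] <- lam_par
  # association fibers: principal along y
  lower[assoc, 1L] <- gx * lam_perp
  lower[assoc, 3L] <- lam_par
  lower[assoc, 6L] <- lam_perp

  x_proj <- gx * lam_perp
  x_assoc <- gx * lam_perp
  y_proj <- lam_perp
  z_assoc <- lam_perp
  roi_x <- c(proj = mean(rl$proj_offset_mm), assoc = mean(rl$assoc_offset_mm))
  centers <- list(
    right = list(projection = c(mid[1] + roi_x["proj"], mid[2], mid[3]),
                 association = c(mid[1] + roi_x["assoc"], mid[2], mid[3])),
    left = list(projection = c(mid[1] - roi_x["proj"], mid[2], mid[3]),
                association = c(mid[1] - roi_x["assoc"], mid[2], mid[3]))
  )
  centers <- lapply(centers, lapply, unname)
  truth <- list(
    x_proj = x_proj, x_assoc = x_assoc, y_proj = y_proj, z_assoc = z_assoc,
    true_alps = (x_proj + x_assoc) / (y_proj + z_assoc),
    roi_centers_mm = centers,
    lesions = list()
  )
  list(tensors = tensor_field(array(lower, c(gs, 6L)), affine),
       regions = array(regions, gs),
       truth = truth)
}

#' Default diffusion gradient scheme
#'
#' One b=0 volume plus nine unit directions (three axis-aligned, six oblique),
#' the minimal full-rank design for the six tensor unknowns.
#'
#' @param bval b-value for the weighted volumes (s/mm^2).
#' @param n_b0 Number of b=0 volumes.
#' @return List with `bvals` and 3 x n `bvecs`.
#' @export
default_gradients <- function(bval = 1000, n_b0 = 1L) {
  s <- 1 / sqrt(2)
  dirs <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(s, s, 0), c(s, 0, s), c(0, s, s),
                c(s, -s, 0), c(s, 0, -s), c(0, s, -s))
  list(bvals = c(rep(0, n_b0), rep(bval, ncol(dirs))),
       bvecs = cbind(matrix(0, 3, n_b0), dirs))
}

#' Deterministic near-uniform unit directions (spherical Fibonacci lattice)
#'
#' @param n Number of directions.
#' @return 3 x n matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Reference multi-shell gradient scheme
#'
#' Emulates a clinical dementia-cohort acquisition: 10 b=0 volumes and 30
#' near-uniform directions at each of b = 700 and b = 1000 s/mm^2 (the
#' two-shell 70-volume protocol used by multi-centre dementia studies).
#'
#' @param bvals_shells b-values of the weighted shells.
#' @param n_dirs Directions per shell.
#' @param n_b0 Number of b=0 volumes.
#' @return List with `bvals` and 3 x n `bvecs`.
#' @export
reference_gradients <- function(bvals_shells = c(700, 1000), n_dirs = 30L,
                                n_b0 = 10L) {
  dirs <- fibonacci_directions(n_dirs)
  list(bvals = c(rep(0, n_b0), rep(bvals_shells, each = n_dirs)),
       bvecs = cbind(matrix(0, 3, n_b0),
                     do.call(cbind, rep(list(dirs), length(bvals_shells)))))
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Noise-free signal per voxel and direction is `s0 * exp(-b * g' D g)`;
#' Rician noise is applied as the magnitude of the complex signal after
#' adding independent Gaussian noise of scale `rician_sigma` to the real and
#' imaginary channels (the standard magnitude-MRI model).
#'
#' @param tensors A [tensor_field].
#' @param bvals Numeric b-values (s/mm^2), at least one zero.
#' @param bvecs 3 x n matrix of unit directions (zero vectors allowed for
#'   b=0 volumes).
#' @param s0 Baseline signal.
#' @param rician_sigma Noise scale (0 for noise-free).
#' @param seed Integer seed; the call uses its own PRNG stream.
#' @return A `dwi_set` list: `signals` 4-D array, `bvals`, `bvecs`, `affine`.
#' @export
simulate_dwi <- function(tensors, bvals, bvecs, s0 = 1000,
                         rician_sigma = 0, seed = 1L) {
  bvecs <- as.matrix(bvecs)
  nvol <- length(bvals)
  if (ncol(bvecs) != nvol)
    abort("bvecs columns must match bvals length", "alpsdti_validation_error")
  wtd <- bvals > 0
  if (!any(bvals == 0))
    abort("at least one b=0 volume required", "alpsdti_insufficient_design")
  norms <- sqrt(colSums(bvecs[, wtd, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    abort("weighted bvecs must be unit-norm (within 1e-6)",
          "alpsdti_validation_error")
  if (qr(dwi_design(bvals, bvecs))$rank < 7L)
    abort("need >= 6 non-collinear weighted directions",
          "alpsdti_insufficient_design")

  gs <- dim(tensors$lower)[1:3]
  nvox <- prod(gs)
  low <- matrix(tensors$lower, nvox, 6L)
  sig <- matrix(0, nvox, nvol)
  for (v in seq_len(nvol)) {
    g <- bvecs[, v]
    quad <- low[, 1L] * g[1]^2 + low[, 3L] * g[2]^2 + low[, 6L] * g[3]^2 +
      2 * (low[, 2L] * g[1] * g[2] + low[, 4L] * g[1] * g[3] +
             low[, 5L] * g[2] * g[3])
    sig[, v] <- s0 * exp(-bvals[v] * quad)
  }
  if (rician_sigma > 0) {
    sig <- run_seeded(seed, function() {
      n1 <- matrix(stats::rnorm(length(sig), sd = rician_sigma), nrow(sig))
      n2 <- matrix(stats::rnorm(length(sig), sd = rician_sigma), nrow(sig))
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  structure(list(signals = array(sig, c(gs, nvol)),
                 bvals = bvals, bvecs = bvecs, affine = tensors$affine),
            class = "dwi_set")
}

# Design matrix of the log-linear tensor model:
# ln S = ln S0 - b * (gx^2 Dxx + 2 gx gy Dxy + gy^2 Dyy + 2 gx gz Dxz +
#                     2 gy gz Dyz + gz^2 Dzz)
dwi_design <- function(bvals, bvecs) {
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  cbind(1, -bvals * gx^2, -2 * bvals * gx * gy, -bvals * gy^2,
        -2 * bvals * gx * gz, -2 * bvals * gy * gz, -bvals * gz^2)
}

#' Ellipsoidal white-matter-lesion specification
#'
#' @param center_mm World-mm centre.
#' @param semi_axes_mm Ellipsoid semi-axes (mm), length 1 or 3.
#' @param lesion_md Isotropic diffusivity inside the lesion (mm^2/s).
#' @param flair_intensity Multiplier applied to FLAIR intensity inside.
#' @param probability Value written to the lesion-probability map.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center_mm, semi_axes_mm, lesion_md = 1.2e-3,
                        flair_intensity = 2, probability = 1) {
  semi_axes_mm <- rep_len(as.numeric(semi_axes_mm), 3L)
  if (any(semi_axes_mm <= 0) || lesion_md <= 0 ||
      probability < 0 || probability > 1)
    abort("invalid lesion: semi-axes and lesion_md must be > 0, probability in [0,1]",
          "alpsdti_invalid_config")
  structure(list(center_mm = as.numeric(center_mm),
                 semi_axes_mm = semi_axes_mm, lesion_md = lesion_md,
                 flair_intensity = flair_intensity, probability = probability),
            class = "lesion_spec")
}

ellipsoid_voxels <- function(dim3, affine, lesion) {
  co <- grid_world_coords(dim3, affine)
  d <- sweep(co, 2L, lesion$center_mm)
  d <- sweep(d, 2L, lesion$semi_axes_mm, "/")
  rowSums(d^2) <= 1
}

#' Inject ellipsoidal WMH lesions into phantom volumes
#'
#' Inside each ellipsoid the tensor is replaced by the isotropic lesion
#' tensor `lesion_md * I`, FLAIR intensity is multiplied by
#' `flair_intensity`, and the lesion-probability map takes the voxelwise
#' maximum of its current value and `probability` (so repeated injection is
#' idempotent and monotone). Voxels outside all ellipsoids are untouched.
#'
#' @param tensors A [tensor_field] (DTI grid).
#' @param flair A [volume3d] FLAIR image (may have its own grid).
#' @param prob_map A [volume3d] lesion-probability map in FLAIR space.
#' @param lesions List of [lesion_spec] objects.
#' @return List with updated `tensors`, `flair`, `prob_map`, and
#'   `n_modified`: voxels rewritten on the tensor grid per lesion.
#' @export
inject_wmh <- function(tensors, flair, prob_map, lesions) {
  gs <- dim(tensors$lower)[1:3]
  lo <- vox_to_world(tensors$affine, c(0, 0, 0))
  hi <- vox_to_world(tensors$affine, gs - 1L)
  bounds <- rbind(pmin(lo, hi), pmax(lo, hi))
  low <- matrix(tensors$lower, prod(gs), 6L)
  n_modified <- integer(length(lesions))
  for (li in seq_along(lesions)) {
    les <- lesions[[li]]
    if (any(les$center_mm < bounds[1, ] | les$center_mm > bounds[2, ]))
      abort("lesion centre outside the tensor grid", "alpsdti_placement_error")
    inside <- ellipsoid_voxels(gs, tensors$affine, les)
    low[inside, ] <- rep(c(les$lesion_md, 0, les$lesion_md, 0, 0,
                           les$lesion_md), each = sum(inside))
    n_modified[li] <- sum(inside)
    fin <- ellipsoid_voxels(dim(flair$data), flair$affine, les)
    flair$data[fin] <- flair$data[fin] * les$flair_intensity
    pin <- ellipsoid_voxels(dim(prob_map$data), prob_map$affine, les)
    prob_map$data[pin] <- pmax(prob_map$data[pin], les$probability)
  }
  tensors$lower <- array(low, c(gs, 6L))
  list(tensors = tensors, flair = flair, prob_map = prob_map,
       n_modified = n_modified)
}

#' Cohort-simulation configuration
#'
#' Group sizes and ALPS-index distribution parameters default to the values
#' observed for the smallest of the three dementia cohorts the index has been
#' applied to (AD 1.217 +/- 0.122, n 16; controls 1.356 +/- 0.139, n 18),
#' the amyloid cutoff to the 0.05 CSF Abeta42/40 ratio used with the
#' Elecsys/ELISA assays of that cohort. Abeta values are in calibrated
#' arbitrary units; only the association direction with ALPS is meaningful.
#'
#' @param n_ad,n_hc Group sizes (>= 2 each).
#' @param alps_mean_ad,alps_sd_ad,alps_mean_hc,alps_sd_hc ALPS_comb
#'   distribution parameters per group.
#' @param hemi_sd SD of the right/left hemispheric offsets about ALPS_comb.
#' @param age_mean,age_sd,edu_mean,edu_sd,p_female Covariate distributions.
#' @param abeta_cutoff Amyloid-positivity cutoff on the Abeta42/40 ratio
#'   (positive = ratio at or below the cutoff).
#' @param abeta_slope Per-unit slope of the Abeta42/40 ratio on true ALPS
#'   (positive: higher ALPS, higher ratio, i.e. less amyloid).
#' @param abeta_noise_sd Residual SD of the ratio.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_ad = 16L, n_hc = 18L,
                          alps_mean_ad = 1.217, alps_sd_ad = 0.122,
                          alps_mean_hc = 1.356, alps_sd_hc = 0.139,
                          hemi_sd = 0.05,
                          age_mean = 73, age_sd = 6,
                          edu_mean = 14, edu_sd = 3, p_female = 0.5,
                          abeta_cutoff = 0.05, abeta_slope = 0.05,
                          abeta_noise_sd = 0.008, seed = 1L) {
  cfg <- list(n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
              alps_mean_ad = alps_mean_ad, alps_sd_ad = alps_sd_ad,
              alps_mean_hc = alps_mean_hc, alps_sd_hc = alps_sd_hc,
              hemi_sd = hemi_sd, age_mean = age_mean, age_sd = age_sd,
              edu_mean = edu_mean, edu_sd = edu_sd, p_female = p_female,
              abeta_cutoff = abeta_cutoff, abeta_slope = abeta_slope,
              abeta_noise_sd = abeta_noise_sd, seed = as.integer(seed))
  if (cfg$n_ad < 2L || cfg$n_hc < 2L)
    abort("need n >= 2 per group", "alpsdti_invalid_config")
  if (cfg$alps_sd_ad <= 0 || cfg$alps_sd_hc <= 0)
    abort("ALPS SDs must be positive", "alpsdti_invalid_config")
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate an AD/control cohort table
#'
#' Draws per-subject true ALPS indices from the group distributions,
#' covariates (age, sex, education), CDR and MMSE consistent with the group
#' labels (AD: CDR >= 0.5; HC: CDR = 0), and CSF Abeta42/40 ratios with the
#' configured positive slope on true ALPS plus noise, clamped to the amyloid
#' side implied by the group so that every row satisfies the AD/HC
#' classification predicate exactly.
#'
#' @param config A [cohort_config].
#' @return Data frame, one row per subject: id, group, age, sex (1 =
#'   female), education, cdr_global, mmse, abeta42, abeta40, abeta_ratio,
#'   alps_true, alps_r, alps_l, alps_comb, wmh_comb, excluded.
#' @export
generate_cohort <- function(config) {
  cfg <- config
  run_seeded(cfg$seed, function() {
    n <- cfg$n_ad + cfg$n_hc
    group <- rep(c("AD", "HC"), c(cfg$n_ad, cfg$n_hc))
    alps <- c(stats::rnorm(cfg$n_ad, cfg$alps_mean_ad, cfg$alps_sd_ad),
              stats::rnorm(cfg$n_hc, cfg$alps_mean_hc, cfg$alps_sd_hc))
    hemi <- stats::rnorm(n, 0, cfg$hemi_sd)
    alps_r <- alps + hemi
    alps_l <- alps - hemi
    age <- round(stats::rnorm(n, cfg$age_mean, cfg$age_sd), 1)
    sex <- stats::rbinom(n, 1L, cfg$p_female)
    edu <- pmax(6, round(stats::rnorm(n, cfg$edu_mean, cfg$edu_sd)))
    cdr <- ifelse(group == "AD",
                  sample(c(0.5, 1), n, TRUE, prob = c(0.7, 0.3)), 0)
    mmse <- ifelse(group == "AD",
                   pmin(30, pmax(10, round(stats::rnorm(n, 24, 3)))),
                   pmin(30, pmax(24, round(stats::rnorm(n, 29, 1)))))
    # ratio: group baseline + slope on true ALPS + noise, clamped to the
    # amyloid side the group label implies (AD amyloid-positive: <= cutoff)
    base <- ifelse(group == "AD", cfg$abeta_cutoff * 0.7,
                   cfg$abeta_cutoff * 1.5)
    ratio <- base + cfg$abeta_slope * (alps - mean(alps)) +
      stats::rnorm(n, 0, cfg$abeta_noise_sd)
    eps <- cfg$abeta_cutoff * 1e-3
    ratio <- ifelse(group == "AD",
                    pmin(ratio, cfg$abeta_cutoff),
                    pmax(ratio, cfg$abeta_cutoff + eps))
    ratio <- pmax(ratio, eps)
    abeta40 <- stats::rnorm(n, 1.5, 0.25)
    data.frame(
      id = sprintf("sub-%03d", seq_len(n)),
      group = group, age = age, sex = sex, education = edu,
      cdr_global = cdr, mmse = mmse,
      abeta42 = ratio * abeta40, abeta40 = abeta40, abeta_ratio = ratio,
      alps_true = alps, alps_r = alps_r, alps_l = alps_l,
      alps_comb = (alps_r + alps_l) / 2,
      wmh_comb = 0, excluded = FALSE,
      stringsAsFactors = FALSE
    )
  })
}
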