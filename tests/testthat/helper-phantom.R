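# Shared fixtures, built in code at test time.

small_phantom <- function(glymph_x = 1.35, grid = c(32L, 32L, 32L),
                          vox = c(2, 2, 2), ...) {
  phantom_config(grid_shape = grid, voxel_size_mm = vox,
                 glymph_x = glymph_x, ...)
}

# Full noise-free chain: config -> measured ALPS result.
measure_alps_noisefree <- function(cfg, lesions = NULL, seed = 1L) {
  ph <- generate_phantom(cfg)
  tensors <- ph$tensors
  if (!is.null(lesions)) {
    flair <- volume3d(array(1, cfg$grid_shape), tensors$affine)
    prob <- volume3d(array(0, cfg$grid_shape), tensors$affine)
    tensors <- inject_wmh(tensors, flair, prob, lesions)$tensors
  }
  grad <- default_gradients()
  dwi <- simulate_dwi(tensors, grad$bvals, grad$bvecs, s0 = cfg$s0,
                      rician_sigma = 0, seed = seed)
  maps <- diffusivity_maps(fit_tensor(dwi))
  compute_alps(maps, roi_set_from_centers(ph$truth$roi_centers_mm))
}

# Independent oracle: voxel count of a sphere on a regular lattice by
# exhaustive enumeration of integer offsets.
lattice_sphere_count <- function(radius_mm, voxel_mm) {
  r <- ceiling(radius_mm / voxel_mm)
  off <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  sum((off$i^2 + off$j^2 + off$k^2) * voxel_mm^2 <= radius_mm^2)
}

# Independent oracle: brute-force count of voxel centres inside an ellipsoid.
brute_ellipsoid_count <- function(dim3, affine, lesion) {
  cnt <- 0L
  for (i in seq_len(dim3[1]) - 1L)
    for (j in seq_len(dim3[2]) - 1L)
      for (k in seq_len(dim3[3]) - 1L) {
        w <- drop(affine[1:3, 1:3] %*% c(i, j, k) + affine[1:3, 4])
        if (sum(((w - lesion$center_mm) / lesion$semi_axes_mm)^2) <= 1)
          cnt <- cnt + 1L
      }
  cnt
}

# Independent oracle: standardized-beta regression via explicit normal
# equations (solve(X'X) X'y), no shared code with linreg_standardized.
normal_eq_standardized <- function(df, outcome, predictor, covariates) {
  z <- function(v) (v - mean(v)) / sd(v)
  y <- z(df[[outcome]])
  X <- cbind(1, sapply(c(predictor, covariates), function(v) z(df[[v]])))
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  n <- length(y); p <- ncol(X) - 1
  s2 <- sum(res^2) / (n - ncol(X))
  covb <- s2 * solve(t(X) %*% X)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = b[2], se = sqrt(covb[2, 2]),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

expect_alps_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
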