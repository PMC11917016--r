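# synthetic_data: phantom generation, DWI simulation, lesion injection,
# cohort simulation.

test_that("phantom truth follows the ALPS formula and the stated geometry", {
  # glymph_x = 1 with equal perpendicular eigenvalues -> true ALPS exactly 1
  ph1 <- generate_phantom(small_phantom(glymph_x = 1))
  expect_identical(ph1$truth$true_alps, 1)

  # configured diffusivities 1.2e-3 / 0.9e-3 -> 2.4/1.8
  cfg <- small_phantom(glymph_x = 1.2e-3 / 0.9e-3,
                       base_eigenvalues = c(1.7e-3, 0.9e-3))
  ph <- generate_phantom(cfg)
  expect_equal(ph$truth$x_proj, 1.2e-3, tolerance = 1e-12)
  expect_equal(ph$truth$true_alps, 2.4 / 1.8, tolerance = 1e-12)
  tr <- ph$truth
  expect_identical(tr$true_alps,
                   (tr$x_proj + tr$x_assoc) / (tr$y_proj + tr$z_assoc))

  # principal eigenvalue along z in projection slabs, along y in association
  gs <- cfg$grid_shape
  low <- matrix(ph$tensors$lower, prod(gs), 6)
  reg <- as.vector(ph$regions)
  expect_true(all(low[reg == 2L, 6] > low[reg == 2L, c(1, 3)]))
  expect_true(all(low[reg == 3L, 3] > low[reg == 3L, c(1, 6)]))
  # x-diagonal = glymph_x * perpendicular eigenvalue in both fiber regions
  expect_equal(unique(low[reg %in% c(2L, 3L), 1]),
               cfg$glymph_x * cfg$base_eigenvalues[2], tolerance = 1e-15)
})

test_that("invalid phantom configs are rejected", {
  expect_alps_error(phantom_config(glymph_x = 0), "alpsdti_invalid_config")
  expect_alps_error(phantom_config(base_eigenvalues = c(1.7e-3, -1e-4)),
                    "alpsdti_invalid_config")
  # overlapping projection/association slabs
  expect_alps_error(
    phantom_config(region_layout = list(ventricle_halfwidth_mm = 4,
                                        proj_offset_mm = c(6, 22),
                                        assoc_offset_mm = c(20, 30),
                                        slab_frac = 0.6)),
    "alpsdti_invalid_config")
  expect_alps_error(phantom_config(grid_shape = c(16, 64, 64)),
                    "alpsdti_invalid_config")
})

test_that("simulate_dwi reproduces the analytic signal model", {
  ph <- generate_phantom(small_phantom(grid = c(16L, 16L, 16L),
                                       region_layout = list(
                                         ventricle_halfwidth_mm = 2,
                                         proj_offset_mm = c(3, 7),
                                         assoc_offset_mm = c(8, 14),
                                         slab_frac = 0.6)))
  grad <- default_gradients(bval = 1000)
  dwi <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, s0 = 500,
                      rician_sigma = 0, seed = 3)
  # b=0 -> s0 everywhere
  expect_true(all(dwi$signals[, , , 1] == 500))
  # isotropic voxel: signal independent of direction, s0*exp(-b*d)
  bg <- which(ph$regions == 0L, arr.ind = TRUE)[1, ]
  s_bg <- dwi$signals[bg[1], bg[2], bg[3], ]
  expect_equal(s_bg[-1], rep(500 * exp(-1000 * 0.7e-3), 9),
               tolerance = 1e-12)
})

test_that("single-voxel anisotropic signals match hand-computed exponents", {
  # frozen oracle: direct g' D g evaluation for an off-diagonal tensor
  D <- matrix(c(1.5e-3, 2e-4, 1e-4,
                2e-4, 0.8e-3, 5e-5,
                1e-4, 5e-5, 0.4e-3), 3, 3)
  low <- array(c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3]),
               c(1, 1, 1, 6))
  tf <- tensor_field(low)
  grad <- default_gradients(bval = 800)
  dwi <- simulate_dwi(tf, grad$bvals, grad$bvecs, s0 = 100, seed = 1)
  for (v in 2:10) {
    g <- grad$bvecs[, v]
    expect_equal(dwi$signals[1, 1, 1, v],
                 100 * exp(-800 * drop(t(g) %*% D %*% g)), tolerance = 1e-12)
  }
})

test_that("simulate_dwi validates its design", {
  tf <- tensor_field(array(1e-3 * c(1, 0, 1, 0, 0, 1), c(1, 1, 1, 6)))
  expect_alps_error(
    simulate_dwi(tf, c(0, 1000, 1000), cbind(0, c(1, 0, 0), c(0, 1, 0))),
    "alpsdti_insufficient_design")
  bad <- default_gradients()
  bad$bvecs[, 2] <- c(2, 0, 0)
  expect_alps_error(simulate_dwi(tf, bad$bvals, bad$bvecs),
                    "alpsdti_validation_error")
  expect_alps_error(
    simulate_dwi(tf, rep(1000, 10), default_gradients()$bvecs[, c(2:10, 2)]),
    "alpsdti_insufficient_design")
})

test_that("simulate_dwi is deterministic given seed and leaves global RNG alone", {
  ph <- generate_phantom(small_phantom(grid = c(16L, 16L, 16L),
                                       region_layout = list(
                                         ventricle_halfwidth_mm = 2,
                                         proj_offset_mm = c(3, 7),
                                         assoc_offset_mm = c(8, 14),
                                         slab_frac = 0.6)))
  grad <- default_gradients()
  set.seed(99)
  probe1 <- runif(1)
  set.seed(99)
  a <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, rician_sigma = 30,
                    seed = 11)
  b <- simulate_dwi(ph$tensors, grad$bvals, grad$bvecs, rician_sigma = 30,
                    seed = 11)
  probe2 <- runif(1)
  expect_identical(a$signals, b$signals)
  expect_identical(probe1, probe2) # caller's RNG stream untouched
  ph2 <- generate_phantom(small_phantom(grid = c(16L, 16L, 16L),
                                        region_layout = list(
                                          ventricle_halfwidth_mm = 2,
                                          proj_offset_mm = c(3, 7),
                                          assoc_offset_mm = c(8, 14),
                                          slab_frac = 0.6)))
  expect_identical(ph$tensors$lower, ph2$tensors$lower)
})

test_that("inject_wmh matches the brute-force ellipsoid oracle and is monotone", {
  cfg <- small_phantom()
  ph <- generate_phantom(cfg)
  gs <- cfg$grid_shape
  flair <- volume3d(array(1, gs), ph$tensors$affine)
  prob <- volume3d(array(0, gs), ph$tensors$affine)

  # empty lesion list -> identity
  out0 <- inject_wmh(ph$tensors, flair, prob, list())
  expect_identical(out0$tensors$lower, ph$tensors$lower)
  expect_identical(out0$prob_map$data, prob$data)

  les <- lesion_spec(ph$truth$roi_centers_mm$right$projection,
                     semi_axes_mm = c(4, 3, 2), probability = 0.8)
  out <- inject_wmh(ph$tensors, flair, prob, list(les))
  expect_identical(out$n_modified,
                   brute_ellipsoid_count(gs, ph$tensors$affine, les))
  # isotropic replacement inside
  low <- matrix(out$tensors$lower, prod(gs), 6)
  ins <- which(out$prob_map$data > 0)
  expect_true(all(low[ins, 1] == les$lesion_md))
  expect_true(all(low[ins, c(2, 4, 5)] == 0))

  # idempotent and monotone on the probability map
  out2 <- inject_wmh(out$tensors, out$flair, out$prob_map, list(les))
  expect_identical(out2$prob_map$data, out$prob_map$data)
  les_hi <- lesion_spec(les$center_mm, 2, probability = 1)
  out3 <- inject_wmh(out$tensors, out$flair, out$prob_map, list(les_hi))
  expect_true(all(out3$prob_map$data >= out$prob_map$data))

  expect_alps_error(
    inject_wmh(ph$tensors, flair, prob,
               list(lesion_spec(c(500, 0, 0), 3))),
    "alpsdti_placement_error")
})

test_that("ROI contamination with mean-diffusivity lesions pulls ALPS toward 1", {
  cfg <- small_phantom(glymph_x = 1.35)
  ph <- generate_phantom(cfg)
  md <- mean(c(1.35 * 0.4e-3, 0.4e-3, 1.7e-3)) # projection-tensor MD
  les <- lesion_spec(ph$truth$roi_centers_mm$left$projection, 4,
                     lesion_md = md)
  clean <- measure_alps_noisefree(cfg)
  dirty <- measure_alps_noisefree(cfg, lesions = list(les))
  expect_lt(dirty$alps_l, clean$alps_l)
  expect_gt(dirty$alps_l, 1)
})

test_that("generate_cohort honours the configured distributions", {
  big <- cohort_config(n_ad = 10000L, n_hc = 10000L, seed = 42L)
  tab <- generate_cohort(big)
  # CLT bound: sample means within 3 SD/sqrt(n) of the configured means
  expect_lt(abs(mean(tab$alps_true[tab$group == "AD"]) - 1.217),
            3 * 0.122 / sqrt(10000))
  expect_lt(abs(mean(tab$alps_true[tab$group == "HC"]) - 1.356),
            3 * 0.139 / sqrt(10000))
  # classification predicate holds for every row
  expect_identical(
    suppressMessages(classify_subjects(tab, cutoff = big$abeta_cutoff)),
    tab$group)
  # positive configured slope shows up as a positive association
  expect_gt(cor(tab$alps_true, tab$abeta_ratio, method = "spearman"), 0)

  # abeta_slope = 0 -> correlation compatible with zero (within-group,
  # the group offset itself still separates ratios)
  tab0 <- generate_cohort(cohort_config(n_ad = 4000L, n_hc = 4000L,
                                        abeta_slope = 0, seed = 7L))
  ad <- tab0[tab0$group == "AD" & tab0$abeta_ratio < 0.05, ]
  expect_lt(abs(cor(ad$alps_true, ad$abeta_ratio)), 3 / sqrt(nrow(ad)))
})

test_that("generate_cohort is deterministic and validates config", {
  cfg <- cohort_config(seed = 5L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_alps_error(cohort_config(n_ad = 1L), "alpsdti_invalid_config")
  expect_alps_error(cohort_config(alps_sd_ad = 0), "alpsdti_invalid_config")
})
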