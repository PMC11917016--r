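# Diffusion tensor fitting and derived maps.
#
# The fit is the classical unweighted log-linear least-squares solution of
# ln(S) = ln(S0) - b g' D g per voxel, solved for all voxels at once by one
# QR factorisation of the shared design matrix. Axis diffusivity maps are the
# diagonals of the tensor after rotation into the world (RAS) frame, so that
# dxx/dyy/dzz always mean right-left / anterior-posterior / inferior-superior
# regardless of how the volume is stored on disk.

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves, per voxel, the linear model relating log-signal to the six unique
#' tensor components and log baseline signal. All weighted shells enter one
#' unweighted fit. Voxels with any non-positive signal are masked invalid
#' and left as zero tensors.
#'
#' @param dwi A `dwi_set` as produced by [simulate_dwi], or a list with
#'   `signals` (4-D array), `bvals`, `bvecs` (3 x n), `affine`.
#' @return A [tensor_field] with validity mask.
#' @export
fit_tensor <- function(dwi) {
  sig <- dwi$signals
  gs <- dim(sig)[1:3]
  nvol <- dim(sig)[4]
  if (nvol != length(dwi$bvals))
    abort("signal volumes must match bvals length", "alpsdti_validation_error")
  if (!any(dwi$bvals == 0))
    abort("at least one b=0 volume required", "alpsdti_insufficient_design")
  X <- dwi_design(dwi$bvals, as.matrix(dwi$bvecs))
  qrX <- qr(X)
  if (qrX$rank < 7L)
    abort("rank-deficient gradient design: need >= 6 non-collinear directions",
          "alpsdti_insufficient_design")
  smat <- matrix(sig, prod(gs), nvol)
  valid <- rowSums(smat <= 0) == 0L
  lower <- matrix(0, prod(gs), 6L)
  if (any(valid)) {
    beta <- qr.coef(qrX, t(log(smat[valid, , drop = FALSE])))
    # beta rows: ln S0, Dxx, Dxy, Dyy, Dxz, Dyz, Dzz
    lower[valid, ] <- t(beta[2:7, , drop = FALSE])
  }
  tensor_field(array(lower, c(gs, 6L)), dwi$affine, array(valid, gs))
}

# Vectorised eigenvalues of symmetric 3x3 tensors (rows of `low` in
# Dxx, Dxy, Dyy, Dxz, Dyz, Dzz order); trigonometric closed form.
# Returns a 3-column matrix, eigenvalues descending.
tensor_eigenvalues <- function(low) {
  a11 <- low[, 1L]; a12 <- low[, 2L]; a22 <- low[, 3L]
  a13 <- low[, 4L]; a23 <- low[, 5L]; a33 <- low[, 6L]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1e-300) * 1e3 | p == 0
  b11 <- (a11 - q); b22 <- (a22 - q); b33 <- (a33 - q)
  detb <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(iso, 0, pmin(pmax(detb / (2 * pmax(p, 1e-300)^3), -1), 1))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  out
}

# Fractional anisotropy from a 3-column eigenvalue matrix.
fa_from_eigenvalues <- function(ev) {
  m <- rowMeans(ev)
  num <- rowSums((ev - m)^2)
  den <- rowSums(ev^2)
  fa <- sqrt(1.5 * num / pmax(den, 1e-300))
  fa[den <= 0] <- 0
  pmin(fa, 1)
}

# Principal eigenvector (unit, arbitrary sign) per row, via the spectral
# projector (A - l2 I)(A - l3 I) whose column space is span(e1). Rows where
# the tensor is (near-)isotropic get a zero vector.
tensor_principal_evec <- function(low, ev) {
  a11 <- low[, 1L]; a12 <- low[, 2L]; a22 <- low[, 3L]
  a13 <- low[, 4L]; a23 <- low[, 5L]; a33 <- low[, 6L]
  l2 <- ev[, 2L]; l3 <- ev[, 3L]
  # C = (A - l2 I)(A - l3 I), symmetric; computed columnwise
  c1 <- cbind((a11 - l2) * (a11 - l3) + a12 * a12 + a13 * a13,
              a12 * (a11 - l3) + (a22 - l2) * a12 + a23 * a13,
              a13 * (a11 - l3) + a23 * a12 + (a33 - l2) * a13)
  c2 <- cbind((a11 - l2) * a12 + a12 * (a22 - l3) + a13 * a23,
              a12 * a12 + (a22 - l2) * (a22 - l3) + a23 * a23,
              a13 * a12 + a23 * (a22 - l3) + (a33 - l2) * a23)
  c3 <- cbind((a11 - l2) * a13 + a12 * a23 + a13 * (a33 - l3),
              a12 * a13 + (a22 - l2) * a23 + a23 * (a33 - l3),
              a13 * a13 + a23 * a23 + (a33 - l2) * (a33 - l3))
  n1 <- rowSums(c1^2); n2 <- rowSums(c2^2); n3 <- rowSums(c3^2)
  best <- max.col(cbind(n1, n2, n3), ties.method = "first")
  e <- c1
  e[best == 2L, ] <- c2[best == 2L, ]
  e[best == 3L, ] <- c3[best == 3L, ]
  nn <- sqrt(rowSums(e^2))
  e <- e / pmax(nn, 1e-300)
  e[nn <= 1e-300, ] <- 0
  e
}

#' Derive axis diffusivity, FA and color-FA maps from a tensor field
#'
#' Tensors are first rotated into the world RAS frame using the orthogonal
#' part of the affine; `dxx`/`dyy`/`dzz` are the rotated diagonals (raw,
#' unclamped — the ALPS index averages diagonals, not eigenvalues). FA is
#' computed from eigenvalues clamped to a small positive floor, as
#' sqrt(3/2) * sqrt(sum((l_i - lbar)^2) / sum(l_i^2)); the color-FA channels
#' are FA times the absolute principal-eigenvector components (red = x,
#' green = y, blue = z).
#'
#' @param tensors A [tensor_field].
#' @return A `diffusivity_maps` list: `dxx`, `dyy`, `dzz`, `fa` as
#'   [volume3d]; `color_fa` 4-D array (x, y, z, 3); `mask`; `affine`.
#' @export
diffusivity_maps <- function(tensors) {
  gs <- dim(tensors$lower)[1:3]
  if (abs(det(tensors$affine[1:3, 1:3])) < .Machine$double.eps)
    abort("non-invertible affine", "alpsdti_geometry_error")
  low <- matrix(tensors$lower, prod(gs), 6L)
  R <- affine_rotation(tensors$affine)
  if (max(abs(R - diag(3))) > 1e-12) {
    low <- rotate_tensor_components(low, R)
  }
  ev <- tensor_eigenvalues(low)
  evc <- pmax(ev, 1e-12) # clamp for FA only; diagonals stay raw
  fa <- fa_from_eigenvalues(evc)
  e1 <- tensor_principal_evec(low, ev)
  color <- abs(e1) * fa
  msk <- as.vector(tensors$mask)
  fa[!msk] <- 0
  color[!msk, ] <- 0
  af <- tensors$affine
  structure(list(
    dxx = volume3d(array(low[, 1L], gs), af),
    dyy = volume3d(array(low[, 3L], gs), af),
    dzz = volume3d(array(low[, 6L], gs), af),
    fa = volume3d(array(fa, gs), af),
    color_fa = array(color, c(gs, 3L)),
    mask = tensors$mask, affine = af
  ), class = "diffusivity_maps")
}

# Apply D_world = R D_vox R' to every row of the (n x 6) component matrix.
# The map is linear in the components; build its 6x6 matrix from the images
# of the six basis tensors under conjugation by R.
rotate_tensor_components <- function(low, R) {
  basis_idx <- list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(2, 3), c(3, 3))
  M <- matrix(0, 6L, 6L)
  for (b in seq_len(6L)) {
    E <- matrix(0, 3, 3)
    ij <- basis_idx[[b]]
    E[ij[1], ij[2]] <- 1
    E[ij[2], ij[1]] <- 1
    W <- R %*% E %*% t(R)
    M[, b] <- c(W[1, 1], W[1, 2], W[2, 2], W[1, 3], W[2, 3], W[3, 3])
  }
  low %*% t(M)
}
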