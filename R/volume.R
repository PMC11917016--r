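#' @keywords internal
"_PACKAGE"

# Condition helper: every package error carries a subclass so callers and
# tests can dispatch on the failure mode rather than on message text.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "alpsdti_error")))
}

#' 3-D scalar volume with a voxel-to-world affine
#'
#' The basic spatial container: a 3-D numeric array plus a 4x4 affine mapping
#' 0-based voxel indices (i, j, k) to world coordinates in millimetres
#' (RAS convention: +x right, +y anterior, +z superior).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; last row must be (0, 0, 0, 1).
#' @return An object of class `volume3d` with elements `data` and `affine`.
#' @export
volume3d <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    abort("volume3d data must be a 3-D array", "alpsdti_geometry_error")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    abort("affine must be an invertible 4x4 matrix", "alpsdti_geometry_error")
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x$affine), 4), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Voxel dimensions (mm) implied by an affine
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return Numeric length-3 vector of per-axis voxel sizes in mm.
#' @export
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map 0-based voxel indices to world mm
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
vox_to_world <- function(affine, ijk) {
  ijk <- rbind2mat(ijk)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' Map world mm to (fractional, 0-based) voxel indices
#'
#' @inheritParams vox_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world coordinates (mm).
#' @return n x 3 matrix of fractional voxel indices.
#' @export
world_to_vox <- function(affine, xyz) {
  xyz <- rbind2mat(xyz)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4])
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

# World coordinates of every voxel centre, as an (nvox x 3) matrix in
# column-major voxel order (i fastest). Shared by masks and phantom layout.
grid_world_coords <- function(dim3, affine) {
  i <- seq_len(dim3[1]) - 1
  j <- seq_len(dim3[2]) - 1
  k <- seq_len(dim3[3]) - 1
  ijk <- cbind(
    rep.int(i, times = dim3[2] * dim3[3]),
    rep.int(rep.int(j, times = dim3[3]), rep.int(dim3[1], dim3[2] * dim3[3])),
    rep.int(k, rep.int(dim3[1] * dim3[2], dim3[3]))
  )
  vox_to_world(affine, ijk)
}

# Orthogonal (rotation or rotation+flip) part of an affine via polar
# decomposition; exact for rotation-times-diagonal affines. A reflection is
# kept as-is: flipped storage axes must flip the tensor frame too.
affine_rotation <- function(affine) {
  s <- svd(affine[1:3, 1:3])
  s$u %*% t(s$v)
}
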