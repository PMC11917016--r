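# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package ships with the supported R stack, so the subset of the
# format this pipeline needs is implemented here: single-file .nii / .nii.gz,
# 3-D or 4-D, common datatypes, sform affine, scl_slope/scl_inter scaling,
# both endiannesses on read. Written files use float64, sform_code = 2,
# little-endian, and are readable by nibabel/FSL.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file `.nii` or `.nii.gz` image. 3-D images are returned as
#' a [volume3d]; 4-D images as a list with the 4-D `data` array and `affine`.
#' The sform affine is used when set, otherwise an affine is built from
#' `pixdim`. Data are scaled by `scl_slope`/`scl_inter` when present.
#'
#' @param path File path.
#' @return A [volume3d] (3-D) or list(data, affine) (4-D).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    abort(paste0("NIfTI file not found: ", path), "alpsdti_parse_error")
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    abort(paste0("truncated NIfTI header: ", path), "alpsdti_parse_error")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L)
      abort(paste0("not a NIfTI-1 file: ", path), "alpsdti_parse_error")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    abort(paste0("unsupported NIfTI magic '", magic, "': ", path),
          "alpsdti_parse_error")
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L)
    abort(paste0("only 3-D/4-D NIfTI supported, got ndim=", ndim),
          "alpsdti_parse_error")
  dims <- dim_field[2:(ndim + 1)]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    abort(paste0("unsupported NIfTI datatype ", datatype), "alpsdti_parse_error")
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n)
    abort(paste0("truncated NIfTI data: ", path), "alpsdti_parse_error")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(vals, dim = dims)
  if (ndim == 3L) volume3d(arr, affine) else list(data = arr, affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D array as a single-file NIfTI-1 image (gzipped when the
#' path ends in `.gz`), float64 storage, sform affine.
#'
#' @param x A [volume3d], or a list/array with `data` (3-D/4-D) and `affine`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine Optional 4x4 affine overriding the one in `x`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "volume3d") || (is.list(x) && !is.null(x$data))) {
    data <- x$data
    if (is.null(affine)) affine <- x$affine
  } else {
    data <- x
  }
  if (is.null(affine)) affine <- diag(4)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    abort("write_nifti supports 3-D or 4-D arrays", "alpsdti_geometry_error")
  dims <- dim(data)
  vs <- voxel_size(affine)

  hdr <- raw(348L)
  put <- function(off, vals, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(vals) else as.double(vals),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
    hdr
  }
  hdr <- put(0L, 348L, 4L)
  hdr <- put(40L, c(nd, dims, rep(1L, 7L - nd)), 2L)
  hdr <- put(70L, 64L, 2L)                 # datatype float64
  hdr <- put(72L, 64L, 2L)                 # bitpix
  hdr <- put(76L, c(1, vs, rep(1, 4)), 4L, "double")
  hdr <- put(108L, 352, 4L, "double")      # vox_offset
  hdr <- put(112L, 1, 4L, "double")        # scl_slope
  hdr <- put(116L, 0, 4L, "double")        # scl_inter
  hdr <- put(252L, 0L, 2L)                 # qform_code
  hdr <- put(254L, 2L, 2L)                 # sform_code: aligned
  hdr <- put(280L, t(affine[1:3, ]), 4L, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # no extensions
  writeBin(as.double(data), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read FSL-style bvals/bvecs gradient tables
#'
#' `bvals` is one whitespace-separated row of b-values (s/mm^2); `bvecs` is
#' three rows (x, y, z components, one column per volume).
#'
#' @param bvals_path,bvecs_path File paths.
#' @return list with `bvals` (numeric) and `bvecs` (3 x n matrix).
#' @export
read_gradients <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, what = double(), quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) != 3L && ncol(bv) == 3L) bv <- t(bv)
  if (nrow(bv) != 3L || ncol(bv) != length(bvals))
    abort("bvecs must be 3 x n matching bvals length", "alpsdti_parse_error")
  dimnames(bv) <- NULL
  list(bvals = bvals, bvecs = bv)
}

#' Write FSL-style bvals/bvecs gradient tables
#'
#' @param bvals Numeric b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions.
#' @param bvals_path,bvecs_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradients <- function(bvals, bvecs, bvals_path, bvecs_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvals_path)
  writeLines(apply(bvecs, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Read a 4x4 world-to-world transform from a text file
#'
#' Plain text, 4 rows x 4 columns (FSL/ANTs-style matrix text). The string
#' `"identity"` returns the identity transform.
#'
#' @param path File path or `"identity"`.
#' @return 4x4 matrix.
#' @export
read_transform <- function(path) {
  if (identical(path, "identity")) return(diag(4))
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L)))
    abort("transform file must contain a 4x4 matrix", "alpsdti_parse_error")
  m
}
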