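# Spherical ROIs and the ALPS (along-the-perivascular-space) index.
#
# ALPS = (meanDxx_projection + meanDxx_association) /
#        (meanDyy_projection + meanDzz_association)
# computed per hemisphere from four 5 mm spheres placed in the
# periventricular white matter; the combined index is the mean of the two
# hemispheric indices.

#' Spherical ROI specification
#'
#' @param side `"left"` or `"right"`.
#' @param fiber `"projection"` or `"association"`.
#' @param center_mm World-mm centre (DTI space).
#' @param radius_mm Sphere radius, default 5 mm.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(side, fiber, center_mm, radius_mm = 5) {
  side <- match.arg(side, c("left", "right"))
  fiber <- match.arg(fiber, c("projection", "association"))
  if (radius_mm <= 0)
    abort("radius must be positive", "alpsdti_invalid_config")
  if (length(center_mm) != 3L || !all(is.finite(center_mm)))
    abort("center_mm must be 3 finite coordinates", "alpsdti_invalid_config")
  structure(list(side = side, fiber = fiber,
                 center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "roi_spec")
}

#' Build the standard four-ROI set from per-hemisphere centres
#'
#' @param centers Nested list `centers$left$projection`, etc., of world-mm
#'   coordinates (the layout produced in a phantom truth manifest).
#' @param radius_mm Sphere radius.
#' @return List of four [roi_spec] objects.
#' @export
roi_set_from_centers <- function(centers, radius_mm = 5) {
  out <- list()
  for (sd in c("right", "left"))
    for (fb in c("projection", "association"))
      out[[length(out) + 1L]] <-
        roi_spec(sd, fb, centers[[sd]][[fb]], radius_mm)
  out
}

#' Voxel mask of a world-space sphere
#'
#' A voxel belongs to the sphere when its world-space centre lies within
#' `radius_mm` of `center_mm`, boundary inclusive. Distances are measured in
#' world mm through the affine, so anisotropic voxels are handled correctly.
#'
#' @param geom A [volume3d], or a list with `dim` (length-3) and `affine`.
#' @param center_mm Sphere centre, world mm.
#' @param radius_mm Sphere radius, mm.
#' @return Logical 3-D array; attribute `empty` is TRUE when no voxel falls
#'   inside (sphere outside the grid), flagged with a warning.
#' @export
sphere_mask <- function(geom, center_mm, radius_mm) {
  if (inherits(geom, "volume3d")) geom <- list(dim = dim(geom$data),
                                               affine = geom$affine)
  if (!all(is.finite(center_mm)) || radius_mm <= 0)
    abort("sphere centre must be finite and radius positive",
          "alpsdti_invalid_config")
  dim3 <- geom$dim
  co <- grid_world_coords(dim3, geom$affine)
  d2 <- (co[, 1] - center_mm[1])^2 + (co[, 2] - center_mm[2])^2 +
    (co[, 3] - center_mm[3])^2
  m <- array(d2 <= radius_mm^2, dim3)
  if (!any(m)) {
    warning("sphere mask is empty (ROI outside grid)")
    attr(m, "empty") <- TRUE
  } else attr(m, "empty") <- FALSE
  m
}

#' Mean of a map over a voxel mask
#'
#' @param map A [volume3d] (or bare 3-D array).
#' @param mask Logical array of the same shape.
#' @return Arithmetic mean over masked voxels; `NA` for an empty mask (the
#'   undefined-side convention).
#' @export
roi_mean <- function(map, mask) {
  data <- if (inherits(map, "volume3d")) map$data else map
  if (!any(mask)) return(NA_real_)
  mean(data[mask])
}

#' The ALPS index from the four regional mean diffusivities
#'
#' @param x_proj,x_assoc Mean x-axis diffusivity in the projection- and
#'   association-fiber spheres (mm^2/s).
#' @param y_proj Mean y-axis diffusivity in the projection sphere.
#' @param z_assoc Mean z-axis diffusivity in the association sphere.
#' @return `(x_proj + x_assoc) / (y_proj + z_assoc)`, dimensionless.
#' @export
alps_index <- function(x_proj, x_assoc, y_proj, z_assoc) {
  den <- y_proj + z_assoc
  if (!is.na(den) && den <= 0)
    abort("ALPS index undefined: non-positive denominator",
          "alpsdti_undefined_index")
  (x_proj + x_assoc) / den
}

#' Compute hemispheric and combined ALPS indices from diffusivity maps
#'
#' For each hemisphere, averages `dxx` over the projection and association
#' spheres, `dyy` over the projection sphere and `dzz` over the association
#' sphere, then forms the ALPS ratio. The combined index is the mean of the
#' two hemispheric indices; if either hemisphere is undefined (empty ROI)
#' the combined index is reported missing, never as the surviving side.
#'
#' @param maps A `diffusivity_maps` object ([diffusivity_maps]).
#' @param rois List of four [roi_spec]s, one per (side, fiber) pair.
#' @return An `alps_result` list: per-side means (`x_proj`, `x_assoc`,
#'   `y_proj`, `z_assoc`), `alps_r`, `alps_l`, `alps_comb`,
#'   `roi_voxel_counts`.
#' @export
compute_alps <- function(maps, rois) {
  key <- vapply(rois, function(r) paste(r$side, r$fiber), character(1))
  need <- c("right projection", "right association",
            "left projection", "left association")
  if (!setequal(key, need) || anyDuplicated(key))
    abort("need exactly one ROI per (side, fiber) pair",
          "alpsdti_roi_spec_error")
  geom <- list(dim = dim(maps$dxx$data), affine = maps$affine)
  byname <- stats::setNames(rois, key)
  sides <- list()
  counts <- integer(0)
  for (sd in c("right", "left")) {
    rp <- byname[[paste(sd, "projection")]]
    ra <- byname[[paste(sd, "association")]]
    mp <- suppressWarnings(sphere_mask(geom, rp$center_mm, rp$radius_mm))
    ma <- suppressWarnings(sphere_mask(geom, ra$center_mm, ra$radius_mm))
    sides[[sd]] <- list(
      x_proj = roi_mean(maps$dxx, mp), x_assoc = roi_mean(maps$dxx, ma),
      y_proj = roi_mean(maps$dyy, mp), z_assoc = roi_mean(maps$dzz, ma))
    counts[paste0(sd, "_projection")] <- sum(mp)
    counts[paste0(sd, "_association")] <- sum(ma)
  }
  idx <- lapply(sides, function(s) {
    if (anyNA(unlist(s))) NA_real_
    else alps_index(s$x_proj, s$x_assoc, s$y_proj, s$z_assoc)
  })
  alps_r <- idx$right
  alps_l <- idx$left
  structure(list(
    means = sides,
    alps_r = alps_r, alps_l = alps_l,
    alps_comb = if (is.na(alps_r) || is.na(alps_l)) NA_real_
                else (alps_r + alps_l) / 2,
    roi_voxel_counts = counts
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> R %.4f  L %.4f  comb %.4f\n",
              x$alps_r, x$alps_l, x$alps_comb))
  invisible(x)
}

#' Read ROI specifications from JSON
#'
#' Schema: a JSON array of objects with fields `subject_id` (optional),
#' `side`, `fiber`, `center_mm` (length-3) and `radius_mm` (default 5).
#'
#' @param path JSON file path.
#' @return Named list (by subject id, `"default"` when absent) of lists of
#'   [roi_spec].
#' @export
read_roi_json <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- list()
  for (e in entries) {
    sid <- if (is.null(e$subject_id)) "default" else e$subject_id
    r <- roi_spec(e$side, e$fiber, unlist(e$center_mm),
                  if (is.null(e$radius_mm)) 5 else e$radius_mm)
    out[[sid]] <- c(out[[sid]], list(r))
  }
  out
}

#' Write ROI specifications to JSON
#'
#' @param roi_sets Named list (by subject id) of lists of [roi_spec].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi_sets, path) {
  rows <- list()
  for (sid in names(roi_sets))
    for (r in roi_sets[[sid]])
      rows[[length(rows) + 1L]] <- list(
        subject_id = sid, side = r$side, fiber = r$fiber,
        center_mm = r$center_mm, radius_mm = r$radius_mm)
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
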