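# White-matter-hyperintensity quantification inside and outside the ALPS
# ROIs. Lesion-probability maps (FLAIR space) are thresholded, ROI centres
# are carried from DTI space to FLAIR space through a supplied world-to-world
# transform, 5 mm spheres are rebuilt around the transformed centres on the
# FLAIR grid, and intersecting lesion voxels are counted. Any lesion voxel in
# any of the four spheres marks the subject excluded from the main analyses.

#' Threshold a lesion-probability map
#'
#' @param prob A [volume3d] with values in `[0, 1]`.
#' @param threshold Inclusive threshold, default 0.5 (the usual convention
#'   for lesion-segmentation probability maps).
#' @return A `lesion_map` list: `probability` (the input volume), `binary`
#'   logical array, `threshold`.
#' @export
binarize_lesions <- function(prob, threshold = 0.5) {
  p <- prob$data
  if (min(p) < 0 || max(p) > 1)
    abort("lesion probabilities must lie in [0, 1]", "alpsdti_validation_error")
  structure(list(probability = prob, binary = p >= threshold,
                 threshold = threshold), class = "lesion_map")
}

#' Map a DTI-space ROI centre into FLAIR space
#'
#' @param center_mm_dti World-mm coordinate in DTI space.
#' @param transform 4x4 DTI-world to FLAIR-world matrix (identity for
#'   co-registered data).
#' @return World-mm coordinate in FLAIR space.
#' @export
map_roi_to_flair <- function(center_mm_dti, transform = diag(4)) {
  if (abs(det(transform)) < .Machine$double.eps)
    abort("singular DTI-to-FLAIR transform", "alpsdti_geometry_error")
  drop(transform[1:3, 1:3] %*% center_mm_dti + transform[1:3, 4])
}

#' Count WMH voxels inside the ALPS ROI spheres
#'
#' Builds each ROI sphere in FLAIR space (mm radius around the transformed
#' centre, FLAIR voxel geometry) and counts binary lesion voxels inside.
#' Reports per-ROI counts and volumes, per-side and combined totals, the
#' any-lesion exclusion flag, and the lesion load outside all ROI spheres
#' (volume plus 26-connected component count).
#'
#' @param lesions A `lesion_map` from [binarize_lesions].
#' @param rois List of four [roi_spec]s (DTI-space centres).
#' @param transform 4x4 DTI-world to FLAIR-world matrix.
#' @return A `wmh_roi_report` list: `per_roi` data frame (side, fiber,
#'   count, volume_mm3), `wmh_r`, `wmh_l`, `wmh_comb` (volumes, mm3),
#'   `excluded`, `global_wmh_volume_mm3`, `global_wmh_count`,
#'   `total_wmh_volume_mm3`.
#' @export
wmh_in_roi <- function(lesions, rois, transform = diag(4)) {
  vol <- lesions$probability
  geom <- list(dim = dim(vol$data), affine = vol$affine)
  voxvol <- prod(voxel_size(vol$affine))
  bin <- lesions$binary
  in_any_roi <- array(FALSE, geom$dim)
  per <- data.frame(side = character(0), fiber = character(0),
                    count = integer(0), volume_mm3 = double(0))
  for (r in rois) {
    cf <- map_roi_to_flair(r$center_mm, transform)
    m <- suppressWarnings(sphere_mask(geom, cf, r$radius_mm))
    cnt <- sum(bin & m)
    in_any_roi <- in_any_roi | m
    per <- rbind(per, data.frame(side = r$side, fiber = r$fiber,
                                 count = cnt, volume_mm3 = cnt * voxvol))
  }
  wmh_r <- sum(per$volume_mm3[per$side == "right"])
  wmh_l <- sum(per$volume_mm3[per$side == "left"])
  outside <- bin & !in_any_roi
  structure(list(
    per_roi = per,
    wmh_r = wmh_r, wmh_l = wmh_l, wmh_comb = wmh_r + wmh_l,
    excluded = sum(per$count) > 0L,
    global_wmh_volume_mm3 = sum(outside) * voxvol,
    global_wmh_count = count_components_26(outside),
    total_wmh_volume_mm3 = sum(bin) * voxvol
  ), class = "wmh_roi_report")
}

# Number of 26-connected components of a logical 3-D array. Breadth-first
# labelling over the foreground voxels only; intended for sparse lesion
# masks, not whole-brain segmentations.
count_components_26 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * (d[1] * d[2]) + (pos[, 2] - 1) * d[1] + pos[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  visited <- logical(length(idx))
  ncomp <- 0L
  for (i in seq_along(idx)) {
    if (visited[i]) next
    ncomp <- ncomp + 1L
    queue <- i
    visited[i] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      p <- pos[cur, ]
      for (n in seq_len(nrow(nb))) {
        q <- p + nb[n, ]
        if (any(q < 1L) || any(q > d)) next
        k <- as.character((q[3] - 1) * (d[1] * d[2]) + (q[2] - 1) * d[1] + q[1])
        j <- lookup[[k]]
        if (!is.null(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}

#' Split subjects into clean and WMH-contaminated subsets
#'
#' @param reports Named list of `wmh_roi_report`s, one per subject.
#' @return List with `clean` and `contaminated` character vectors of subject
#'   ids (disjoint, exhaustive) and `sizes`.
#' @export
partition_cohort <- function(reports) {
  excl <- vapply(reports, function(r) isTRUE(r$excluded), logical(1))
  ids <- names(reports)
  if (is.null(ids)) ids <- as.character(seq_along(reports))
  list(clean = ids[!excl], contaminated = ids[excl],
       sizes = c(clean = sum(!excl), contaminated = sum(excl)))
}
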