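# End-to-end orchestration: one configuration drives simulate (or ingest) ->
# tensor fit -> diffusivity maps -> ALPS -> WMH-in-ROI -> exclusion
# partition -> cohort statistics, with a reproducibility manifest recording
# subject counts at every filter step and checksums of every written file.

#' Build and validate a pipeline run configuration
#'
#' @param mode `"synthetic"` (phantom cohort simulated in-process) or
#'   `"files"` (NIfTI/JSON/CSV inputs on disk).
#' @param out_dir Output directory (created).
#' @param seed Integer seed (required in synthetic mode).
#' @param n_ad,n_hc Synthetic group sizes.
#' @param n_contaminated Number of subjects receiving a WMH lesion inside
#'   the left projection ROI.
#' @param grid_shape,voxel_size_mm Phantom grid (kept small by default so a
#'   full run stays interactive).
#' @param rician_sigma DWI noise scale (0 = noise-free).
#' @param s0 Baseline signal.
#' @param lesion_threshold Lesion-probability threshold.
#' @param abeta_cutoff Amyloid cutoff for classification.
#' @param cohort Optional [cohort_config] overriding the defaults.
#' @param paths In file mode: named list with `subject_table`, `roi_json`,
#'   and per-subject `dwi`, `bvals`, `bvecs`, `lesion_prob`, `transform`.
#' @param write_volumes Write per-subject NIfTI maps (slower; default off).
#' @return A validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"), out_dir, seed = 1L,
                       n_ad = 16L, n_hc = 18L, n_contaminated = 2L,
                       grid_shape = c(32L, 32L, 32L),
                       voxel_size_mm = c(2, 2, 2),
                       rician_sigma = 0, s0 = 1000,
                       lesion_threshold = 0.5, abeta_cutoff = 0.05,
                       cohort = NULL, paths = NULL, write_volumes = FALSE) {
  mode <- match.arg(mode)
  if (mode == "synthetic" && is.null(seed))
    abort("synthetic mode requires a seed", "alpsdti_invalid_config")
  if (mode == "files") {
    if (is.null(paths))
      abort("file mode requires input paths", "alpsdti_invalid_config")
    for (p in unlist(paths))
      if (!identical(p, "identity") && !file.exists(p))
        abort(paste0("input path does not exist: ", p),
              "alpsdti_invalid_config")
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
                 n_contaminated = as.integer(n_contaminated),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 rician_sigma = rician_sigma, s0 = s0,
                 lesion_threshold = lesion_threshold,
                 abeta_cutoff = abeta_cutoff, cohort = cohort,
                 paths = paths, write_volumes = write_volumes),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  do.call(run_config, j)
}

#' Run the full ALPS analysis pipeline
#'
#' In synthetic mode: draws a cohort table, builds one phantom per subject
#' with `glymph_x` equal to the subject's true ALPS index, simulates DWI,
#' injects a periventricular lesion into the first `n_contaminated`
#' subjects, fits tensors, computes ALPS and the WMH-in-ROI report, applies
#' the any-lesion exclusion rule, and runs the group statistics on the clean
#' subset (ANCOVA adjusted for age and sex; Mann-Whitney U on the CDR
#' split) and the ALPS-vs-ROI-WMH regression on the contaminated subset
#' when it is large enough. All tables plus a manifest are written under
#' `config$out_dir`; re-running with the same config and seed reproduces
#' byte-identical tables.
#'
#' @param config A [run_config].
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (config$mode == "synthetic") {
    res <- pipeline_synthetic(config)
  } else {
    res <- pipeline_files(config)
  }
  subjects <- res$subjects
  reports <- res$reports

  part <- partition_cohort(reports)
  subjects$excluded <- subjects$id %in% part$contaminated
  labels <- suppressMessages(
    classify_subjects(subjects, cutoff = config$abeta_cutoff))
  subjects$group <- labels
  n_unclassified <- sum(is.na(labels))
  clean <- subjects[!subjects$excluded & !is.na(subjects$group), ]
  contaminated <- subjects[subjects$excluded & !is.na(subjects$group), ]
  for (s in part$contaminated)
    message("excluded (WMH in ROI): ", s)

  stats_out <- list()
  if (length(unique(clean$group)) == 2L &&
      min(table(clean$group)) >= 3L) {
    anc <- ancova_group(clean, "alps_meas_comb", "group", c("age", "sex"))
    stats_out$group_difference <- list(
      mean_ad = anc$mean_1, sd_ad = anc$sd_1, n_ad = anc$n_1,
      mean_hc = anc$mean_2, sd_hc = anc$sd_2, n_hc = anc$n_2,
      p = anc$p, cohens_d = anc$cohens_d)
    cs <- dichotomize(clean, "cdr_global", "cdr")
    mw <- mann_whitney_u(clean$alps_meas_comb[cs == "low"],
                         clean$alps_meas_comb[cs == "high"])
    stats_out$cdr_split <- list(U = mw$U, p = mw$p, method = mw$method)
  }
  if (nrow(contaminated) >= 5L) {
    contaminated$log_wmh <- log_transform_wmh(contaminated$wmh_comb)
    reg <- linreg_standardized(contaminated, "alps_meas_comb", "log_wmh")
    stats_out$wmh_in_roi_regression <-
      list(beta = reg$beta, se = reg$se, p = reg$p,
           adj_r_squared = reg$adj_r_squared, n = reg$n)
  }

  subj_path <- file.path(config$out_dir, "subjects.csv")
  write_table_csv(subjects, subj_path)
  alps_path <- file.path(config$out_dir, "alps.tsv")
  write_alps_tsv(res$alps_results, alps_path)
  wmh_path <- file.path(config$out_dir, "wmh.tsv")
  write_wmh_tsv(reports, wmh_path)
  stats_path <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE, digits = NA)

  files <- c(subj_path, alps_path, wmh_path, stats_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("alpsdti")),
    seed = config$seed,
    counts = list(
      total = nrow(subjects),
      classified = nrow(subjects) - n_unclassified,
      unclassified_dropped = n_unclassified,
      wmh_excluded = length(part$contaminated),
      analyzed = nrow(clean)),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

# Synthetic branch: phantom + DWI per subject; measured ALPS replaces the
# drawn value as the analysis outcome.
pipeline_synthetic <- function(config) {
  ccfg <- config$cohort
  if (is.null(ccfg))
    ccfg <- cohort_config(n_ad = config$n_ad, n_hc = config$n_hc,
                          abeta_cutoff = config$abeta_cutoff,
                          seed = config$seed)
  subjects <- generate_cohort(ccfg)
  grad <- default_gradients()
  reports <- list()
  alps_results <- list()
  meas <- matrix(NA_real_, nrow(subjects), 3L)
  for (i in seq_len(nrow(subjects))) {
    pcfg <- phantom_config(grid_shape = config$grid_shape,
                           voxel_size_mm = config$voxel_size_mm,
                           glymph_x = max(subjects$alps_true[i], 0.2),
                           s0 = config$s0,
                           rician_sigma = config$rician_sigma,
                           seed = config$seed + i)
    ph <- generate_phantom(pcfg)
    flair <- volume3d(array(1, config$grid_shape), ph$tensors$affine)
    prob <- volume3d(array(0, config$grid_shape), ph$tensors$affine)
    tensors <- ph$tensors
    if (i <= config$n_contaminated) {
      les <- lesion_spec(ph$truth$roi_centers_mm$left$projection,
                         semi_axes_mm = 3, lesion_md = 1.2e-3)
      inj <- inject_wmh(tensors, flair, prob, list(les))
      tensors <- inj$tensors
      prob <- inj$prob_map
    }
    dwi <- simulate_dwi(tensors, grad$bvals, grad$bvecs, s0 = config$s0,
                        rician_sigma = config$rician_sigma,
                        seed = config$seed + i)
    maps <- diffusivity_maps(fit_tensor(dwi))
    rois <- roi_set_from_centers(ph$truth$roi_centers_mm)
    ares <- compute_alps(maps, rois)
    lmap <- binarize_lesions(prob, config$lesion_threshold)
    rep_i <- wmh_in_roi(lmap, rois, diag(4))
    sid <- subjects$id[i]
    alps_results[[sid]] <- ares
    reports[[sid]] <- rep_i
    meas[i, ] <- c(ares$alps_r, ares$alps_l, ares$alps_comb)
    subjects$wmh_comb[i] <- rep_i$wmh_comb
    if (config$write_volumes) {
      sdir <- file.path(config$out_dir, "volumes")
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      write_nifti(maps$dxx, file.path(sdir, paste0(sid, "_dxx.nii.gz")))
      write_nifti(maps$fa, file.path(sdir, paste0(sid, "_fa.nii.gz")))
    }
  }
  subjects$alps_meas_r <- meas[, 1]
  subjects$alps_meas_l <- meas[, 2]
  subjects$alps_meas_comb <- meas[, 3]
  list(subjects = subjects, reports = reports, alps_results = alps_results)
}

# File branch: per-subject DWI + lesion maps listed in a subject table.
pipeline_files <- function(config) {
  p <- config$paths
  subjects <- read_table_csv(p$subject_table)
  if (is.null(subjects$wmh_comb)) subjects$wmh_comb <- NA_real_
  roi_sets <- read_roi_json(p$roi_json)
  reports <- list()
  alps_results <- list()
  meas <- matrix(NA_real_, nrow(subjects), 3L)
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$id[i]
    rois <- roi_sets[[sid]]
    if (is.null(rois)) rois <- roi_sets[["default"]]
    if (is.null(rois))
      abort(paste0("no ROI set for subject ", sid), "alpsdti_roi_spec_error")
    dwi_img <- read_nifti(subjects$dwi[i])
    grad <- read_gradients(subjects$bvals[i], subjects$bvecs[i])
    dwi <- list(signals = dwi_img$data, bvals = grad$bvals,
                bvecs = grad$bvecs, affine = dwi_img$affine)
    maps <- diffusivity_maps(fit_tensor(dwi))
    ares <- compute_alps(maps, rois)
    prob <- read_nifti(subjects$lesion_prob[i])
    xfm <- if (is.null(subjects$transform) ||
               subjects$transform[i] == "identity") diag(4)
           else read_transform(subjects$transform[i])
    lmap <- binarize_lesions(prob, config$lesion_threshold)
    rep_i <- wmh_in_roi(lmap, rois, xfm)
    alps_results[[sid]] <- ares
    reports[[sid]] <- rep_i
    meas[i, ] <- c(ares$alps_r, ares$alps_l, ares$alps_comb)
    subjects$wmh_comb[i] <- rep_i$wmh_comb
  }
  subjects$alps_meas_r <- meas[, 1]
  subjects$alps_meas_l <- meas[, 2]
  subjects$alps_meas_comb <- meas[, 3]
  list(subjects = subjects, reports = reports, alps_results = alps_results)
}

#' Write/read a subject table (CSV, missingness-preserving)
#'
#' @param table Data frame.
#' @param path File path.
#' @return The path (write) or data frame (read).
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}

write_alps_tsv <- function(alps_results, path) {
  rows <- lapply(names(alps_results), function(sid) {
    a <- alps_results[[sid]]
    data.frame(id = sid,
               x_proj_r = a$means$right$x_proj, x_assoc_r = a$means$right$x_assoc,
               y_proj_r = a$means$right$y_proj, z_assoc_r = a$means$right$z_assoc,
               x_proj_l = a$means$left$x_proj, x_assoc_l = a$means$left$x_assoc,
               y_proj_l = a$means$left$y_proj, z_assoc_l = a$means$left$z_assoc,
               alps_r = a$alps_r, alps_l = a$alps_l, alps_comb = a$alps_comb)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_wmh_tsv <- function(reports, path) {
  rows <- lapply(names(reports), function(sid) {
    r <- reports[[sid]]
    data.frame(id = sid, wmh_r = r$wmh_r, wmh_l = r$wmh_l,
               wmh_comb = r$wmh_comb, excluded = r$excluded,
               global_wmh_volume_mm3 = r$global_wmh_volume_mm3,
               global_wmh_count = r$global_wmh_count)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
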