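# End-to-end orchestration: simulate -> quantify -> scalar stats -> SUVR ->
# voxel-wise stats, with on-disk artifacts (NIfTI / TSV / YAML / JSON) and
# seeded determinism.

roi_file_names <- c("search_roi_left", "search_roi_right", "background_roi",
                    "brain_mask", "reference_region", "analysis_mask")

#' Write a simulated phantom cohort to disk
#'
#' Emits NM volumes (`nm_<id>.nii.gz`), PET volumes (`pet_<id>.nii.gz`),
#' masks under `masks/`, the covariate TSV, a YAML ground-truth sidecar
#' and a JSON manifest with seed, version and per-file MD5 checksums.
#'
#' @param config a [phantom_config()] (or an `lc_cohort` already
#'   generated).
#' @param out_dir output directory (created if needed).
#' @return the cohort (invisibly); side effect: files in `out_dir`.
#' @export
run_simulation <- function(config, out_dir) {
  cohort <- if (inherits(config, "lc_cohort")) config
            else generate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  cfg <- cohort$config

  write.table(cohort$subjects, file.path(out_dir, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$nm))
    write_volume(cohort$nm[[id]],
                 file.path(out_dir, sprintf("nm_%s.nii.gz", id)))
  for (id in names(cohort$pet))
    write_volume(cohort$pet[[id]],
                 file.path(out_dir, sprintf("pet_%s.nii.gz", id)))
  for (nm in roi_file_names)
    write_volume(cohort$rois[[nm]],
                 file.path(out_dir, "masks", paste0(nm, ".nii.gz")))

  truth <- cohort$truth
  yaml::write_yaml(list(
    true_contrast = truth$true_contrast,
    latent_score = as.list(truth$latent_score),
    cluster_center = as.integer(truth$cluster_center),
    cluster_amplitude = as.numeric(truth$cluster_amplitude),
    slice_gains = apply(truth$slice_gains, 2, as.numeric,
                        simplify = FALSE)),
    file.path(out_dir, "ground_truth.yaml"))
  write_volume(truth$cluster_mask, file.path(out_dir, "masks",
               "true_cluster.nii.gz"),
               voxel_size_mm = cfg$voxel_size_mm)

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("lcnm")),
    n_subjects = nrow(cohort$subjects),
    grid_shape = cfg$grid_shape,
    voxel_size_mm = cfg$voxel_size_mm,
    md5 = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

# load a cohort written by run_simulation (images + masks + covariates)
read_cohort_dir <- function(dir) {
  cov_path <- file.path(dir, "covariates.tsv")
  if (!file.exists(cov_path))
    stop("missing covariates.tsv in ", dir, call. = FALSE)
  subjects <- read.delim(cov_path, stringsAsFactors = FALSE)
  rois <- lapply(setNames(roi_file_names, roi_file_names), function(nm)
    read_volume(file.path(dir, "masks", paste0(nm, ".nii.gz"))))
  nm_files <- file.path(dir, sprintf("nm_%s.nii.gz", subjects$subject_id))
  nm <- setNames(lapply(nm_files, read_volume), subjects$subject_id)
  pet_files <- file.path(dir, sprintf("pet_%s.nii.gz", subjects$subject_id))
  has_pet <- file.exists(pet_files)
  pet <- setNames(lapply(pet_files[has_pet], read_volume),
                  subjects$subject_id[has_pet])
  list(subjects = subjects, nm = nm, pet = pet, rois = rois)
}

#' Quantify LC contrast for every subject of a cohort
#'
#' @param cohort an `lc_cohort` (or the list returned by the internal
#'   directory reader): needs `nm` volumes and `rois`.
#' @param ... passed to [quantify_subject()].
#' @return list with `results` (per-subject `lc_contrast` objects),
#'   `long` (the [contrast_table()]) and `wide` (subject x subregion
#'   left/right-averaged contrasts).
#' @export
quantify_cohort <- function(cohort, ...) {
  results <- lapply(cohort$nm, quantify_subject, rois = cohort$rois, ...)
  long <- contrast_table(results)
  avg <- long[long$side == "avg", ]
  wide <- data.frame(subject_id = unique(avg$subject_id),
                     stringsAsFactors = FALSE)
  for (reg in c("rostral", "middle", "caudal"))
    wide[[reg]] <- avg$contrast[avg$subregion == reg][
      match(wide$subject_id, avg$subject_id[avg$subregion == reg])]
  list(results = results, long = long, wide = wide)
}

#' Run the full statistical analysis on a cohort
#'
#' Quantifies sub-regional LC contrast for every subject, runs the
#' per-subregion permutation omnibus (age covariate) with gated one-
#' tailed post hocs, Levene and descriptive tests, Spearman correlations
#' between contrasts and education-adjusted MoCA in the patient groups,
#' and - when PET volumes are present - SUVR conversion, smoothing and
#' cluster-FWE association mapping against MoCA (primary threshold) and
#' rostral LC contrast (exploratory threshold).
#'
#' @param input an `lc_cohort` object or a directory written by
#'   [run_simulation()].
#' @param out_dir optional output directory; when given, writes
#'   `contrasts.tsv`, `results.json`, cluster TSVs, t-map NIfTIs and a
#'   plain-text `report.txt`.
#' @param n_perm permutations for scalar tests (default 10000).
#' @param n_perm_voxel permutations for cluster-level FWE (default 1000).
#' @param seed integer seed; every random step derives from it and is
#'   recorded in the outputs.
#' @param alpha significance threshold (default 0.05).
#' @param cluster_forming_p primary voxel-level threshold (default
#'   0.001).
#' @param exploratory_p exploratory voxel-level threshold (default 0.01).
#' @param fwhm_mm PET smoothing kernel (default 8 mm).
#' @param gate_posthoc run post hocs only after a significant omnibus
#'   (default TRUE).
#' @param ... passed to [quantify_subject()].
#' @return results list of class `lc_report` (invisibly when `out_dir`
#'   is given).
#' @export
run_analysis <- function(input, out_dir = NULL, n_perm = 10000L,
                         n_perm_voxel = 1000L, seed = 1L, alpha = 0.05,
                         cluster_forming_p = 0.001, exploratory_p = 0.01,
                         fwhm_mm = 8, gate_posthoc = TRUE, ...) {
  cohort <- if (is.character(input)) read_cohort_dir(input) else input
  subjects <- cohort$subjects
  subjects$moca_adj <- adjust_moca(subjects$moca_raw,
                                   subjects$education_years)
  q <- quantify_cohort(cohort, ...)
  dat <- merge(subjects, q$wide, by = "subject_id", sort = TRUE)
  dat <- dat[order(dat$subject_id), ]
  subregions <- c("rostral", "middle", "caudal")

  group_results <- list()
  for (i in seq_along(subregions)) {
    reg <- subregions[i]
    y <- dat[[reg]]
    lev <- levene_test(y, dat$group)
    omni <- permutation_ancova(y, dat$group, covariates = dat$age,
                               n_perm = n_perm, seed = seed + i)
    ph <- NULL
    posthoc_run <- !gate_posthoc || omni$p < alpha
    if (posthoc_run)
      ph <- posthoc_pairwise(y, dat$group, covariates = dat$age,
                             n_perm = n_perm, seed = seed + 100L + i)
    group_results[[reg]] <- list(levene = lev, omnibus = omni,
                                 posthoc = ph, posthoc_run = posthoc_run)
  }

  correlations <- list()
  patient_groups <- setdiff(unique(dat$group), "HC")
  corr_sets <- c(as.list(patient_groups),
                 list(patients_combined = patient_groups))
  names(corr_sets) <- c(patient_groups, "patients_combined")
  for (nm in names(corr_sets)) {
    sel <- dat$group %in% corr_sets[[nm]]
    if (sum(sel) < 3L) next
    correlations[[nm]] <- lapply(setNames(subregions, subregions),
      function(reg) spearman_corr(dat[[reg]][sel], dat$moca_adj[sel]))
  }

  descriptives <- descriptive_tests(dat)

  voxelwise <- NULL
  if (length(cohort$pet)) {
    pet_ids <- names(cohort$pet)
    pdat <- dat[match(pet_ids, dat$subject_id), ]
    suvr <- lapply(cohort$pet, function(v)
      smooth_gaussian(compute_suvr(v, cohort$rois$reference_region),
                      fwhm_mm = fwhm_mm))
    amask <- cohort$rois$analysis_mask != 0
    ct_moca <- cluster_fwe(suvr, pdat$moca_adj, mask = amask,
                           cluster_forming_p = cluster_forming_p,
                           n_perm = n_perm_voxel, seed = seed + 201L)
    ct_rostral <- cluster_fwe(suvr, pdat$rostral, mask = amask,
                              cluster_forming_p = exploratory_p,
                              n_perm = n_perm_voxel, seed = seed + 202L)
    voxelwise <- list(moca = ct_moca, rostral_exploratory = ct_rostral,
                      pet_ids = pet_ids, fwhm_mm = fwhm_mm)
  }

  report <- structure(list(
    data = dat, contrasts_long = q$long,
    group_results = group_results, correlations = correlations,
    descriptives = descriptives, voxelwise = voxelwise,
    settings = list(n_perm = n_perm, n_perm_voxel = n_perm_voxel,
                    seed = seed, alpha = alpha,
                    cluster_forming_p = cluster_forming_p,
                    exploratory_p = exploratory_p, fwhm_mm = fwhm_mm)),
    class = "lc_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  if (is.null(out_dir)) report else invisible(report)
}

# serialize an lc_report to disk (TSV + JSON + NIfTI + plain text)
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$contrasts_long, file.path(out_dir, "contrasts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  jsonable <- list(
    settings = report$settings,
    group_results = lapply(report$group_results, function(gr) list(
      levene = gr$levene,
      omnibus = unclass(gr$omnibus),
      posthoc_run = gr$posthoc_run,
      posthoc = if (!is.null(gr$posthoc)) as.data.frame(gr$posthoc))),
    correlations = report$correlations,
    descriptives = list(
      age_kruskal = report$descriptives$age_kruskal,
      sex_chisq = report$descriptives$sex_chisq[c("statistic", "df", "p")],
      score_tests = report$descriptives$score_tests),
    voxelwise = if (!is.null(report$voxelwise)) list(
      moca_clusters = as.data.frame(report$voxelwise$moca),
      rostral_exploratory_clusters =
        as.data.frame(report$voxelwise$rostral_exploratory),
      fwhm_mm = report$voxelwise$fwhm_mm))
  jsonlite::write_json(jsonable, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)

  if (!is.null(report$voxelwise)) {
    write.table(as.data.frame(report$voxelwise$moca),
                file.path(out_dir, "clusters_moca.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report$voxelwise$rostral_exploratory),
                file.path(out_dir, "clusters_rostral_exploratory.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tm <- attr(report$voxelwise$moca, "stat_map")
    tmap <- tm$t; tmap[is.na(tmap)] <- 0
    write_volume(tmap, file.path(out_dir, "tmap_moca.nii.gz"),
                 voxel_size_mm = tm$voxel_size_mm)
  }

  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.lc_report <- function(x, ...) {
  cat("LC neuromelanin pipeline report\n")
  cat("===============================\n")
  cat(sprintf("subjects: %d (%s); seed %d; %d scalar permutations\n",
              nrow(x$data),
              paste(sprintf("%s=%d", names(table(x$data$group)),
                            as.integer(table(x$data$group))), collapse = ", "),
              x$settings$seed, x$settings$n_perm))
  cat("\n-- Sub-regional group comparisons --\n")
  for (reg in names(x$group_results)) {
    gr <- x$group_results[[reg]]
    cat(sprintf("%s: Levene W = %.3f (p = %.3f); omnibus F(%d,%d) = %.3f, p = %.4g\n",
                reg, gr$levene$W, gr$levene$p, gr$omnibus$df[1],
                gr$omnibus$df[2], gr$omnibus$observed, gr$omnibus$p))
    if (!gr$posthoc_run) {
      cat("   post hocs skipped (omnibus not significant)\n")
    } else if (!is.null(gr$posthoc)) {
      for (r in seq_len(nrow(gr$posthoc)))
        cat(sprintf("   %-8s t(%d) = %6.3f  p = %.4f  p_FWER = %.4f\n",
                    gr$posthoc$contrast[r], gr$posthoc$df[r],
                    gr$posthoc$t[r], gr$posthoc$p[r], gr$posthoc$p_fwer[r]))
    }
  }
  cat("\n-- Spearman correlations with adjusted MoCA --\n")
  for (nm in names(x$correlations)) {
    cc <- x$correlations[[nm]]
    cat(sprintf("%s: %s\n", nm, paste(vapply(names(cc), function(reg)
      sprintf("%s rho = %.3f (p = %.3f)", reg, cc[[reg]]$rho, cc[[reg]]$p),
      character(1)), collapse = "; ")))
  }
  d <- x$descriptives
  cat(sprintf("\n-- Descriptives --\nage: H = %.3f, p = %.3f; sex: chi2 = %.3f, p = %.3f\n",
              d$age_kruskal$H, d$age_kruskal$p, d$sex_chisq$statistic,
              d$sex_chisq$p))
  if (!is.null(x$voxelwise)) {
    cat("\n-- Voxel-wise FDG-PET associations --\n")
    cat("MoCA (primary threshold):\n")
    print(x$voxelwise$moca)
    cat("rostral LC contrast (exploratory threshold):\n")
    print(x$voxelwise$rostral_exploratory)
  }
  invisible(x)
}

#' Validate an input directory for the pipeline
#'
#' Checks the covariate schema, presence of the per-subject volumes and
#' masks, grid compatibility, mask disjointness (search vs background)
#' and search-ROI slice span.  Failures are reported, not raised.
#'
#' @param dir directory laid out as written by [run_simulation()].
#' @return data.frame of class `lc_validation` with columns `check`,
#'   `status` (`"pass"`/`"fail"`) and `detail`; attribute `ok` is TRUE
#'   when every check passed.
#' @export
validate_inputs <- function(dir) {
  checks <- list()
  add <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = if (isTRUE(pass)) "pass" else "fail",
      detail = detail, stringsAsFactors = FALSE)

  cov_path <- file.path(dir, "covariates.tsv")
  subjects <- NULL
  if (file.exists(cov_path)) {
    subjects <- read.delim(cov_path, stringsAsFactors = FALSE)
    need <- c("subject_id", "group", "age", "sex", "education_years",
              "moca_raw")
    miss <- setdiff(need, names(subjects))
    add("covariate schema", length(miss) == 0L,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "")
  } else {
    add("covariate table present", FALSE, cov_path)
  }

  mask_paths <- file.path(dir, "masks", paste0(roi_file_names, ".nii.gz"))
  have_masks <- file.exists(mask_paths)
  add("mask files present", all(have_masks),
      if (!all(have_masks))
        paste("missing:", paste(roi_file_names[!have_masks], collapse = ", "))
      else "")

  if (all(have_masks)) {
    masks <- lapply(setNames(mask_paths, roi_file_names), read_volume)
    dims <- lapply(masks, dim)
    same <- all(vapply(dims, identical, logical(1), y = dims[[1]]))
    add("masks on a common grid", same, "")
    if (same) {
      overlap_l <- sum(masks$search_roi_left != 0 & masks$background_roi != 0)
      overlap_r <- sum(masks$search_roi_right != 0 & masks$background_roi != 0)
      add("search ROIs disjoint from background ROI",
          overlap_l + overlap_r == 0,
          if (overlap_l + overlap_r > 0)
            sprintf("overlap: search_roi_left=%d, search_roi_right=%d voxels",
                    overlap_l, overlap_r) else "")
      add("background ROI nonempty", any(masks$background_roi != 0), "")
      for (side in c("search_roi_left", "search_roi_right")) {
        span <- sum(apply(masks[[side]] != 0, 3, any))
        add(paste(side, "spans >= 3 axial slices"), span >= 3L,
            sprintf("%d slices", span))
      }
      if (!is.null(subjects)) {
        nm_paths <- file.path(dir, sprintf("nm_%s.nii.gz",
                                           subjects$subject_id))
        have_nm <- file.exists(nm_paths)
        add("NM volume per subject", all(have_nm),
            if (!all(have_nm))
              paste("missing:", paste(subjects$subject_id[!have_nm],
                                      collapse = ", ")) else "")
        if (any(have_nm)) {
          v1 <- read_volume(nm_paths[which(have_nm)[1]])
          add("NM volumes on the mask grid",
              identical(dim(v1), dims[[1]]), "")
        }
      }
    }
  }
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$status == "pass")
  class(out) <- c("lc_validation", "data.frame")
  out
}

#' @export
print.lc_validation <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(if (attr(x, "ok")) "all checks passed\n" else "validation FAILED\n")
  invisible(x)
}
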