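# Synthetic phantom cohorts with known ground truth.
#
# The phantom is a pontine slab in its own common space: two straight
# hyperintense axial "LC tubes" on a uniform background, a background ROI
# between them, a brain mask for slice normalization, plus (for PET) a
# reference region and a planted cortical-like cluster whose amplitude
# co-varies with a latent cognition score.  The tube axis sits midway
# between two voxel columns so the default 1-voxel radius yields a 2-voxel
# in-plane cross-section (~1 mm at 0.5 mm spacing), i.e. six voxels per
# tri-section third.

#' Phantom cohort configuration
#'
#' Builds and validates the configuration controlling
#' [generate_cohort()].  Defaults mirror the study conditions: three
#' groups (18 HC, 11 MSA, 18 PD), healthy rostral/middle/caudal contrasts
#' around 0.30/0.25/0.20 with patient reductions concentrated in the
#' middle and caudal thirds for MSA and the middle third for PD,
#' multiplicative per-slice gains in (0.9, 1.1), additive Gaussian noise,
#' and three averaged acquisitions (noise scaled by 1/sqrt(3)).
#'
#' @param grid_shape integer length-3 voxel counts (all >= 16).
#' @param voxel_size_mm per-axis spacing in mm.
#' @param background_mean pontine background intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise SD per acquisition (intensity
#'   units).
#' @param n_acquisitions number of averaged acquisitions; effective noise
#'   SD is `noise_sd / sqrt(n_acquisitions)`.
#' @param slice_gain_range positive multiplicative bounds for per-slice
#'   intensity drift.
#' @param lc_tube_radius_vox in-plane tube radius in voxels (axis offset
#'   by half a voxel; radius 1 gives a 2-voxel cross-section).
#' @param lc_length_slices number of axial slices spanned by the tubes.
#' @param contrast_means named list (one entry per group) of length-3
#'   vectors `c(rostral, middle, caudal)` of mean true NM contrasts.
#' @param contrast_sd between-subject SD of true contrast (per side and
#'   subregion).
#' @param n_per_group named integer vector of group sizes (all >= 2).
#' @param pet_group group label receiving PET volumes.
#' @param pet_baseline baseline PET uptake.
#' @param pet_noise_sd additive PET noise SD.
#' @param pet_cluster_radius_vox radius (voxels) of the planted spherical
#'   cluster.
#' @param cognition_model list with `rostral_loading` (latent score
#'   loading on standardized rostral contrast), `noise_sd` (residual score
#'   SD), `cluster_amplitude` (fractional uptake change per score unit),
#'   `moca_mean`, `moca_sd` (raw MoCA location/scale).
#' @param seed integer RNG seed.
#' @return object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(grid_shape = c(32, 32, 16),
                           voxel_size_mm = c(0.5, 0.5, 2.5),
                           background_mean = 100,
                           noise_sd = 2,
                           n_acquisitions = 3,
                           slice_gain_range = c(0.9, 1.1),
                           lc_tube_radius_vox = 1,
                           lc_length_slices = 9,
                           contrast_means = list(
                             HC  = c(rostral = 0.30, middle = 0.25,  caudal = 0.20),
                             MSA = c(rostral = 0.27, middle = 0.175, caudal = 0.14),
                             PD  = c(rostral = 0.285, middle = 0.2125, caudal = 0.18)),
                           contrast_sd = 0.05,
                           n_per_group = c(HC = 18, MSA = 11, PD = 18),
                           pet_group = "MSA",
                           pet_baseline = 100,
                           pet_noise_sd = 15,
                           pet_cluster_radius_vox = 3,
                           cognition_model = list(
                             rostral_loading = 0.8,
                             noise_sd = sqrt(1 - 0.8^2),
                             cluster_amplitude = 0.05,
                             moca_mean = 26,
                             moca_sd = 2.5),
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              background_mean = background_mean,
              noise_sd = noise_sd,
              n_acquisitions = n_acquisitions,
              slice_gain_range = as.numeric(slice_gain_range),
              lc_tube_radius_vox = lc_tube_radius_vox,
              lc_length_slices = as.integer(lc_length_slices),
              contrast_means = contrast_means,
              contrast_sd = contrast_sd,
              n_per_group = n_per_group,
              pet_group = pet_group,
              pet_baseline = pet_baseline,
              pet_noise_sd = pet_noise_sd,
              pet_cluster_radius_vox = pet_cluster_radius_vox,
              cognition_model = cognition_model,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("invalid phantom configuration field `%s`: %s", field, why),
         call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 16L))
    fail("grid_shape", "must be three voxel counts, all >= 16")
  if (length(cfg$voxel_size_mm) != 3L || any(cfg$voxel_size_mm <= 0))
    fail("voxel_size_mm", "must be three positive spacings")
  if (!is.finite(cfg$background_mean) || cfg$background_mean <= 0)
    fail("background_mean", "must be positive")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    fail("noise_sd", "must be >= 0")
  if (cfg$n_acquisitions < 1)
    fail("n_acquisitions", "must be >= 1")
  if (length(cfg$slice_gain_range) != 2L || any(cfg$slice_gain_range <= 0) ||
      cfg$slice_gain_range[1] > cfg$slice_gain_range[2])
    fail("slice_gain_range", "must be positive increasing bounds")
  if (cfg$lc_tube_radius_vox < 0.5)
    fail("lc_tube_radius_vox", "must be >= 0.5")
  if (cfg$lc_length_slices < 3L || cfg$lc_length_slices > cfg$grid_shape[3])
    fail("lc_length_slices", "must be in [3, grid_shape[3]]")
  grp <- names(cfg$n_per_group)
  if (is.null(grp) || any(!nzchar(grp)))
    fail("n_per_group", "must be a named vector of group sizes")
  if (any(cfg$n_per_group < 2))
    fail("n_per_group", "every group needs >= 2 subjects")
  if (!all(grp %in% names(cfg$contrast_means)))
    fail("contrast_means", "needs one entry per group in n_per_group")
  cm <- unlist(cfg$contrast_means[grp])
  if (any(!is.finite(cm)) || any(cm <= -1))
    fail("contrast_means", "true contrasts must be finite and > -1")
  if (!is.finite(cfg$contrast_sd) || cfg$contrast_sd < 0)
    fail("contrast_sd", "must be >= 0")
  if (!cfg$pet_group %in% grp)
    fail("pet_group", "must be one of the group labels")
  if (cfg$pet_baseline <= 0) fail("pet_baseline", "must be positive")
  if (cfg$pet_noise_sd < 0) fail("pet_noise_sd", "must be >= 0")
  if (cfg$pet_cluster_radius_vox < 1)
    fail("pet_cluster_radius_vox", "must be >= 1")
  needed <- c("rostral_loading", "noise_sd", "cluster_amplitude",
              "moca_mean", "moca_sd")
  if (!all(needed %in% names(cfg$cognition_model)))
    fail("cognition_model", paste("needs fields:", paste(needed, collapse = ", ")))
  invisible(cfg)
}

# Deterministic geometry of the phantom space: tube voxels, tri-section
# blocks, search/background/brain/reference masks and the planted cluster.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- floor(nx / 2); cy <- floor(ny / 2)
  offset <- max(5L, round(nx / 5))
  x0_left <- cx - offset - 1L       # left column of the left voxel pair
  x0_right <- cx + offset
  y0 <- cy + 4L
  z0 <- floor((nz - cfg$lc_length_slices) / 2) + 1L
  tube_slices <- z0:(z0 + cfg$lc_length_slices - 1L)

  cross_section <- function(x0) {
    r2 <- cfg$lc_tube_radius_vox^2
    xs <- (x0 - 3L):(x0 + 4L); ys <- (y0 - 3L):(y0 + 3L)
    g <- expand.grid(x = xs, y = ys)
    g <- g[(g$x - x0 - 0.5)^2 + (g$y - y0)^2 <= r2 + 1e-9, , drop = FALSE]
    as.matrix(g)
  }
  cs_left <- cross_section(x0_left)
  cs_right <- cross_section(x0_right)
  in_grid <- function(cs) all(cs[, 1] >= 1 & cs[, 1] <= nx &
                              cs[, 2] >= 1 & cs[, 2] <= ny)
  if (!in_grid(cs_left) || !in_grid(cs_right) ||
      min(tube_slices) < 1 || max(tube_slices) > nz)
    stop("LC tube geometry does not fit inside the grid", call. = FALSE)

  dilate_inplane <- function(cs, by = 1L) {
    g <- expand.grid(dx = -by:by, dy = -by:by)
    out <- unique(data.frame(
      x = rep(cs[, 1], each = nrow(g)) + rep(g$dx, times = nrow(cs)),
      y = rep(cs[, 2], each = nrow(g)) + rep(g$dy, times = nrow(cs))))
    out <- out[out$x >= 1 & out$x <= nx & out$y >= 1 & out$y <= ny, ]
    as.matrix(out)
  }

  mask_from_xy <- function(xy, slices) {
    m <- array(FALSE, d)
    for (z in slices) m[cbind(xy, z)] <- TRUE
    m
  }

  sr_left_xy <- dilate_inplane(cs_left, 1L)
  sr_right_xy <- dilate_inplane(cs_right, 1L)
  search_left <- mask_from_xy(sr_left_xy, tube_slices)
  search_right <- mask_from_xy(sr_right_xy, tube_slices)

  bg_xy <- as.matrix(expand.grid(x = (cx - 2L):(cx + 2L),
                                 y = (y0 - 1L):(y0 + 1L)))
  background <- mask_from_xy(bg_xy, tube_slices)

  # brain mask: in-plane disc on every slice, minus the search ROIs plus a
  # one-voxel margin (excluded on all slices so every slice sees the same
  # in-mask region; keeps slice normalization blind to the hyperintensity)
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  rb <- min(nx, ny) / 2 - 2
  disc <- (xg - (nx + 1) / 2)^2 + (yg - (ny + 1) / 2)^2 <= rb^2
  excl <- matrix(FALSE, nx, ny)
  excl[rbind(dilate_inplane(cs_left, 2L), dilate_inplane(cs_right, 2L))] <- TRUE
  brain <- array(disc & !excl, d)

  reference <- mask_from_xy(
    as.matrix(expand.grid(x = (cx - 3L):(cx + 3L), y = 3:6)),
    seq_len(nz))

  ctr <- c(cx + round(nx / 4), ny - 7L, nz - 4L)
  ax <- arrayInd(seq_len(prod(d)), d)
  cluster <- array(colSums((t(ax) - ctr)^2) <= cfg$pet_cluster_radius_vox^2, d)

  # gray-matter-like analysis volume: cortical-ribbon annulus (outer 40%
  # of the brain disc) over the upper two-thirds of slices, sparing the
  # reference region; the planted "frontal" cluster sits inside it, the
  # pontine structures below/inside it do not
  ribbon2 <- (xg - (nx + 1) / 2)^2 + (yg - (ny + 1) / 2)^2
  annulus <- disc & ribbon2 >= (0.6 * rb)^2
  analysis <- array(annulus, d) & !reference
  analysis[, , seq_len(floor(nz / 3))] <- FALSE

  list(tube_slices = tube_slices,
       cross = list(left = cs_left, right = cs_right),
       tube_masks = list(left = mask_from_xy(cs_left, tube_slices),
                         right = mask_from_xy(cs_right, tube_slices)),
       search_roi_left = search_left,
       search_roi_right = search_right,
       background_roi = background,
       brain_mask = brain,
       reference_region = reference,
       cluster_mask = cluster,
       analysis_mask = analysis,
       cluster_center = ctr)
}

# rostral-first split of a decreasing-superior slice list into three blocks
trisect_slices <- function(slices) {
  n <- length(slices)
  if (n < 3L) stop("need at least 3 axial slices to trisect", call. = FALSE)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- c(rostral = base + (rem >= 1L),
             middle  = base + (rem >= 2L),
             caudal  = base)
  s <- sort(slices, decreasing = TRUE)   # superior first
  split(s, rep(c("rostral", "middle", "caudal"), times = sizes))[
    c("rostral", "middle", "caudal")]
}

#' Render noiseless bilateral LC tubes for one subject
#'
#' Produces a volume with uniform pontine background and bilateral tube
#' voxels set, third by third, to
#' `background_mean * (1 + true contrast)`.
#'
#' @param config a [phantom_config()].
#' @param subject_truth list with `left` and `right` length-3 contrast
#'   vectors `c(rostral, middle, caudal)`.
#' @return 3-D intensity array (noiseless).
#' @export
make_lc_tubes <- function(config, subject_truth) {
  geom <- phantom_geometry(config)
  vol <- array(config$background_mean, config$grid_shape)
  blocks <- trisect_slices(geom$tube_slices)
  for (side in c("left", "right")) {
    cs <- geom$cross[[side]]
    tc <- subject_truth[[side]]
    if (length(tc) != 3L || any(tc <= -1))
      stop("subject_truth contrasts must be three values > -1", call. = FALSE)
    for (b in seq_along(blocks)) {
      val <- config$background_mean * (1 + tc[b])
      for (z in blocks[[b]]) vol[cbind(cs, z)] <- val
    }
  }
  as_volume(vol, config$voxel_size_mm)
}

#' Apply multiplicative per-slice intensity drift
#'
#' @param volume 3-D array; axial axis is the third dimension.
#' @param gains numeric vector, one positive multiplier per axial slice.
#' @return the gain-perturbed volume.
#' @export
apply_slice_gain <- function(volume, gains) {
  d <- dim(volume)
  if (length(gains) != d[3])
    stop("`gains` must have one value per axial slice", call. = FALSE)
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop("slice gains must be positive and finite", call. = FALSE)
  out <- volume * rep(gains, each = d[1] * d[2])
  attributes(out) <- attributes(volume)
  out
}

#' Render a PET uptake phantom with a cognition-linked planted cluster
#'
#' Baseline uptake everywhere; inside the planted cluster the uptake is
#' `baseline * (1 + a * score)` with `a` the configured cluster
#' amplitude.  The reference region does not overlap the cluster, so its
#' uptake is independent of the score.  Additive Gaussian noise is drawn
#' from the current RNG state.
#'
#' @param config a [phantom_config()].
#' @param subject_truth list with at least `score` (latent cognition
#'   score, standardized scale).
#' @return 3-D uptake array.
#' @export
make_suvr_phantom <- function(config, subject_truth) {
  geom <- phantom_geometry(config)
  a <- config$cognition_model$cluster_amplitude
  vol <- array(config$pet_baseline, config$grid_shape)
  vol[geom$cluster_mask] <- config$pet_baseline * (1 + a * subject_truth$score)
  if (config$pet_noise_sd > 0)
    vol <- vol + array(rnorm(prod(config$grid_shape), 0, config$pet_noise_sd),
                       config$grid_shape)
  as_volume(vol, config$voxel_size_mm)
}

# covariate core shared by generate_covariates() and generate_cohort();
# draws from the current RNG state
draw_covariates <- function(config, groups, latent_score) {
  n <- length(groups)
  cm <- config$cognition_model
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    age = sample(45:80, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education_years = sample(8:20, n, replace = TRUE),
    moca_raw = pmin(30L, pmax(0L, as.integer(round(
      cm$moca_mean + cm$moca_sd * latent_score)))),
    stringsAsFactors = FALSE)
}

#' Generate a covariate table alone
#'
#' Draws ages (45-80 years), sex, education years and raw MoCA scores
#' (integer, 0-30, derived from a latent cognition score) for the
#' configured groups.  Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param latent_score optional per-subject latent score; standard normal
#'   draws if omitted.
#' @return data.frame with columns `subject_id, group, age, sex,
#'   education_years, moca_raw`.
#' @export
generate_covariates <- function(config, latent_score = NULL) {
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  if (is.null(latent_score)) latent_score <- rnorm(length(groups))
  draw_covariates(config, groups, latent_score)
}

#' Generate a full phantom cohort with ground truth
#'
#' Draws per-subject true sub-regional contrasts (group mean + between-
#' subject variation, independently per side), renders one neuromelanin-
#' sensitive volume per subject (noise scaled by `1/sqrt(n_acquisitions)`,
#' then per-slice gains), one PET volume per subject of `pet_group`, the
#' shared ROI set, the covariate table, and the complete ground truth.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return object of class `lc_cohort`: list with `subjects` (covariate
#'   data.frame), `nm` (named list of NM volumes), `pet` (named list of
#'   PET volumes for the PET group), `rois` (named list of masks:
#'   `search_roi_left`, `search_roi_right`, `background_roi`,
#'   `brain_mask`, `reference_region`, `analysis_mask`), `truth`
#'   (true contrasts, tube/cluster masks, latent scores, slice gains,
#'   planted amplitudes) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  set.seed(config$seed)
  geom <- phantom_geometry(config)
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  subregions <- c("rostral", "middle", "caudal")

  true_contrast <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- config$contrast_means[[groups[i]]]
    data.frame(subject_id = ids[i], group = groups[i],
               side = rep(c("left", "right"), each = 3L),
               subregion = rep(subregions, 2L),
               true_contrast = rep(mu, 2L) + rnorm(6L, 0, config$contrast_sd),
               stringsAsFactors = FALSE)
  }))

  rostral_mean <- vapply(ids, function(id) {
    mean(true_contrast$true_contrast[true_contrast$subject_id == id &
                                     true_contrast$subregion == "rostral"])
  }, numeric(1))
  cm <- config$cognition_model
  hc_ref <- config$contrast_means[[1L]]["rostral"]
  zr <- (rostral_mean - hc_ref) / max(config$contrast_sd, 1e-8)
  score <- cm$rostral_loading * zr + rnorm(n, 0, cm$noise_sd)

  subjects <- draw_covariates(config, groups, score)

  eff_sd <- config$noise_sd / sqrt(config$n_acquisitions)
  gains <- matrix(runif(n * config$grid_shape[3],
                        config$slice_gain_range[1], config$slice_gain_range[2]),
                  nrow = config$grid_shape[3])
  nm <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    tc <- true_contrast[true_contrast$subject_id == ids[i], ]
    truth_i <- list(
      left = tc$true_contrast[tc$side == "left"][match(subregions, tc$subregion[tc$side == "left"])],
      right = tc$true_contrast[tc$side == "right"][match(subregions, tc$subregion[tc$side == "right"])])
    vol <- make_lc_tubes(config, truth_i)
    if (eff_sd > 0)
      vol <- vol + array(rnorm(prod(config$grid_shape), 0, eff_sd),
                         config$grid_shape)
    nm[[i]] <- apply_slice_gain(as_volume(vol, config$voxel_size_mm),
                                gains[, i])
  }

  pet_ids <- ids[groups == config$pet_group]
  pet <- setNames(lapply(pet_ids, function(id) {
    make_suvr_phantom(config, list(score = score[match(id, ids)]))
  }), pet_ids)

  rois <- lapply(list(search_roi_left = geom$search_roi_left,
                      search_roi_right = geom$search_roi_right,
                      background_roi = geom$background_roi,
                      brain_mask = geom$brain_mask,
                      reference_region = geom$reference_region,
                      analysis_mask = geom$analysis_mask),
                 as_volume, voxel_size_mm = config$voxel_size_mm)

  truth <- list(true_contrast = true_contrast,
                lc_masks = geom$tube_masks,
                cluster_mask = geom$cluster_mask,
                cluster_center = geom$cluster_center,
                cluster_amplitude = cm$cluster_amplitude * score,
                latent_score = setNames(score, ids),
                slice_gains = gains)

  structure(list(subjects = subjects, nm = nm, pet = pet, rois = rois,
                 truth = truth, config = config),
            class = "lc_cohort")
}

#' @export
print.lc_cohort <- function(x, ...) {
  cat("Phantom cohort:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    as.integer(table(x$subjects$group))), collapse = ", "),
      ")\n")
  cat("  grid", paste(x$config$grid_shape, collapse = "x"),
      "voxels @", paste(x$config$voxel_size_mm, collapse = "x"), "mm\n")
  cat("  PET volumes:", length(x$pet), "(group", x$config$pet_group, ")\n")
  invisible(x)
}
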