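test_that("voxel-wise t map matches closed-form OLS and flags perfect fits", {
  set.seed(30)
  n <- 10
  x <- rnorm(n)
  d <- c(5, 5, 4)
  images <- lapply(seq_len(n), function(i) array(rnorm(prod(d)), d))
  map <- voxelwise_glm(images, x)
  expect_equal(map$df, n - 2)
  # hand-computed OLS t at a single voxel
  yv <- vapply(images, function(im) im[2, 3, 1], numeric(1))
  fit <- summary(lm(yv ~ x))
  expect_equal(map$t[2, 3, 1], fit$coefficients["x", "t value"],
               tolerance = 1e-10)
  # a voxel equal to c * regressor is a perfect fit -> infinite t, flagged
  for (i in seq_len(n)) images[[i]][1, 1, 1] <- 3 * x[i]
  map2 <- voxelwise_glm(images, x)
  expect_true(is.infinite(map2$t[1, 1, 1]) && map2$t[1, 1, 1] > 0)
  expect_true(map2$perfect_fit[1, 1, 1])
  # affine rescaling of the regressor leaves t untouched
  map3 <- voxelwise_glm(images, 5 * x - 2)
  expect_equal(map3$t, map2$t, tolerance = 1e-9)
  expect_error(voxelwise_glm(images, rep(1, n)), "constant")
  expect_error(voxelwise_glm(images[1:2], rnorm(2)), "3 subjects")
})

test_that("null t maps follow the Student-t distribution", {
  set.seed(31)
  n <- 12
  x <- rnorm(n)
  d <- c(8, 8, 6)
  images <- lapply(seq_len(n), function(i) array(rnorm(prod(d)), d))
  map <- voxelwise_glm(images, x)
  ks <- ks.test(pt(as.vector(map$t), map$df), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("thresholding uses the one-tailed t quantile and labels blobs", {
  d <- c(10, 10, 6)
  tmap <- array(0, d)
  tmap[2:3, 2:3, 2] <- 6      # blob 1
  tmap[8, 8, 5] <- 7          # blob 2, far away
  map <- structure(list(t = tmap, df = 9, n = 11,
                        mask = array(TRUE, d),
                        voxel_size_mm = c(1, 1, 1)),
                   class = "stat_map")
  thr <- threshold_and_label(map, 0.001)
  expect_equal(thr$t_critical, qt(0.999, 9), tolerance = 1e-12)
  expect_equal(thr$t_critical, 4.2968, tolerance = 1e-4)
  expect_equal(sort(thr$sizes), c(1, 4))
  expect_equal(max(thr$labels), 2)
  expect_error(threshold_and_label(map, 0), "in \\(0, 1\\)")
})

test_that("component labeling equals the flood-fill oracle on random maps", {
  set.seed(32)
  for (r in 1:20) {
    d <- c(7, 7, 5)
    mask <- array(runif(prod(d)) < 0.2, d)
    for (conn in c(6, 18, 26)) {
      sizes <- sort(component_sizes(label_components(mask, conn)),
                    decreasing = TRUE)
      expect_identical(as.integer(sizes),
                       oracle_flood_fill_sizes(mask, conn))
    }
  }
})

test_that("cluster FWE p-values are monotone in extent and nest across thresholds", {
  set.seed(33)
  cfg <- phantom_config(grid_shape = c(24, 24, 16), voxel_size_mm = c(2, 2, 2),
                        n_per_group = c(HC = 2, MSA = 10, PD = 2),
                        pet_noise_sd = 25, seed = 33)
  co <- generate_cohort(cfg)
  suvr <- lapply(co$pet, function(v)
    smooth_gaussian(compute_suvr(v, co$rois$reference_region), 6))
  sc <- co$truth$latent_score[names(co$pet)]
  ct <- cluster_fwe(suvr, sc, mask = co$rois$analysis_mask != 0,
                    cluster_forming_p = 0.01, n_perm = 200, seed = 5)
  if (nrow(ct) >= 2) {
    ord <- order(ct$n_voxels, decreasing = TRUE)
    expect_true(all(diff(ct$p_fwe[ord]) >= -1e-12))
  }
  # every strict-threshold cluster sits inside some loose-threshold cluster
  map <- attr(ct, "stat_map")
  strict <- threshold_and_label(map, 0.001)
  loose <- threshold_and_label(map, 0.01)
  if (max(strict$labels) > 0) {
    for (cl in seq_len(max(strict$labels))) {
      vox <- which(strict$labels == cl)
      parents <- unique(loose$labels[vox])
      expect_true(all(parents > 0))
      expect_length(parents, 1)
    }
  }
})

test_that("exhaustive relabeling matches Monte-Carlo for tiny n", {
  set.seed(34)
  n <- 7
  d <- c(8, 8, 6)
  x <- rnorm(n)
  images <- lapply(seq_len(n), function(i)
    array(rnorm(prod(d), 0, 1), d) + 0.8 * x[i])
  ct_ex <- cluster_fwe(images, x, cluster_forming_p = 0.01,
                       n_perm = 5040, seed = 1)
  expect_true(attr(ct_ex, "exhaustive"))
  expect_equal(attr(ct_ex, "n_perm"), 5040)
  ct_mc <- cluster_fwe(images, x, cluster_forming_p = 0.01,
                       n_perm = 4000, seed = 2, exact = "never")
  expect_false(attr(ct_mc, "exhaustive"))
  if (nrow(ct_ex) && nrow(ct_mc)) {
    p_ex <- ct_ex$p_fwe[1]
    se <- sqrt(p_ex * (1 - p_ex) / 4000)
    expect_lt(abs(ct_mc$p_fwe[1] - p_ex), 3 * se + 1 / 4000)
  }
})
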