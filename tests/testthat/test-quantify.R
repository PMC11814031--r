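test_that("slice normalization equalizes in-mask means and is logged", {
  set.seed(1)
  d <- c(10, 10, 6)
  vol <- array(rnorm(prod(d), 100, 1), d)
  mask <- array(TRUE, d)
  uniform <- array(50, d)
  expect_equal(normalize_slices(uniform, mask), uniform,
               ignore_attr = TRUE)
  pert <- vol
  pert[, , 3] <- pert[, , 3] * 2
  out <- normalize_slices(pert, mask)
  slice_means <- apply(out, 3, mean)
  expect_equal(max(slice_means) - min(slice_means), 0, tolerance = 1e-12)
  expect_equal(mean(out), mean(pert))   # global in-mask mean preserved
  # empty-mask slices are left alone and reported
  m2 <- mask; m2[, , 2] <- FALSE
  out2 <- normalize_slices(pert, m2)
  expect_identical(attr(out2, "unscaled_slices"), 2L)
  expect_equal(out2[, , 2], pert[, , 2])
  expect_error(normalize_slices(vol, array(FALSE, d)), "empty")
})

test_that("trisection partitions the ROI with the rostral-first rule", {
  mk_roi <- function(slices, d = c(6, 6, 12)) {
    roi <- array(FALSE, d)
    roi[3:4, 3:4, slices] <- TRUE
    roi
  }
  r9 <- trisect_roi(mk_roi(2:10))
  for (m in r9) expect_equal(sum(apply(m, 3, any)), 3)
  # rostral = superior (highest slice indices)
  expect_true(all(which(apply(r9$rostral, 3, any)) == 8:10))
  expect_true(all(which(apply(r9$caudal, 3, any)) == 2:4))
  # 8 slices -> (3, 3, 2)
  r8 <- trisect_roi(mk_roi(2:9))
  expect_equal(vapply(r8, function(m) sum(apply(m, 3, any)), numeric(1)),
               c(rostral = 3, middle = 3, caudal = 2))
  # union recovers the mask voxel for voxel, blocks pairwise disjoint
  roi <- mk_roi(2:9)
  expect_identical(r8$rostral | r8$middle | r8$caudal, roi)
  expect_false(any(r8$rostral & r8$middle))
  expect_false(any(r8$middle & r8$caudal))
  expect_error(trisect_roi(mk_roi(2:3)), "3 axial slices")
})

test_that("brightest-connected extraction handles the simple cases", {
  d <- c(8, 8, 8)
  vol <- array(100, d)
  # ROI of exactly five connected voxels returns them all
  roi5 <- array(FALSE, d); roi5[2:6, 3, 3] <- TRUE
  vol5 <- vol; vol5[2:6, 3, 3] <- c(101, 102, 103, 104, 105)
  ex <- extract_brightest_connected(vol5, roi5, 5)
  expect_equal(ex$mean, 103)
  expect_equal(ex$flag, "ok")
  # a bright 5-voxel column inside a dull ROI is found exactly
  roi <- array(FALSE, d); roi[2:7, 2:7, 4] <- TRUE
  volb <- vol; volb[4, 2:6, 4] <- 200
  ex2 <- extract_brightest_connected(volb, roi, 5)
  expect_equal(ex2$mean, 200)
  expect_true(all(ex2$voxels[, 1] == 4))
  # undersized ROI flagged, all voxels used
  roi3 <- array(FALSE, d); roi3[2:4, 2, 2] <- TRUE
  ex3 <- extract_brightest_connected(vol5, roi3, 5)
  expect_equal(ex3$flag, "undersized")
  expect_equal(ex3$k, 3)
  expect_error(extract_brightest_connected(vol, array(FALSE, d), 5),
               "empty")
})

test_that("exact extraction equals the brute-force oracle on random ROIs", {
  set.seed(20)
  for (r in 1:25) {
    roi <- random_roi()
    vol <- array(rnorm(216, 100, 20), c(6, 6, 6))
    ex <- extract_brightest_connected(vol, roi, 5)
    expect_equal(ex$mean, oracle_brightest_connected(vol, roi, 5),
                 tolerance = 1e-12)
  }
  # 6-connectivity variant agrees with its own oracle
  set.seed(21)
  for (r in 1:5) {
    roi <- random_roi()
    vol <- array(rnorm(216, 100, 20), c(6, 6, 6))
    comp_ok <- max(oracle_flood_fill_sizes(roi, 6)) >= 5
    if (!comp_ok) next
    ex <- extract_brightest_connected(vol, roi, 5, connectivity = 6)
    expect_equal(ex$mean,
                 oracle_brightest_connected(vol, roi, 5, connectivity = 6),
                 tolerance = 1e-12)
  }
})

test_that("greedy method stays within the exact optimum", {
  set.seed(22)
  for (r in 1:10) {
    roi <- random_roi()
    vol <- array(rnorm(216, 100, 20), c(6, 6, 6))
    exact <- extract_brightest_connected(vol, roi, 5)
    greedy <- extract_brightest_connected(vol, roi, 5, method = "greedy")
    expect_lte(greedy$mean, exact$mean + 1e-12)
  }
})

test_that("NM contrast follows the ratio formula and its invariances", {
  expect_equal(compute_nm_contrast(125, 100), 0.25)
  expect_equal(compute_nm_contrast(100, 100), 0)
  a <- runif(5, 50, 150); b <- runif(5, 50, 150)
  expect_equal(compute_nm_contrast(3.7 * a, 3.7 * b),
               compute_nm_contrast(a, b))
  expect_error(compute_nm_contrast(100, 0), "positive")
})

test_that("subject quantification recovers noiseless truth exactly", {
  cfg <- tiny_config(noise_sd = 0, slice_gain_range = c(1, 1),
                     contrast_sd = 0)
  co <- generate_cohort(cfg)
  q <- quantify_subject(co$nm[[1]], co$rois)
  expect_equal(unname(q$averaged), c(0.30, 0.25, 0.20), tolerance = 1e-9)
  # per-side contrasts differ when left and right truths differ
  truth <- list(left = c(0.2, 0.2, 0.2), right = c(0.4, 0.4, 0.4))
  vol <- make_lc_tubes(cfg, truth)
  q2 <- quantify_subject(vol, co$rois)
  bl <- q2$by_side
  expect_equal(bl$contrast[bl$side == "left"], rep(0.2, 3),
               tolerance = 1e-9)
  expect_equal(bl$contrast[bl$side == "right"], rep(0.4, 3),
               tolerance = 1e-9)
  expect_equal(unname(q2$averaged), rep(0.3, 3), tolerance = 1e-9)
  # global scaling leaves contrast untouched
  q3 <- quantify_subject(vol * 10, co$rois)
  expect_equal(q3$averaged, q2$averaged, tolerance = 1e-12)
})

test_that("gain-perturbed noiseless phantoms round-trip through normalization", {
  cfg <- tiny_config(noise_sd = 0, contrast_sd = 0, seed = 31)
  co <- generate_cohort(cfg)   # random gains in (0.9, 1.1) applied
  for (id in names(co$nm)[1:3]) {
    q <- quantify_subject(co$nm[[id]], co$rois)
    expect_equal(unname(q$averaged), c(0.30, 0.25, 0.20),
                 tolerance = 1e-6)
  }
})

test_that("raising tube intensities strictly raises the extracted contrast", {
  cfg <- tiny_config(noise_sd = 0, slice_gain_range = c(1, 1),
                     contrast_sd = 0)
  co <- generate_cohort(cfg)
  vol <- co$nm[[1]]
  q1 <- quantify_subject(vol, co$rois)
  up <- vol
  up[co$truth$lc_masks$left | co$truth$lc_masks$right] <-
    up[co$truth$lc_masks$left | co$truth$lc_masks$right] + 5
  q2 <- quantify_subject(up, co$rois)
  expect_true(all(q2$averaged > q1$averaged))
})
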