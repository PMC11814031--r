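# Mass-univariate association mapping between SUVR images and a scalar
# regressor, with cluster-forming thresholds and permutation-based
# cluster-extent family-wise error correction.

# stack a list of 3-D arrays (or a 4-D array) into a V_mask x n matrix
stack_images <- function(images, mask_idx) {
  if (is.array(images) && length(dim(images)) == 4L) {
    n <- dim(images)[4]
    images <- lapply(seq_len(n), function(i) images[, , , i])
  }
  vapply(images, function(im) im[mask_idx], numeric(length(mask_idx)))
}

#' Voxel-wise simple-regression t map
#'
#' Fits, at every mask voxel, the regression of image intensity on a
#' single regressor (with intercept) and returns the slope t statistic
#' with `df = n - 2`.  Voxels with a numerically perfect fit are set to
#' signed infinity and flagged.
#'
#' @param images list of co-grid 3-D arrays (or a 4-D array, subjects
#'   last), n >= 3.
#' @param regressor per-subject scalar (non-constant), e.g. MoCA or
#'   rostral LC contrast.
#' @param mask optional analysis mask; defaults to all voxels.
#' @return object of class `stat_map`: list with `t` (array, NA outside
#'   the mask), `df`, `n`, `mask`, `voxel_size_mm`, `perfect_fit`
#'   (logical array flag).
#' @export
voxelwise_glm <- function(images, regressor, mask = NULL) {
  first <- if (is.array(images) && length(dim(images)) == 4L)
    images[, , , 1] else images[[1]]
  d <- dim(first)
  n <- if (is.array(images) && length(dim(images)) == 4L) dim(images)[4]
       else length(images)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (length(regressor) != n)
    stop("regressor length must match the number of images", call. = FALSE)
  if (sd(regressor) == 0)
    stop("regressor is constant", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d))
    stop("mask is not on the image grid", call. = FALSE)
  mask_idx <- which(mask != 0)
  Y <- stack_images(images, mask_idx)
  xc <- regressor - mean(regressor)
  sxx <- sum(xc^2)
  Yc <- Y - rowMeans(Y)
  bx <- drop(Yc %*% xc)
  ssy <- rowSums(Yc^2)
  df <- n - 2L
  rss <- pmax(ssy - bx^2 / sxx, 0)
  se2 <- rss / df / sxx
  tvals <- (bx / sxx) / sqrt(se2)
  perfect <- rss <= 1e-12 * pmax(ssy, 1e-300)
  tvals[perfect] <- sign(bx[perfect]) * Inf
  tmap <- array(NA_real_, d)
  tmap[mask_idx] <- tvals
  pf_arr <- array(FALSE, d)
  pf_arr[mask_idx] <- perfect
  structure(list(t = tmap, df = df, n = n, mask = mask != 0,
                 voxel_size_mm = voxel_size(first),
                 perfect_fit = pf_arr),
            class = "stat_map")
}

#' Threshold a t map and label suprathreshold clusters
#'
#' Retains voxels whose one-tailed parametric p falls below the
#' cluster-forming threshold (positive direction: t above the upper
#' t-quantile) and labels connected components.
#'
#' @param map a `stat_map` from [voxelwise_glm()].
#' @param cluster_forming_p voxel-level threshold in (0, 1), e.g. 0.001
#'   (or 0.01 for exploratory maps).
#' @param connectivity cluster connectivity: 6, 18 (default, SPM
#'   convention) or 26.
#' @return list with `labels` (integer array), `sizes` (voxels per
#'   cluster), `t_critical`, `cluster_forming_p`, `connectivity`.
#' @export
threshold_and_label <- function(map, cluster_forming_p = 0.001,
                                connectivity = 18) {
  if (!is.finite(cluster_forming_p) || cluster_forming_p <= 0 ||
      cluster_forming_p >= 1)
    stop("`cluster_forming_p` must be in (0, 1)", call. = FALSE)
  tcrit <- qt(1 - cluster_forming_p, map$df)
  supra <- !is.na(map$t) & map$t > tcrit
  labels <- label_components(supra, connectivity)
  list(labels = labels, sizes = component_sizes(labels),
       t_critical = tcrit, cluster_forming_p = cluster_forming_p,
       connectivity = connectivity)
}

# max cluster extent of a thresholded voxel index set (internal, used in
# the permutation loop); labels only the suprathreshold voxels
max_extent <- function(supra_idx, d, connectivity) {
  if (!length(supra_idx)) return(0L)
  m <- array(FALSE, d)
  m[supra_idx] <- TRUE
  sz <- component_sizes(label_components(m, connectivity))
  max(sz)
}

#' Cluster-extent FWE-corrected association mapping
#'
#' Voxel-wise regression followed by cluster-forming thresholding and
#' permutation-based family-wise error correction on cluster extent: the
#' regressor is permuted across subjects (Freedman-Lane with an
#' intercept-only nuisance model, i.e. simple relabeling), the maximum
#' suprathreshold cluster extent is recorded for each permutation, and
#' each observed cluster receives
#' `p_FWE = (1 + #\{max extent >= size\}) / (1 + n_perm)`.  For n <= 7
#' subjects with `factorial(n) <= n_perm`, all relabelings are
#' enumerated and the p-value is exact.
#'
#' @inheritParams voxelwise_glm
#' @param cluster_forming_p voxel-level threshold (default 0.001).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draw.
#' @param connectivity cluster connectivity (default 18).
#' @param exact `"auto"` (default) or `"never"`.
#' @return object of class `cluster_table`: data.frame with one row per
#'   observed cluster (`cluster`, `n_voxels`, `peak_t`, `peak_i/j/k`
#'   voxel indices, `peak_x/y/z_mm`, `p_fwe`), ordered by extent;
#'   attributes carry the t map, labels, threshold, permutation count and
#'   null maximum extents.
#' @export
cluster_fwe <- function(images, regressor, mask = NULL,
                        cluster_forming_p = 0.001, n_perm = 1000L,
                        seed = NULL, connectivity = 18,
                        exact = c("auto", "never")) {
  exact <- match.arg(exact)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  map <- voxelwise_glm(images, regressor, mask)
  thr <- threshold_and_label(map, cluster_forming_p, connectivity)
  d <- dim(map$t)
  mask_idx <- which(map$mask)
  Y <- stack_images(images, mask_idx)
  n <- map$n
  Yc <- Y - rowMeans(Y)
  ssy <- rowSums(Yc^2)
  xc <- regressor - mean(regressor)
  sxx <- sum(xc^2)
  df <- map$df

  exhaustive <- exact == "auto" && n <= 7L && factorial(n) <= n_perm
  if (exhaustive) {
    P <- perm_matrix(n)
    Xp <- matrix(xc[t(P)], n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    Xp <- vapply(seq_len(n_perm), function(i) xc[sample.int(n)],
                 numeric(n))
  }
  m <- ncol(Xp)
  bx <- Yc %*% Xp                      # V x m
  rss <- pmax(ssy - bx^2 / sxx, 0)
  tperm <- (bx / sxx) / sqrt(rss / df / sxx)
  bad <- which(!is.finite(tperm))
  tperm[bad] <- ifelse(bx[bad] > 0, Inf, -Inf)
  null_max <- vapply(seq_len(m), function(j) {
    max_extent(mask_idx[tperm[, j] > thr$t_critical], d, connectivity)
  }, integer(1))

  sizes <- thr$sizes
  nclust <- length(sizes)
  vs <- map$voxel_size_mm
  rows <- lapply(seq_len(nclust), function(cl) {
    vox <- which(thr$labels == cl)
    peak <- vox[which.max(map$t[vox])]
    pc <- arrayInd(peak, d)
    p_fwe <- if (exhaustive) mean(null_max >= sizes[cl])
             else (1 + sum(null_max >= sizes[cl])) / (1 + m)
    data.frame(cluster = cl, n_voxels = sizes[cl],
               peak_t = map$t[peak],
               peak_i = pc[1], peak_j = pc[2], peak_k = pc[3],
               peak_x_mm = (pc[1] - 1) * vs[1],
               peak_y_mm = (pc[2] - 1) * vs[2],
               peak_z_mm = (pc[3] - 1) * vs[3],
               p_fwe = p_fwe)
  })
  out <- if (nclust) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n_voxels = integer(0),
               peak_t = numeric(0), peak_i = integer(0),
               peak_j = integer(0), peak_k = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), p_fwe = numeric(0))
  attr(out, "stat_map") <- map
  attr(out, "labels") <- thr$labels
  attr(out, "t_critical") <- thr$t_critical
  attr(out, "cluster_forming_p") <- cluster_forming_p
  attr(out, "n_perm") <- m
  attr(out, "exhaustive") <- exhaustive
  attr(out, "null_max_extent") <- null_max
  attr(out, "seed") <- seed
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf(
    "Cluster-extent FWE (cluster-forming p = %g, t > %.3f, %d permutations%s)\n",
    attr(x, "cluster_forming_p"), attr(x, "t_critical"),
    attr(x, "n_perm"), if (attr(x, "exhaustive")) ", exhaustive" else ""))
  if (!nrow(x)) cat("no suprathreshold clusters\n")
  else print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
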