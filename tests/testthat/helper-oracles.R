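# Independent oracles used across test files.  These deliberately avoid
# the package's own code paths: brute-force enumeration, closed forms,
# and stats-package model fits.

# best connected k-subset by mean intensity: exhaustive combn enumeration
# with reachability-based connectivity check
oracle_brightest_connected <- function(vol, roi, k = 5, connectivity = 26) {
  idx <- which(roi != 0)
  cc <- arrayInd(idx, dim(vol))
  vals <- vol[idx]
  n <- length(idx)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(cc[i, ] - cc[j, ])
    A[i, j] <- i != j && switch(as.character(connectivity),
      "26" = max(d) == 1,
      "18" = max(d) == 1 && sum(d) <= 2,
      "6"  = sum(d) == 1)
  }
  best <- -Inf
  for (s in asplit(combn(n, k), 2)) {
    B <- A[s, s]
    R <- B | diag(k)
    for (t in seq_len(ceiling(log2(k)))) R <- (R %*% R) > 0
    if (all(R[1, ])) best <- max(best, mean(vals[s]))
  }
  best
}

# random ROI in a small grid guaranteed to contain a connected component
# of at least 5 voxels (random walk) plus scattered extra voxels
random_roi <- function(d = c(6, 6, 6), n_extra = 8) {
  roi <- array(FALSE, d)
  p <- sapply(d, function(k) sample(2:(k - 1), 1))
  for (s in 1:8) {
    roi[p[1], p[2], p[3]] <- TRUE
    p <- pmin(pmax(p + sample(-1:1, 3, replace = TRUE), 1), d)
  }
  roi[sample(prod(d), n_extra)] <- TRUE
  roi
}

# flood fill labeling oracle: iterative label propagation to a fixed point
oracle_flood_fill_sizes <- function(mask, connectivity = 26) {
  idx <- which(mask != 0)
  if (!length(idx)) return(integer(0))
  cc <- arrayInd(idx, dim(mask))
  n <- length(idx)
  lab <- seq_len(n)
  nb_of <- function(i, j) {
    d <- abs(cc[i, ] - cc[j, ])
    i != j && switch(as.character(connectivity),
      "26" = max(d) == 1,
      "18" = max(d) == 1 && sum(d) <= 2,
      "6"  = sum(d) == 1)
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (nb_of(i, j) && lab[j] < lab[i]) { lab[i] <- lab[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  sort(as.integer(table(lab)), decreasing = TRUE)
}

# independent recursive permutation enumerator (rows = permutations)
oracle_all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

# small fast phantom config for unit tests
tiny_config <- function(...) {
  phantom_config(n_per_group = c(HC = 3, MSA = 3, PD = 3),
                 n_acquisitions = 1, ...)
}
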