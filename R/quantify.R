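# Sub-regional LC neuromelanin contrast extraction: slice normalization,
# search-ROI tri-section, five-brightest-connected-voxel extraction and
# the NM contrast ratio.

#' Slice-to-slice intensity normalization
#'
#' Scales every axial slice by (global in-mask mean) / (slice in-mask
#' mean), removing multiplicative per-slice drift while preserving the
#' global in-mask mean.  Slices with an empty brain mask are left
#' unscaled and recorded in the `unscaled_slices` attribute.
#'
#' @param volume 3-D intensity array (axial axis third).
#' @param brain_mask logical/0-1 mask on the same grid; should exclude
#'   the hyperintense structures being quantified.
#' @return normalized volume (attributes preserved).
#' @export
normalize_slices <- function(volume, brain_mask) {
  d <- dim(volume)
  if (!identical(d, dim(brain_mask)))
    stop("volume and brain mask are on different grids", call. = FALSE)
  bm <- brain_mask != 0
  if (!any(bm)) stop("brain mask is empty", call. = FALSE)
  nz <- d[3]
  slice_mean <- vapply(seq_len(nz), function(z) {
    sl <- volume[, , z][bm[, , z]]
    if (length(sl)) mean(sl) else NA_real_
  }, numeric(1))
  global_mean <- mean(volume[bm])
  scale <- global_mean / slice_mean
  unscaled <- which(!is.finite(scale))
  scale[unscaled] <- 1
  out <- volume * rep(scale, each = d[1] * d[2])
  attributes(out) <- attributes(volume)
  attr(out, "unscaled_slices") <- unscaled
  out
}

#' Trisect a search ROI into rostral, middle and caudal thirds
#'
#' Partitions the ROI by axial slice index into three contiguous blocks
#' (superior block = rostral).  When the slice count is not divisible by
#' three the remainder is assigned rostral-first, e.g. 8 slices give
#' blocks of (3, 3, 2).
#'
#' @param search_roi logical/0-1 3-D mask spanning >= 3 axial slices.
#' @return named list of three masks (`rostral`, `middle`, `caudal`)
#'   forming a partition of the input.
#' @export
trisect_roi <- function(search_roi) {
  m <- search_roi != 0
  slices <- which(apply(m, 3, any))
  if (length(slices) < 3L)
    stop("search ROI must span at least 3 axial slices", call. = FALSE)
  blocks <- trisect_slices(slices)
  lapply(blocks, function(zs) {
    out <- array(FALSE, dim(m))
    out[, , zs] <- m[, , zs]
    out
  })
}

# adjacency list among a set of voxel coordinates (k x 3 matrix)
voxel_adjacency <- function(coords, connectivity = 26) {
  v <- nrow(coords)
  off <- conn_offsets(connectivity)
  span <- apply(coords, 2, max) + 1L
  key <- function(cc) (cc[, 1] * span[2] + cc[, 2]) * span[3] + cc[, 3]
  keys <- key(coords)
  lapply(seq_len(v), function(i) {
    nb <- coords[rep(i, nrow(off)), , drop = FALSE] + off
    hits <- match(key(nb), keys)
    sort(hits[!is.na(hits)])
  })
}

# greedy bright-cluster growth from a seed (ranks refer to `vals`)
greedy_grow <- function(seed, k, adj, vals) {
  s <- seed
  repeat {
    if (length(s) == k) break
    cand <- setdiff(unique(unlist(adj[s])), s)
    if (!length(cand)) break
    s <- c(s, cand[which.max(vals[cand])])
  }
  s
}

#' Extract the brightest connected voxel subset of an ROI
#'
#' Finds the connected subset of `k` voxels inside `roi` that maximizes
#' mean intensity.  The default method is an exact branch-and-bound
#' enumeration of connected subsets (initialized by greedy growth from
#' the `n_seeds` brightest voxels); `method = "greedy"` returns the best
#' greedy cluster instead.  If the ROI (or its largest connected
#' component) holds fewer than `k` voxels the result uses all available
#' voxels and is flagged `undersized`.
#'
#' @param volume 3-D intensity array.
#' @param roi logical/0-1 mask; the search is restricted to its voxels.
#' @param k subset size (default 5, the five brightest connected voxels).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param method `"exact"` (default) or `"greedy"`.
#' @param n_seeds number of brightest seed voxels for greedy
#'   initialization.
#' @return list with `voxels` (subset coordinates, one row per voxel),
#'   `mean` (their mean intensity), `k` (subset size used) and `flag`
#'   (`"ok"` or `"undersized"`).
#' @export
extract_brightest_connected <- function(volume, roi, k = 5L,
                                        connectivity = 26,
                                        method = c("exact", "greedy"),
                                        n_seeds = 10L) {
  method <- match.arg(method)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  idx <- which(roi != 0)
  if (!length(idx)) stop("ROI is empty", call. = FALSE)
  coords <- arrayInd(idx, dim(volume))
  vals <- volume[idx]
  flag <- "ok"

  if (length(idx) <= k) {
    return(list(voxels = coords, mean = mean(vals), k = length(idx),
                flag = if (length(idx) < k) "undersized" else "ok"))
  }

  adj <- voxel_adjacency(coords, connectivity)

  # restrict k to the largest component if necessary
  comp <- label_components(roi != 0, connectivity)
  comp_of <- comp[idx]
  max_comp <- max(tabulate(comp_of))
  if (max_comp < k) {
    k <- max_comp
    flag <- "undersized"
  }

  ord <- order(vals, decreasing = TRUE)          # ranks in brightness order
  rank_of <- integer(length(vals)); rank_of[ord] <- seq_along(ord)
  svals <- vals[ord]                             # sorted descending
  sadj <- lapply(ord, function(i) sort(rank_of[adj[[i]]]))

  # greedy initialization from the brightest seeds
  best_set <- NULL; best_sum <- -Inf
  for (seed in seq_len(min(n_seeds, length(svals)))) {
    s <- greedy_grow(seed, k, sadj, svals)
    if (length(s) == k && sum(svals[s]) > best_sum) {
      best_sum <- sum(svals[s]); best_set <- s
    }
  }
  if (is.null(best_set)) {  # all seeds stuck in tiny components
    for (seed in seq_along(svals)) {
      s <- greedy_grow(seed, k, sadj, svals)
      if (length(s) == k) { best_sum <- sum(svals[s]); best_set <- s; break }
    }
  }

  if (method == "exact") {
    # upper bound for a partial set: its sum plus the largest remaining
    # values with rank > start, ignoring connectivity
    suffix_top <- function(start, exclude, need) {
      tot <- 0; got <- 0L; j <- start + 1L
      while (got < need && j <= length(svals)) {
        if (!(j %in% exclude)) { tot <- tot + svals[j]; got <- got + 1L }
        j <- j + 1L
      }
      if (got < need) -Inf else tot
    }
    env <- new.env()
    env$best_sum <- best_sum; env$best_set <- best_set
    recurse <- function(set, sum_set, ext, start) {
      if (length(set) == k) {
        if (sum_set > env$best_sum) {
          env$best_sum <- sum_set; env$best_set <- set
        }
        return(invisible())
      }
      need <- k - length(set)
      while (length(ext)) {
        ub <- sum_set + suffix_top(start, set, need)
        if (ub <= env$best_sum + 1e-12) return(invisible())
        w <- ext[1L]; ext <- ext[-1L]
        nb <- sadj[[w]]
        nb <- nb[nb > start & !(nb %in% set) & !(nb %in% ext) & nb != w]
        recurse(c(set, w), sum_set + svals[w], c(ext, nb), start)
      }
      invisible()
    }
    for (s in seq_len(length(svals) - k + 1L)) {
      if (sum(svals[s:(s + k - 1L)]) <= env$best_sum + 1e-12) break
      ext <- sadj[[s]]; ext <- ext[ext > s]
      recurse(s, svals[s], ext, s)
    }
    best_set <- env$best_set; best_sum <- env$best_sum
  }

  sel <- ord[best_set]
  list(voxels = coords[sel, , drop = FALSE],
       mean = mean(vals[sel]), k = k, flag = flag)
}

#' Neuromelanin contrast ratio
#'
#' `(roi_mean - background_mean) / background_mean`, the LC neuromelanin
#' contrast used throughout the package.
#'
#' @param roi_mean mean intensity of the extracted LC voxels.
#' @param background_mean mean intensity of the background (pontine) ROI;
#'   must be positive.
#' @return dimensionless contrast (vectorized).
#' @export
compute_nm_contrast <- function(roi_mean, background_mean) {
  if (any(!is.finite(background_mean)) || any(background_mean <= 0))
    stop("background mean must be positive", call. = FALSE)
  (roi_mean - background_mean) / background_mean
}

#' Quantify sub-regional LC neuromelanin contrast for one subject
#'
#' Applies slice normalization, computes the background mean over the
#' background ROI, tri-sects each search ROI into rostral/middle/caudal
#' thirds, extracts the `k` brightest connected voxels per side and
#' third, converts to NM contrast and averages left/right.
#'
#' @param volume neuromelanin-sensitive 3-D intensity array.
#' @param rois named list of masks on the same grid: `search_roi_left`,
#'   `search_roi_right`, `background_roi`, `brain_mask`.
#' @param k voxels extracted per side and subregion (default 5).
#' @param connectivity voxel connectivity for the extraction (default 26).
#' @param method extraction method, see [extract_brightest_connected()].
#' @param normalize apply [normalize_slices()] first (default TRUE).
#' @param background_scope `"whole"` (default: one background mean over
#'   the full background ROI) or `"per_subregion"` (background restricted
#'   to each subregion's slice extent).
#' @return object of class `lc_contrast`: list with `by_side`
#'   (data.frame: side, subregion, roi_mean, background_mean, contrast,
#'   flag), `averaged` (named length-3 vector of left/right-averaged
#'   contrasts), `background_mean`, and `selected_voxels` (audit list of
#'   coordinates).
#' @export
quantify_subject <- function(volume, rois, k = 5L, connectivity = 26,
                             method = c("exact", "greedy"),
                             normalize = TRUE,
                             background_scope = c("whole", "per_subregion")) {
  method <- match.arg(method)
  background_scope <- match.arg(background_scope)
  needed <- c("search_roi_left", "search_roi_right", "background_roi",
              "brain_mask")
  if (!all(needed %in% names(rois)))
    stop("`rois` must contain: ", paste(needed, collapse = ", "),
         call. = FALSE)
  for (nm in needed)
    if (!identical(dim(volume), dim(rois[[nm]])))
      stop("mask `", nm, "` is not on the volume grid", call. = FALSE)
  if (!any(rois$background_roi != 0))
    stop("background ROI is empty", call. = FALSE)

  vol <- if (normalize) normalize_slices(volume, rois$brain_mask) else volume

  bg_all <- mean(vol[rois$background_roi != 0])
  subregions <- c("rostral", "middle", "caudal")
  rows <- list(); selected <- list()
  for (side in c("left", "right")) {
    sr <- rois[[paste0("search_roi_", side)]]
    thirds <- trisect_roi(sr)
    for (reg in subregions) {
      bg <- if (background_scope == "whole") bg_all else {
        zs <- which(apply(thirds[[reg]], 3, any))
        bgm <- rois$background_roi != 0
        bgm[, , setdiff(seq_len(dim(vol)[3]), zs)] <- FALSE
        if (!any(bgm)) bg_all else mean(vol[bgm])
      }
      ex <- extract_brightest_connected(vol, thirds[[reg]], k = k,
                                        connectivity = connectivity,
                                        method = method)
      rows[[paste(side, reg)]] <- data.frame(
        side = side, subregion = reg, roi_mean = ex$mean,
        background_mean = bg,
        contrast = compute_nm_contrast(ex$mean, bg),
        flag = ex$flag, stringsAsFactors = FALSE)
      selected[[paste(side, reg, sep = "_")]] <- ex$voxels
    }
  }
  by_side <- do.call(rbind, rows)
  rownames(by_side) <- NULL
  averaged <- vapply(subregions, function(reg)
    mean(by_side$contrast[by_side$subregion == reg]), numeric(1))
  structure(list(by_side = by_side, averaged = averaged,
                 background_mean = bg_all, selected_voxels = selected),
            class = "lc_contrast")
}

#' @export
print.lc_contrast <- function(x, ...) {
  cat("LC neuromelanin contrast (left/right averaged):\n")
  print(round(x$averaged, 4))
  cat("background mean:", format(x$background_mean), "\n")
  if (any(x$by_side$flag != "ok"))
    cat("note: undersized ROI flags present\n")
  invisible(x)
}

#' Tabulate per-subject contrasts across a cohort
#'
#' @param results named list of `lc_contrast` objects (names = subject
#'   ids).
#' @return long data.frame: subject_id, side, subregion, roi_mean,
#'   background_mean, contrast, flag (side `"avg"` rows carry the
#'   left/right average).
#' @export
contrast_table <- function(results) {
  do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    avg <- data.frame(side = "avg", subregion = names(r$averaged),
                      roi_mean = NA_real_,
                      background_mean = r$background_mean,
                      contrast = as.numeric(r$averaged), flag = "ok",
                      stringsAsFactors = FALSE)
    out <- rbind(r$by_side, avg)
    cbind(subject_id = id, out, stringsAsFactors = FALSE)
  }))
}
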