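# 3-D volume helpers shared by all modules.  Volumes are plain numeric
# arrays; voxel spacing travels in the "voxel_size_mm" attribute (or the
# NIfTI pixdim when read from disk).  The axial (slice) axis is the third
# array dimension throughout.

#' Attach voxel spacing metadata to a 3-D array
#'
#' @param x 3-D numeric array.
#' @param voxel_size_mm numeric length-3, per-axis spacing in mm.
#' @return the array with a `voxel_size_mm` attribute.
#' @export
as_volume <- function(x, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(x)) != 3L)
    stop("`x` must be a 3-D array")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive finite values")
  attr(x, "voxel_size_mm") <- as.numeric(voxel_size_mm)
  x
}

#' Voxel spacing of a volume
#'
#' Reads the `voxel_size_mm` attribute, falling back to the NIfTI pixdim
#' for images read with [read_volume()], then to 1 mm isotropic.
#'
#' @param x 3-D array or `niftiImage`.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_mm")
  if (!is.null(vs)) return(as.numeric(vs))
  if (inherits(x, "niftiImage")) {
    pd <- RNifti::pixdim(x)
    if (length(pd) >= 3L && all(pd[1:3] > 0)) return(as.numeric(pd[1:3]))
  }
  c(1, 1, 1)
}

#' Read a 3-D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return numeric 3-D array with a `voxel_size_mm` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  as_volume(arr, ifelse(vs > 0, vs, 1))
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param x 3-D array (mask or intensity volume).
#' @param path output path (`.nii.gz` recommended).
#' @param voxel_size_mm spacing in mm; defaults to [voxel_size()] of `x`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = voxel_size(x)) {
  dat <- if (is.logical(x)) array(as.integer(x), dim(x)) else x
  img <- RNifti::asNifti(array(dat, dim(x)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Neighbourhood offset matrix (m x 3) for 6-, 18- or 26-connectivity.
conn_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1,
    "18" = ord >= 1 & ord <= 2,
    "26" = ord >= 1)
  unname(g[keep, , drop = FALSE])
}

#' Label connected components of a 3-D binary mask
#'
#' Breadth-first labeling with 6-, 18- (SPM cluster convention) or
#' 26-neighbourhood connectivity.
#'
#' @param mask logical/0-1 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in decreasing size order.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3-D array")
  lab <- array(0L, d)
  idx <- which(mask != 0)
  if (length(idx) == 0L) return(lab)
  off <- conn_offsets(connectivity)
  coords <- arrayInd(idx, d)
  # compact id lookup over the full grid
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  comp <- integer(length(idx))
  cur <- 0L
  for (i in seq_along(idx)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    comp[i] <- cur
    frontier <- i
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(fc)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) { frontier <- integer(0); next }
      ids <- vid[nb]
      ids <- unique(ids[ids > 0L])
      ids <- ids[comp[ids] == 0L]
      comp[ids] <- cur
      frontier <- ids
    }
  }
  # renumber components largest-first for stable downstream reporting
  sz <- tabulate(comp, cur)
  ord <- order(sz, decreasing = TRUE)
  renum <- integer(cur)
  renum[ord] <- seq_len(cur)
  lab[idx] <- renum[comp]
  lab
}

# sizes of labeled components, by label
component_sizes <- function(labels) {
  m <- max(labels)
  if (m == 0L) integer(0) else tabulate(labels[labels > 0L], m)
}
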