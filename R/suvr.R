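# FDG-PET SUVR computation and Gaussian smoothing.

#' Compute an SUVR image from a PET uptake volume
#'
#' Divides every voxel by the median uptake inside the reference region
#' (the lateral-occipital-like reference mask), yielding a dimensionless
#' standardized uptake value ratio image whose in-reference median is 1.
#'
#' @param pet 3-D uptake array.
#' @param reference_mask logical/0-1 mask on the same grid; nonempty,
#'   with positive median uptake.
#' @return SUVR array with attributes `reference_median` and `fwhm_mm`
#'   (0, no smoothing applied yet).
#' @export
compute_suvr <- function(pet, reference_mask) {
  if (!identical(dim(pet), dim(reference_mask)))
    stop("PET volume and reference mask are on different grids",
         call. = FALSE)
  ref <- pet[reference_mask != 0]
  if (!length(ref)) stop("reference mask is empty", call. = FALSE)
  med <- median(ref)
  if (!is.finite(med) || med <= 0)
    stop("reference-region median uptake must be positive", call. = FALSE)
  out <- pet / med
  attributes(out) <- attributes(pet)
  attr(out, "reference_median") <- med
  attr(out, "fwhm_mm") <- 0
  out
}

# 1-D smoothing matrix (L x L) with symmetric (reflect) boundary; columns
# sum to 1, so total image mass is preserved.
gaussian_slab_matrix <- function(L, sigma_vox) {
  if (sigma_vox <= 0) return(diag(L))
  r <- max(1L, ceiling(4.5 * sigma_vox))
  w <- dnorm(-r:r, sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, L, L)
  for (i in seq_len(L)) {
    j <- i + (-r:r)
    # fold out-of-range indices back into [1, L] (mirror, edge repeated)
    while (any(j < 1L | j > L)) {
      j <- ifelse(j < 1L, 1L - j, j)
      j <- ifelse(j > L, 2L * L + 1L - j, j)
    }
    for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + w[t]
  }
  K
}

#' Smooth a volume with a separable Gaussian kernel
#'
#' Per-axis sigma is `fwhm_mm / sqrt(8 log 2) / voxel_size_mm[axis]`
#' (anisotropic voxels handled per axis).  Boundary handling is
#' reflection, which preserves total image intensity.
#'
#' @param volume 3-D array.
#' @param fwhm_mm full width at half maximum in mm (scalar, >= 0; 0 is
#'   the identity).
#' @param voxel_size_mm per-axis spacing; defaults to [voxel_size()] of
#'   the volume.
#' @return smoothed array; attribute `fwhm_mm` records the kernel.
#' @export
smooth_gaussian <- function(volume, fwhm_mm,
                            voxel_size_mm = voxel_size(volume)) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be >= 0", call. = FALSE)
  d <- dim(volume)
  atts <- attributes(volume)
  out <- volume
  if (fwhm_mm > 0) {
    sigma_mm <- fwhm_mm / sqrt(8 * log(2))
    for (ax in 1:3) {
      sig <- sigma_mm / voxel_size_mm[ax]
      K <- gaussian_slab_matrix(d[ax], sig)
      perm <- c(ax, setdiff(1:3, ax))
      x <- aperm(out, perm)
      x <- array(K %*% matrix(x, d[ax]), d[perm])
      out <- aperm(x, order(perm))
    }
  }
  attributes(out) <- atts
  attr(out, "fwhm_mm") <- fwhm_mm
  out
}
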