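# CBF-FCS neurovascular coupling. Per subject, both maps are smoothed
# (6-mm FWHM Gaussian, mask-renormalized), z-scored within the gray-matter
# mask, and correlated across in-mask voxels - globally and within each
# atlas region.

gaussian_kernel_matrix <- function(L, sigma_vox) {
  if (sigma_vox <= 0) return(diag(L))
  r <- ceiling(4 * sigma_vox)
  d <- outer(seq_len(L), seq_len(L), `-`)
  K <- exp(-d^2 / (2 * sigma_vox^2))
  K[abs(d) > r] <- 0
  K
}

# separable 3D convolution: multiply the axis kernel into each dimension
conv_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  out <- K %*% m
  a <- array(out, dim(a))
  aperm(a, order(perm))
}

conv3 <- function(arr, kernels) {
  for (ax in 1:3) arr <- conv_axis(arr, kernels[[ax]], ax)
  arr
}

#' Mask-renormalized Gaussian smoothing
#'
#' Smooths a map with a separable Gaussian kernel of the given full width at
#' half maximum (per axis, in mm; sigma = fwhm / (2 sqrt(2 ln 2))). Out-of-
#' mask voxels carry zero weight and the kernel is renormalized over the
#' in-mask neighborhood, so a constant map stays constant and no signal
#' bleeds across the mask edge. `fwhm_mm = 0` is the identity.
#'
#' @param vol a [masked_volume].
#' @param fwhm_mm full width at half maximum in mm (scalar).
#' @return The smoothed [masked_volume] (same mask).
#' @export
smooth_map <- function(vol, fwhm_mm = 6) {
  if (fwhm_mm < 0) stop_nc("fwhm must be >= 0", "nc_validation_error")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(vol$data)
  kernels <- lapply(1:3, function(ax)
    gaussian_kernel_matrix(d[ax], sigma_mm / vol$voxel_size_mm[ax]))
  m <- array(as.numeric(vol$mask), d)
  num <- conv3(vol$data * m, kernels)
  den <- conv3(m, kernels)
  out <- array(0, d)
  out[vol$mask] <- num[vol$mask] / den[vol$mask]
  masked_volume(out, vol$mask, vol$voxel_size_mm)
}

#' Global CBF-FCS coupling
#'
#' Pearson correlation between two z-scored maps across all in-mask voxels:
#' one coupling coefficient per subject at the global gray-matter level.
#'
#' @param cbf_z,fcs_z z-scored [masked_volume]s on the same grid.
#' @param mask optional common mask (defaults to the CBF map's).
#' @return Scalar correlation.
#' @export
global_coupling <- function(cbf_z, fcs_z, mask = NULL) {
  if (!same_grid(cbf_z, fcs_z))
    stop_nc("map grids differ", "nc_grid_mismatch_error")
  if (is.null(mask)) mask <- cbf_z$mask
  if (sum(mask) < 3)
    stop_nc("need at least 3 in-mask voxels", "nc_validation_error")
  cor(cbf_z$data[mask], fcs_z$data[mask])
}

#' Regional CBF-FCS coupling
#'
#' Per atlas region, the Pearson correlation of the two z-maps across that
#' region's in-mask voxels - a per-subject regional coupling scalar. Regions
#' with fewer than 3 in-mask voxels are reported as missing (`NA`), never
#' fabricated.
#'
#' @param cbf_z,fcs_z z-scored [masked_volume]s.
#' @param atlas an [atlas_parcellation] on the same grid.
#' @param mask optional common mask (defaults to the CBF map's).
#' @return data.frame with `region_id`, `r`, `n_voxels`.
#' @export
regional_coupling <- function(cbf_z, fcs_z, atlas, mask = NULL) {
  if (is.null(mask)) mask <- cbf_z$mask
  if (!identical(dim(atlas$labels), dim(cbf_z$data)))
    stop_nc("atlas grid differs from the maps", "nc_grid_mismatch_error")
  lab <- as.vector(atlas$labels)[as.vector(mask)]
  x <- cbf_z$data[mask]; y <- fcs_z$data[mask]
  ids <- atlas$regions$id
  r <- vapply(ids, function(id) {
    i <- lab == id
    if (sum(i) < 3) NA_real_ else cor(x[i], y[i])
  }, numeric(1))
  n <- vapply(ids, function(id) sum(lab == id), integer(1))
  data.frame(region_id = ids, r = r, n_voxels = n)
}

#' Per-subject coupling analysis
#'
#' The full per-subject coupling stage: smooth both raw maps (6-mm FWHM by
#' default), z-score each within the mask, then compute the global and
#' regional coupling coefficients.
#'
#' @param cbf,fcs raw CBF and FCS [masked_volume]s.
#' @param atlas an [atlas_parcellation] (or `NULL` for global only).
#' @param mask optional common mask.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param subject_id identifier carried into the result.
#' @return Object of class `coupling_result`: list with `subject_id`,
#'   `global_r`, `regional` (data.frame or `NULL`).
#' @export
coupling_analysis <- function(cbf, fcs, atlas = NULL, mask = NULL,
                              fwhm_mm = 6, subject_id = NA_character_) {
  if (is.null(mask)) mask <- cbf$mask
  cbf_s <- smooth_map(masked_volume(cbf$data, mask, cbf$voxel_size_mm), fwhm_mm)
  fcs_s <- smooth_map(masked_volume(fcs$data, mask, fcs$voxel_size_mm), fwhm_mm)
  cbf_z <- zscore_map(cbf_s)
  fcs_z <- zscore_map(fcs_s)
  res <- structure(list(
    subject_id = subject_id,
    global_r = global_coupling(cbf_z, fcs_z, mask),
    regional = if (is.null(atlas)) NULL
               else regional_coupling(cbf_z, fcs_z, atlas, mask)),
    class = "coupling_result")
  nc_log("coupling_analysis", subject = subject_id, fwhm = fwhm_mm,
         global_r = round(res$global_r, 4))
  res
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result %s: global r = %.3f%s>\n",
              x$subject_id, x$global_r,
              if (is.null(x$regional)) ""
              else sprintf(", %d regions", nrow(x$regional))))
  invisible(x)
}

#' Group-level voxelwise coupling map
#'
#' The across-subject alternative reading of regional coupling: at each
#' in-mask voxel, the Pearson correlation between CBF and FCS z-values
#' across subjects. Not part of the default per-subject pipeline.
#'
#' @param cbf_z_list,fcs_z_list lists of z-scored [masked_volume]s, one per
#'   subject, on a common grid and mask.
#' @return A [masked_volume] of voxelwise across-subject correlations.
#' @export
coupling_group_map <- function(cbf_z_list, fcs_z_list) {
  n <- length(cbf_z_list)
  if (n < 3) stop_nc("need at least 3 subjects", "nc_validation_error")
  mask <- cbf_z_list[[1]]$mask
  X <- vapply(cbf_z_list, function(v) v$data[mask], numeric(sum(mask)))
  Y <- vapply(fcs_z_list, function(v) v$data[mask], numeric(sum(mask)))
  xc <- X - rowMeans(X); yc <- Y - rowMeans(Y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  out <- array(0, dim(mask))
  out[mask] <- r
  masked_volume(out, mask, cbf_z_list[[1]]$voxel_size_mm)
}
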