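# Voxelwise functional connectivity strength (FCS): a weighted
# degree-centrality measure. For voxel i,
#
#   FCS_i = (1 / (N - 1)) * sum_{j != i} r_ij * [r_ij >= r0]
#
# with r_ij the Pearson correlation between the two voxel series and
# r0 = 0.2 by default. Correlations lower than r0 are set to zero (r0 itself
# is kept); with the default "all" denominator the zeroed pairs still count
# in N - 1, so FCS lies in [0, 1]. No spatial smoothing is applied before
# FCS - smoothing belongs to the coupling stage only.

#' Compute a voxelwise FCS map
#'
#' @param bold preprocessed [bold_series].
#' @param mask 3D logical gray-matter mask.
#' @param threshold correlation threshold `r0` in `[0, 1)`; values below it
#'   are zeroed, the boundary value is kept.
#' @param denominator `"all"` divides by the number of remaining voxels
#'   (N - 1, the default); `"suprathreshold"` divides by the number of
#'   surviving correlations for the voxel.
#' @return FCS [masked_volume]. Zero-variance voxels are dropped from the
#'   output mask, with the count in attribute `n_zero_variance`.
#' @export
compute_fcs <- function(bold, mask, threshold = 0.2,
                        denominator = c("all", "suprathreshold")) {
  denominator <- match.arg(denominator)
  if (!(threshold >= 0 && threshold < 1))
    stop_nc("threshold must lie in [0, 1)", "nc_validation_error")
  mask <- array(as.logical(mask), dim(mask))
  ts <- bold_matrix(bold, mask)            # time x voxels
  v <- apply(ts, 2, var)
  flat_idx <- which(as.vector(mask))
  nzv <- sum(v == 0)
  if (nzv > 0) {
    nc_log("compute_fcs", n_zero_variance_dropped = nzv)
    keep <- v > 0
    flat_idx <- flat_idx[keep]
    ts <- ts[, keep, drop = FALSE]
    mask <- array(FALSE, dim(mask)); mask[flat_idx] <- TRUE
  }
  N <- ncol(ts)
  if (N < 2) stop_nc("need at least 2 in-mask voxels", "nc_validation_error")
  R <- cor(ts)
  keepR <- R >= threshold
  diag(keepR) <- FALSE
  s <- rowSums(R * keepR)
  fcs <- if (denominator == "all") s / (N - 1) else {
    cnt <- rowSums(keepR)
    ifelse(cnt > 0, s / cnt, 0)
  }
  out <- array(0, dim(mask))
  out[flat_idx] <- fcs
  res <- masked_volume(out, mask, bold$voxel_size_mm)
  attr(res, "n_zero_variance") <- nzv
  nc_log("compute_fcs", n_voxels = N, threshold = threshold,
         denominator = denominator)
  res
}

#' Z-score a map within its mask
#'
#' Subtracts the in-mask mean and divides by the in-mask sample standard
#' deviation, so the result has mean 0 and SD 1 over the mask (global
#' gray-matter standardization).
#'
#' @param vol a [masked_volume].
#' @param mask optional replacement mask (defaults to the volume's own).
#' @return The z-scored [masked_volume].
#' @export
zscore_map <- function(vol, mask = NULL) {
  if (is.null(mask)) mask <- vol$mask
  v <- vol$data[mask]
  s <- sd(v)
  if (!is.finite(s) || s == 0)
    stop_nc("cannot z-score a constant map", "nc_validation_error")
  out <- array(0, dim(vol$data))
  out[mask] <- (v - mean(v)) / s
  masked_volume(out, mask, vol$voxel_size_mm)
}
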