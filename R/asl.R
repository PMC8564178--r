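# Single-compartment pCASL quantification.
#
# CBF (ml/100g/min) is obtained from the mean control-label difference dM and
# the proton-density reference PD as
#
#   CBF = 6000 * lambda * dM * exp(PLD / T1b)
#         ---------------------------------------------
#         2 * alpha * T1b * PD * (1 - exp(-tau / T1b))
#
# the consensus single-compartment model for pseudo-continuous labeling, with
# lambda the partition coefficient (ml/g), alpha the labeling efficiency, T1b
# the longitudinal relaxation time of arterial blood (s), tau the labeling
# duration (s) and PLD the post-label delay (s). A single global alpha is
# used. Quantified values driven negative by noise are floored at 0 and the
# count is logged.

# voxelwise factor f with CBF = dM / (PD) * f_const, i.e. CBF = dM * f / PD
cbf_scaling_factor <- function(p, pd) {
  num <- 6000 * p$partition_coefficient *
    exp(p$post_label_delay_s / p$blood_t1_s)
  den <- 2 * p$labeling_efficiency * p$blood_t1_s *
    (1 - exp(-p$labeling_duration_s / p$blood_t1_s))
  num / (den * pd)
}

#' Mean label/control perfusion difference
#'
#' Voxelwise mean over pairs of (control - label), the perfusion-weighted
#' difference signal dM.
#'
#' @param asl an [asl_series].
#' @param mask optional 3D logical mask for the output volume.
#' @return dM as a [masked_volume].
#' @export
perfusion_difference <- function(asl, mask = NULL) {
  if (!inherits(asl, "asl_series"))
    stop_nc("expected an asl_series", "nc_validation_error")
  ctrl <- which(asl$tags == "control")
  labl <- which(asl$tags == "label")
  if (length(ctrl) == 0L)
    stop_nc("need at least one label/control pair", "nc_unpaired_error")
  dims <- dim(asl$frames)[1:3]
  flat <- matrix(asl$frames, ncol = dim(asl$frames)[4])
  dm <- rowMeans(flat[, ctrl, drop = FALSE]) - rowMeans(flat[, labl, drop = FALSE])
  nc_log("perfusion_difference", n_pairs = length(ctrl), grid = dims)
  masked_volume(array(dm, dims), mask = mask, voxel_size_mm = asl$voxel_size_mm)
}

#' Quantify CBF from the difference signal
#'
#' Applies the single-compartment model (see the formula at the top of this
#' file's source) voxelwise. CBF is linear in dM and inversely proportional
#' to the proton-density reference. Negative quantified values are floored at
#' 0; voxels with nonpositive PD inside the mask are reported in the
#' `error_mask` attribute and returned as 0.
#'
#' @param dm perfusion difference [masked_volume].
#' @param pd proton-density reference [masked_volume] (positive in-mask).
#' @param acq_params pCASL parameters, see [asl_params()].
#' @return CBF [masked_volume] in ml/100g/min, with attributes
#'   `n_clamped` (voxels floored at 0) and `error_mask` (nonpositive PD).
#' @export
quantify_cbf <- function(dm, pd, acq_params = asl_params()) {
  check_asl_params(acq_params)
  if (!same_grid(dm, pd))
    stop_nc("dM and PD grids differ", "nc_grid_mismatch_error")
  mask <- dm$mask
  bad <- mask & (pd$data <= 0)
  pd_safe <- ifelse(pd$data > 0, pd$data, 1)
  cbf <- dm$data * cbf_scaling_factor(acq_params, pd_safe)
  cbf[bad] <- 0
  n_clamped <- sum(cbf[mask] < 0)
  cbf <- pmax(cbf, 0)
  cbf[!mask] <- 0
  nc_log("quantify_cbf", n_clamped = n_clamped, n_bad_pd = sum(bad))
  out <- masked_volume(array(cbf, dim(dm$data)), mask, dm$voxel_size_mm)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "error_mask") <- bad
  out
}

#' One-call CBF estimation from an ASL series
#'
#' Convenience wrapper: [perfusion_difference()] then [quantify_cbf()] with
#' the series' own acquisition parameters and proton-density reference.
#'
#' @param asl an [asl_series].
#' @param mask optional 3D logical mask.
#' @return CBF [masked_volume].
#' @export
estimate_cbf <- function(asl, mask = NULL) {
  dm <- perfusion_difference(asl, mask)
  pd <- masked_volume(asl$pd_reference, mask = mask,
                      voxel_size_mm = asl$voxel_size_mm)
  quantify_cbf(dm, pd, asl$acq_params)
}
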