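#' @importFrom stats cor lm pf pt pchisq rnorm runif sd
#'   kruskal.test chisq.test anova quantile var .lm.fit
#' @importFrom utils read.delim write.table
NULL

# classed error helper: every distinct failure mode gets its own condition class
stop_nc <- function(msg, class) {
  stop(structure(
    class = c(class, "nc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

nc_log <- function(stage, ...) {
  lvl <- getOption("neurocouple.log_level", "info")
  if (identical(lvl, "quiet")) return(invisible(NULL))
  fields <- list(...)
  kv <- if (length(fields)) {
    paste(names(fields), vapply(fields, function(x) paste(format(x), collapse = "x"),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[neurocouple] stage=%s %s", stage, kv))
  invisible(NULL)
}

#' Scalar brain map restricted to a voxel mask
#'
#' A `masked_volume` couples a 3D scalar field (CBF in ml/100g/min, FCS,
#' z-scores, ...) with the boolean mask of voxels that carry meaning (e.g. a
#' gray-matter mask). Every statistic in the package ignores out-of-mask
#' voxels. All volumes in one analysis must share a single voxel grid; no
#' world-coordinate resampling is performed.
#'
#' @param data 3D numeric array.
#' @param mask 3D logical array of the same shape; defaults to all `TRUE`.
#' @param voxel_size_mm length-3 voxel edge lengths in mm.
#' @return An object of class `masked_volume`.
#' @export
masked_volume <- function(data, mask = NULL, voxel_size_mm = c(3, 3, 3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_nc("masked_volume data must be a 3D array", "nc_dimension_error")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(data), dim(mask)))
    stop_nc("data and mask shapes differ", "nc_dimension_error")
  if (any(!is.finite(data[mask])))
    stop_nc("non-finite values inside the mask", "nc_validation_error")
  structure(list(data = data, mask = mask,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "masked_volume")
}

#' @export
print.masked_volume <- function(x, ...) {
  v <- x$data[x$mask]
  cat(sprintf("<masked_volume %s, %d/%d in-mask, range [%.3g, %.3g]>\n",
              paste(dim(x$data), collapse = "x"), sum(x$mask), length(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' In-mask values of a masked volume
#' @param vol a [masked_volume].
#' @return Numeric vector of the values inside the mask.
#' @export
in_mask <- function(vol) vol$data[vol$mask]

same_grid <- function(a, b) identical(dim(a$data), dim(b$data))

#' Resting-state BOLD time series
#'
#' A 4D BOLD array (x, y, z, time) with its repetition time and, optionally,
#' per-frame rigid-body motion parameters (3 translations in mm, 3 rotations
#' in degrees) and nuisance signal columns.
#'
#' @param data 4D numeric array, time on the 4th dimension.
#' @param tr_s repetition time in seconds.
#' @param motion_params frames x 6 matrix or `NULL`.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(data, tr_s, motion_params = NULL,
                        voxel_size_mm = c(3, 3, 3)) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop_nc("bold_series data must be a 4D array", "nc_dimension_error")
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop_nc("tr_s must be positive", "nc_validation_error")
  nt <- dim(data)[4]
  if (!is.null(motion_params)) {
    motion_params <- as.matrix(motion_params)
    if (nrow(motion_params) != nt || ncol(motion_params) != 6L)
      stop_nc("motion_params must be frames x 6", "nc_validation_error")
  }
  structure(list(data = data, tr_s = tr_s, motion_params = motion_params,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series %s, %d frames, TR %.3g s>\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4], x$tr_s))
  invisible(x)
}

n_frames <- function(bold) dim(bold$data)[4]

# time x voxel matrix of the in-mask series
bold_matrix <- function(bold, mask) {
  nt <- n_frames(bold)
  m <- matrix(bold$data, ncol = nt)[as.vector(mask), , drop = FALSE]
  t(m)
}

#' Arterial spin labeling label/control series
#'
#' Ordered 3D frames tagged `label` or `control`, plus a proton-density
#' reference volume and the pCASL acquisition parameters used by the
#' single-compartment quantification: labeling duration tau (s), post-label
#' delay PLD (s), labeling efficiency alpha, blood T1 (s), and the blood-brain
#' partition coefficient lambda (ml/g).
#'
#' @param frames 4D array, one 3D volume per frame.
#' @param tags character vector of `"label"`/`"control"`, one per frame.
#' @param pd_reference 3D proton-density reference array.
#' @param acq_params named list; see [asl_params()] for the defaults.
#' @param voxel_size_mm length-3 voxel size in mm.
#' @return Object of class `asl_series`.
#' @export
asl_series <- function(frames, tags, pd_reference, acq_params = asl_params(),
                       voxel_size_mm = c(3, 3, 3)) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 4L)
    stop_nc("asl frames must be a 4D array", "nc_dimension_error")
  tags <- match.arg(tags, c("label", "control"), several.ok = TRUE)
  if (length(tags) != dim(frames)[4])
    stop_nc("one tag per frame required", "nc_validation_error")
  if (sum(tags == "label") != sum(tags == "control"))
    stop_nc("unequal numbers of label and control frames", "nc_unpaired_error")
  pd_reference <- as.array(pd_reference)
  if (!identical(dim(pd_reference), dim(frames)[1:3]))
    stop_nc("pd_reference grid differs from frames", "nc_dimension_error")
  check_asl_params(acq_params)
  structure(list(frames = frames, tags = tags, pd_reference = pd_reference,
                 acq_params = acq_params, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "asl_series")
}

#' pCASL acquisition parameters
#'
#' Defaults follow the consensus single-compartment quantification for
#' pseudo-continuous ASL: lambda = 0.9 ml/g, alpha = 0.85, blood T1 = 1.65 s,
#' labeling duration 1.45 s, post-label delay 2.025 s. All overridable.
#'
#' @param labeling_duration_s labeling duration tau in seconds.
#' @param post_label_delay_s post-label delay in seconds.
#' @param labeling_efficiency labeling efficiency alpha in (0, 1].
#' @param blood_t1_s longitudinal relaxation time of arterial blood, seconds.
#' @param partition_coefficient blood-brain partition coefficient, ml/g.
#' @return Named list of parameters.
#' @export
asl_params <- function(labeling_duration_s = 1.45, post_label_delay_s = 2.025,
                       labeling_efficiency = 0.85, blood_t1_s = 1.65,
                       partition_coefficient = 0.9) {
  p <- list(labeling_duration_s = labeling_duration_s,
            post_label_delay_s = post_label_delay_s,
            labeling_efficiency = labeling_efficiency,
            blood_t1_s = blood_t1_s,
            partition_coefficient = partition_coefficient)
  check_asl_params(p)
  p
}

check_asl_params <- function(p) {
  need <- c("labeling_duration_s", "post_label_delay_s", "labeling_efficiency",
            "blood_t1_s", "partition_coefficient")
  if (!all(need %in% names(p)))
    stop_nc("missing acquisition parameters", "nc_validation_error")
  vals <- unlist(p[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_nc("acquisition parameters must be positive", "nc_validation_error")
  if (p$labeling_efficiency > 1)
    stop_nc("labeling efficiency must lie in (0, 1]", "nc_validation_error")
  invisible(TRUE)
}

#' Integer-labeled brain parcellation
#'
#' A 3D integer label volume (0 = background) together with a region table
#' holding, per region, its id, name, and whether it is treated as a network
#' hub. Any labeled atlas on the analysis grid can be used; the number of
#' regions is free.
#'
#' @param labels 3D integer array, 0 for background.
#' @param regions data.frame with columns `id`, `name`, `is_hub`.
#' @return Object of class `atlas_parcellation`.
#' @export
atlas_parcellation <- function(labels, regions) {
  labels <- array(as.integer(labels), dim(labels))
  if (length(dim(labels)) != 3L)
    stop_nc("atlas labels must be a 3D array", "nc_dimension_error")
  regions <- as.data.frame(regions)
  if (!all(c("id", "name", "is_hub") %in% names(regions)))
    stop_nc("region table needs columns id, name, is_hub", "nc_validation_error")
  if (anyDuplicated(regions$id))
    stop_nc("region ids must be unique", "nc_validation_error")
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% regions$id))
    stop_nc("labels present in the volume but missing from the region table",
            "nc_validation_error")
  structure(list(labels = labels, regions = regions),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat(sprintf("<atlas_parcellation %s, %d regions (%d hubs)>\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$regions),
              sum(x$regions$is_hub)))
  invisible(x)
}
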