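# Temporal BOLD preprocessing and motion quality control. The stage order is
# fixed: discard initial frames -> nuisance regression -> band-pass. Spatial
# steps (slice timing, realignment, normalization) are out of scope: inputs
# are assumed to live on one common grid and motion parameters arrive as
# data.

#' Nuisance regressor set
#'
#' Regressors removed from every voxel series by ordinary least squares:
#' an optional linear trend, mean white-matter and CSF signals, and the
#' rigid-body motion parameters (all 6 by default; set
#' `motion_regressors` to the 3 translation columns for the
#' translations-only variant).
#'
#' @param linear_trend include a linear trend column?
#' @param wm_mean,csf_mean per-frame mean tissue signals (or `NULL`).
#' @param motion_regressors frames x k matrix of motion parameters (or `NULL`).
#' @return Object of class `nuisance_set`.
#' @export
nuisance_set <- function(linear_trend = TRUE, wm_mean = NULL, csf_mean = NULL,
                         motion_regressors = NULL) {
  lens <- c(length(wm_mean), length(csf_mean),
            if (!is.null(motion_regressors)) nrow(as.matrix(motion_regressors)))
  lens <- lens[lens > 0]
  if (length(unique(lens)) > 1)
    stop_nc("nuisance regressor lengths differ", "nc_validation_error")
  structure(list(linear_trend = isTRUE(linear_trend), wm_mean = wm_mean,
                 csf_mean = csf_mean,
                 motion_regressors = if (is.null(motion_regressors)) NULL
                                     else as.matrix(motion_regressors)),
            class = "nuisance_set")
}

# trim a nuisance set to frames kept after discard
trim_nuisance <- function(nuis, keep) {
  nuisance_set(nuis$linear_trend,
               if (!is.null(nuis$wm_mean)) nuis$wm_mean[keep],
               if (!is.null(nuis$csf_mean)) nuis$csf_mean[keep],
               if (!is.null(nuis$motion_regressors))
                 nuis$motion_regressors[keep, , drop = FALSE])
}

nuisance_design <- function(nuis, nt) {
  X <- matrix(1, nt, 1, dimnames = list(NULL, "intercept"))
  if (nuis$linear_trend)
    X <- cbind(X, trend = seq_len(nt) - (nt + 1) / 2)
  if (!is.null(nuis$wm_mean)) X <- cbind(X, wm = nuis$wm_mean)
  if (!is.null(nuis$csf_mean)) X <- cbind(X, csf = nuis$csf_mean)
  if (!is.null(nuis$motion_regressors)) {
    mp <- nuis$motion_regressors
    colnames(mp) <- paste0("mp", seq_len(ncol(mp)))
    X <- cbind(X, mp)
  }
  if (nrow(X) != nt)
    stop_nc("nuisance regressor length differs from frame count",
            "nc_validation_error")
  X
}

#' Discard initial BOLD frames
#'
#' Drops the first `n` volumes (magnetization-equilibration frames); motion
#' parameters are truncated in lockstep.
#'
#' @param bold a [bold_series].
#' @param n frames to discard (default 10).
#' @return The shortened [bold_series].
#' @export
discard_initial <- function(bold, n = 10) {
  nt <- n_frames(bold)
  if (nt - n < 20)
    stop_nc("fewer than 20 frames would remain after discard",
            "nc_validation_error")
  if (n == 0) return(bold)
  keep <- (n + 1):nt
  out <- bold_series(bold$data[, , , keep, drop = FALSE], bold$tr_s,
                     if (!is.null(bold$motion_params))
                       bold$motion_params[keep, , drop = FALSE],
                     bold$voxel_size_mm)
  for (a in c("wm_mean", "csf_mean"))
    if (!is.null(attr(bold, a))) attr(out, a) <- attr(bold, a)[keep]
  nc_log("discard_initial", dropped = n, remaining = length(keep))
  out
}

#' Regress nuisance signals out of every voxel series
#'
#' Each voxel's time series is replaced by its residual from an ordinary
#' least-squares fit on the intercept plus the nuisance regressors, leaving
#' residuals exactly orthogonal to every regressor.
#'
#' @param bold a [bold_series].
#' @param nuisance a [nuisance_set].
#' @return A [bold_series] of residual series.
#' @export
regress_nuisance <- function(bold, nuisance) {
  nt <- n_frames(bold)
  X <- nuisance_design(nuisance, nt)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_nc(paste("rank-deficient nuisance design; collinear columns:",
                  paste(dropped, collapse = ", ")), "nc_rank_error")
  }
  Y <- matrix(bold$data, ncol = nt)        # voxels x time
  res <- t(qr.resid(qrX, t(Y)))
  out <- bold_series(array(res, dim(bold$data)), bold$tr_s,
                     bold$motion_params, bold$voxel_size_mm)
  nc_log("regress_nuisance", n_regressors = ncol(X), frames = nt)
  out
}

#' Temporal band-pass filter
#'
#' Zero-phase band-pass via the discrete Fourier transform with even
#' (reflection) extension of each series: frequencies inside
#' `[low, high]` Hz are preserved, everything else (including the DC
#' component) is removed.
#'
#' @param bold a [bold_series].
#' @param low,high band edges in Hz (defaults 0.01 and 0.08).
#' @return The filtered [bold_series].
#' @export
bandpass <- function(bold, low = 0.01, high = 0.08) {
  nt <- n_frames(bold)
  nyq <- 1 / (2 * bold$tr_s)
  if (!(low >= 0 && low < high && high < nyq))
    stop_nc(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz",
                    low, high, nyq), "nc_validation_error")
  Y <- t(matrix(bold$data, ncol = nt))     # time x voxels
  Ye <- rbind(Y, Y[nt:1, , drop = FALSE])  # even extension: continuous ends
  N <- 2L * nt
  f <- (seq_len(N) - 1) / (N * bold$tr_s)
  keep <- (f >= low & f <= high) | (f >= 1 / bold$tr_s - high &
                                    f <= 1 / bold$tr_s - low)
  Fy <- stats::mvfft(Ye)
  Fy[!keep, ] <- 0
  Yf <- Re(stats::mvfft(Fy, inverse = TRUE)) / N
  out <- bold_series(array(t(Yf[seq_len(nt), , drop = FALSE]), dim(bold$data)),
                     bold$tr_s, bold$motion_params, bold$voxel_size_mm)
  nc_log("bandpass", low = low, high = high, frames = nt)
  out
}

#' Framewise displacement
#'
#' Power-style summary of frame-to-frame head motion:
#' `FD_t = sum(|d translations|) + 50 * sum(|d rotations in rad|)`, rotations
#' converted from degrees and projected onto a 50 mm sphere; `FD_1 = 0`.
#'
#' @param motion_params frames x 6 matrix (3 translations mm, 3 rotations
#'   degrees).
#' @param head_radius_mm sphere radius for the rotation term.
#' @return Numeric vector of per-frame FD values (mm).
#' @export
framewise_displacement <- function(motion_params, head_radius_mm = 50) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6L)
    stop_nc("motion parameters must have 6 columns", "nc_validation_error")
  if (nrow(mp) < 2L)
    stop_nc("need at least 2 frames", "nc_validation_error")
  d <- apply(mp, 2, function(x) c(0, diff(x)))
  rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE] * pi / 180))
}

#' Motion exclusion check
#'
#' A subject passes if no translation exceeds 3 mm in absolute value on any
#' axis and no rotation exceeds 3 degrees on any axis ("no more than" - the
#' boundary values themselves pass).
#'
#' @param motion_params frames x 6 matrix (translations mm, rotations deg).
#' @param max_translation_mm,max_rotation_deg thresholds (default 3).
#' @return list with `pass`, `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_exclusion <- function(motion_params, max_translation_mm = 3,
                             max_rotation_deg = 3) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6L)
    stop_nc("motion parameters must have 6 columns", "nc_validation_error")
  wt <- max(abs(mp[, 1:3]))
  wr <- max(abs(mp[, 4:6]))
  list(pass = wt <= max_translation_mm && wr <= max_rotation_deg,
       max_translation_mm = wt, max_rotation_deg = wr)
}

#' Full temporal preprocessing pipeline
#'
#' Fixed order: [discard_initial()], [regress_nuisance()], [bandpass()].
#'
#' @param bold a [bold_series].
#' @param nuisance a [nuisance_set] covering the *original* frames (it is
#'   trimmed alongside the discard).
#' @param n_discard initial frames to drop.
#' @param low,high band edges in Hz.
#' @return The preprocessed [bold_series].
#' @export
preprocess_bold <- function(bold, nuisance, n_discard = 10,
                            low = 0.01, high = 0.08) {
  nt <- n_frames(bold)
  b <- discard_initial(bold, n_discard)
  nuis <- trim_nuisance(nuisance, (n_discard + 1):nt)
  b <- regress_nuisance(b, nuis)
  bandpass(b, low, high)
}
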