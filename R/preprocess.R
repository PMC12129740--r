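#' Framewise displacement from a motion trace
#'
#' Per-volume head-motion summary: the sum over the six rigid-body parameters
#' of the absolute frame-to-frame change, with the three rotations converted
#' from degrees to arc length on a sphere (radians times radius, default
#' 50 mm).  The first frame has no predecessor and gets FD = 0.
#'
#' @param motion t x 6 numeric matrix: translations (mm) then rotations
#'   (degrees).
#' @param sphere_radius_mm radius used for the rotation arc length.
#' @return List with `fd_series` (length t, first entry 0) and `mean_fd`.
#' @examples
#' m <- matrix(0, 10, 6); m[5, 1] <- 1
#' framewise_displacement(m)$fd_series[5]   # 1 mm step
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) == 0L) stop("motion trace is empty")
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (!all(is.finite(motion))) stop("motion parameters must be finite")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * pi / 180 * sphere_radius_mm
  fd <- c(0, rowSums(d))
  list(fd_series = fd, mean_fd = mean(fd))
}

#' Motion-based run exclusion
#'
#' A run is excluded when its maximum absolute translation exceeds
#' `max_translation_mm` (3 mm) on any axis, or when the mean absolute Euler
#' rotation angle exceeds `max_mean_abs_rotation_deg` (1.5 degrees).  The mean
#' absolute angle is computed per rotation axis (mean over time of the
#' absolute angle) and the largest axis is compared to the threshold.
#'
#' @inheritParams framewise_displacement
#' @param max_translation_mm translation limit, mm.
#' @param max_mean_abs_rotation_deg rotation limit, degrees.
#' @return List: `decision` ("retain" or "exclude") and `reasons`
#'   (character vector among "translation", "rotation").
#' @export
motion_qc <- function(motion, max_translation_mm = 3,
                      max_mean_abs_rotation_deg = 1.5) {
  motion <- as.matrix(motion)
  if (nrow(motion) == 0L) stop("motion trace is empty")
  if (!all(is.finite(motion))) stop("motion parameters must be finite")
  max_trans <- max(abs(motion[, 1:3]))
  mean_rot <- max(colMeans(abs(motion[, 4:6, drop = FALSE])))
  reasons <- character()
  if (max_trans > max_translation_mm) reasons <- c(reasons, "translation")
  if (mean_rot > max_mean_abs_rotation_deg) reasons <- c(reasons, "rotation")
  list(decision = if (length(reasons)) "exclude" else "retain",
       reasons = reasons,
       max_translation_mm = max_trans,
       mean_abs_rotation_deg = mean_rot)
}

# Shared core: linear detrend then frequency-domain band mask on a t x k
# matrix of series (columns are series).
bandpass_matrix <- function(x, tr_s, low_hz, high_hz) {
  nt <- nrow(x)
  nyq <- 1 / (2 * tr_s)
  if (low_hz < 0 || low_hz >= high_hz)
    stop("require 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g Hz) must be below the Nyquist frequency %g Hz",
                 high_hz, nyq))
  tt <- seq_len(nt)
  X <- cbind(1, tt - mean(tt))
  x <- x - X %*% qr.coef(qr(X), x)                    # linear detrend
  freqs <- (seq_len(nt) - 1) / (nt * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)              # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  sp <- stats::mvfft(x)
  sp[!keep, ] <- 0
  Re(stats::mvfft(sp, inverse = TRUE)) / nt
}

#' Bandpass filter a BOLD run
#'
#' Voxelwise linear detrend followed by frequency-domain masking retaining
#' \[`low_hz`, `high_hz`\] (default 0.01--0.08 Hz).  The detrend removes the
#' mean and any linear drift, so output voxel means are ~0.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz pass band edges, Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2 tr_s)`.
#' @return A filtered [bold_run()].
#' @export
bandpass <- function(run, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  x <- t(matrix(run$data, nrow = prod(d[1:3])))        # time x voxels
  y <- bandpass_matrix(x, run$tr_s, low_hz, high_hz)
  out <- array(t(y), dim = d)
  bold_run(out, run$grid, run$tr_s, run$subject_id, run$visit_index,
           run$sequence_variant)
}

#' Assemble the nuisance confound set for a run
#'
#' Mean time courses in white matter and CSF (voxels with tissue probability
#' >= `tissue_threshold`), the global mean over the brain mask, their first
#' differences (leading 0), and the six motion parameters, in that column
#' order.  Also computes the framewise-displacement series and its mean.
#'
#' @param run a [bold_run()].
#' @param seg segmentation set: list with probability volumes `wm`, `csf` and
#'   binary `brain_mask` on the run's grid.
#' @param motion t x 6 motion matrix.
#' @param tissue_threshold probability cut for the WM/CSF means (default 0.9,
#'   chosen to avoid partial-volume contamination).
#' @return List of class `confound_set`: `columns` (t x 12 matrix), `fd_series`,
#'   `mean_fd`.
#' @export
extract_confounds <- function(run, seg, motion, tissue_threshold = 0.9) {
  stopifnot(inherits(run, "bold_run"))
  check_same_grid(run$data, seg$wm, "run vs WM segmentation")
  check_same_grid(run$data, seg$csf, "run vs CSF segmentation")
  motion <- as.matrix(motion)
  nt <- dim(run$data)[4]
  if (nrow(motion) != nt) stop("motion length does not match volume count")
  mat <- matrix(run$data, ncol = nt)                   # voxels x time
  mean_over <- function(sel, what) {
    if (!any(sel)) stop(sprintf(
      "no %s voxels at tissue probability >= %g; lower tissue_threshold",
      what, tissue_threshold))
    colMeans(mat[sel, , drop = FALSE])
  }
  wm_mean <- mean_over(as.logical(seg$wm >= tissue_threshold), "white-matter")
  csf_mean <- mean_over(as.logical(seg$csf >= tissue_threshold), "CSF")
  global_mean <- mean_over(as.logical(seg$brain_mask > 0), "brain-mask")
  d1 <- function(x) c(0, diff(x))
  cols <- cbind(wm_mean = wm_mean, csf_mean = csf_mean,
                global_mean = global_mean,
                d_wm = d1(wm_mean), d_csf = d1(csf_mean),
                d_global = d1(global_mean), motion)
  colnames(cols)[7:12] <- paste0("motion_", 1:6)
  fd <- framewise_displacement(motion)
  structure(list(columns = cols, fd_series = fd$fd_series,
                 mean_fd = fd$mean_fd), class = "confound_set")
}

#' Bandpass-filter confound columns
#'
#' Applies the identical detrend + frequency mask used by [bandpass()] to
#' every confound column, so that regressing filtered confounds out of a
#' filtered run cannot reintroduce out-of-band power.
#'
#' @param confounds a `confound_set`.
#' @param tr_s repetition time of the run the confounds belong to.
#' @inheritParams bandpass
#' @return The `confound_set` with filtered columns.
#' @export
filter_confounds <- function(confounds, tr_s, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(confounds, "confound_set"))
  confounds$columns <- bandpass_matrix(confounds$columns, tr_s, low_hz, high_hz)
  confounds
}

#' Voxelwise nuisance regression
#'
#' Ordinary least-squares residualization of every voxel time series on an
#' intercept plus the confound columns.  Exactly collinear (or constant-zero)
#' columns are dropped with a warning, keeping the first occurrence; a design
#' that is still rank deficient afterwards is an error.
#'
#' @param run a [bold_run()].
#' @param confounds a `confound_set` with columns of length t.
#' @return A [bold_run()] of residuals; attribute `dropped_columns` lists any
#'   pruned confounds.
#' @export
nuisance_regression <- function(run, confounds) {
  stopifnot(inherits(run, "bold_run"), inherits(confounds, "confound_set"))
  nt <- dim(run$data)[4]
  C <- confounds$columns
  if (nrow(C) != nt) stop("confound columns do not match run length")
  X <- cbind(intercept = 1, C)
  qrX <- qr(X)
  dropped <- character()
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-sort(keep)]
    warning("dropping exactly collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("design still rank deficient after pruning")
  }
  Y <- t(matrix(run$data, ncol = nt))                  # time x voxels
  res <- qr.resid(qrX, Y)
  out <- bold_run(array(t(res), dim = dim(run$data)), run$grid, run$tr_s,
                  run$subject_id, run$visit_index, run$sequence_variant)
  attr(out, "dropped_columns") <- dropped
  out
}
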