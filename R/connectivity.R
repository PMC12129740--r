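#' Construct a connectivity map object
#'
#' @param data 3D array of voxelwise statistics (NA marks voxels outside the
#'   analysis mask).
#' @param grid the [volume_grid()] of the source run.
#' @param seed_label `"PRC"` or `"PHC"`.
#' @param scale `"pearson_r"` or `"fisher_z"`.
#' @param smoothed_fwhm_mm FWHM of any smoothing applied, or `NULL` for
#'   unsmoothed maps.
#' @param subject_id,visit_index identifiers.
#' @return Object of class `conn_map`.
#' @export
conn_map <- function(data, grid, seed_label, scale = "pearson_r",
                     smoothed_fwhm_mm = NULL, subject_id = "S0001",
                     visit_index = 1L) {
  seed_label <- match.arg(seed_label, c("PRC", "PHC"))
  scale <- match.arg(scale, c("pearson_r", "fisher_z"))
  stopifnot(identical(dim(data), as.integer(grid$shape)))
  if (scale == "pearson_r" &&
      any(abs(data) > 1 + 1e-12, na.rm = TRUE))
    stop("pearson_r values must lie in [-1, 1]")
  attr(data, "grid") <- grid
  structure(list(data = data, grid = grid, seed_label = seed_label,
                 scale = scale, smoothed_fwhm_mm = smoothed_fwhm_mm,
                 subject_id = subject_id, visit_index = visit_index),
            class = "conn_map")
}

#' @method print conn_map
#' @export
print.conn_map <- function(x, ...) {
  cat(sprintf("<conn_map %s seed, %s%s, %s>\n", x$seed_label, x$scale,
              if (is.null(x$smoothed_fwhm_mm)) ", unsmoothed"
              else sprintf(", smoothed %g mm", x$smoothed_fwhm_mm),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Signal-dropout analysis mask
#'
#' Grey-matter mask built from the T1-derived and the non-EPI T2*-derived
#' grey-matter probability maps: each is thresholded at `threshold`
#' (inclusive) and the two are combined.  The default combination is the
#' intersection, because the mask exists to exclude voxels with signal loss:
#' a voxel must look like grey matter on both modalities to be retained.
#'
#' @param gm_t1,gm_t2star probability volumes on one grid.
#' @param threshold probability cut in (0, 1); `>=` is inclusive.
#' @param combine `"intersection"` (default) or `"union"`.
#' @return Binary volume (grid attribute preserved).
#' @export
dropout_mask <- function(gm_t1, gm_t2star, threshold = 0.25,
                         combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  grid <- check_same_grid(gm_t1, gm_t2star, "grey-matter probability maps")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  a <- gm_t1 >= threshold
  b <- gm_t2star >= threshold
  m <- if (combine == "intersection") a & b else a | b
  if (!any(m)) warning("dropout mask is empty at threshold ", threshold)
  out <- array(as.numeric(m), dim = grid$shape)
  attr(out, "grid") <- grid
  out
}

#' Seed-to-voxel correlation map
#'
#' Correlates the mean time course over the seed voxels with every voxel
#' inside the analysis mask.  Voxels outside the mask are set to `NA`;
#' zero-variance voxels get r = 0 (their count is reported via a message).
#'
#' @param run a residualized [bold_run()].
#' @param seed_vox binary seed volume on the run's grid.
#' @param analysis_mask binary volume of voxels to evaluate.
#' @param seed_label `"PRC"` or `"PHC"`.
#' @return A `conn_map` on the `pearson_r` scale.
#' @export
seed_correlation_map <- function(run, seed_vox, analysis_mask,
                                 seed_label = "PRC") {
  stopifnot(inherits(run, "bold_run"))
  check_same_grid(run$data, seed_vox, "run vs seed")
  check_same_grid(run$data, analysis_mask, "run vs analysis mask")
  nt <- dim(run$data)[4]
  if (nt < 3L) stop("need at least 3 time points")
  sel <- as.logical(seed_vox > 0)
  if (!any(sel)) stop("seed is empty within the analysis grid")
  mat <- matrix(run$data, ncol = nt)                  # voxels x time
  seed_series <- colMeans(mat[sel, , drop = FALSE])
  if (stats::sd(seed_series) == 0) stop("seed mean series has zero variance")
  msel <- as.logical(analysis_mask > 0)
  Y <- t(mat[msel, , drop = FALSE])                   # time x voxels
  s <- seed_series - mean(seed_series)
  Yc <- sweep(Y, 2, colMeans(Y))
  den <- sqrt(sum(s^2) * colSums(Yc^2))
  r <- as.vector(crossprod(Yc, s))
  zero_var <- den == 0
  r[!zero_var] <- r[!zero_var] / den[!zero_var]
  r[zero_var] <- 0
  if (any(zero_var))
    message(sum(zero_var), " zero-variance voxel(s) set to r = 0")
  r <- pmin(pmax(r, -1), 1)
  out <- array(NA_real_, run$grid$shape)
  out[msel] <- r
  conn_map(out, run$grid, seed_label, "pearson_r", NULL,
           run$subject_id, run$visit_index)
}

#' Fisher z-transformation of a correlation map
#'
#' z = atanh(r), with r clipped to +/- `clip` first so the transform stays
#' finite; `NA` (out-of-mask) voxels propagate.
#'
#' @param map a `conn_map` on the `pearson_r` scale.
#' @param clip magnitude at which r is clamped before atanh.
#' @return A `conn_map` on the `fisher_z` scale.
#' @export
fisher_z <- function(map, clip = 0.999999) {
  stopifnot(inherits(map, "conn_map"))
  if (map$scale != "pearson_r") stop("fisher_z expects a pearson_r map")
  z <- atanh(pmin(pmax(map$data, -clip), clip))
  conn_map(array(z, dim = map$grid$shape), map$grid, map$seed_label,
           "fisher_z", map$smoothed_fwhm_mm, map$subject_id, map$visit_index)
}

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  radius <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-radius):radius)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D reflective-boundary convolution along the first array dimension
conv_axis1 <- function(arr, kern) {
  d <- dim(arr)
  n <- d[1]
  radius <- (length(kern) - 1L) / 2L
  # half-sample symmetric reflection, valid for kernels wider than the axis
  reflect <- function(i) {
    m <- (i - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  idx <- reflect((1L - radius):(n + radius))
  m <- matrix(arr, nrow = n)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern))
    out <- out + kern[j] * mp[j:(j + n - 1), , drop = FALSE]
  array(out, dim = d)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Kernel standard deviation is `fwhm_mm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxel units by that axis's voxel size; the kernel is
#' truncated at 4 sigma and renormalized.  Boundaries are reflective, which
#' conserves the image sum.  Constant images pass through unchanged.
#'
#' For `conn_map` input, out-of-mask `NA` voxels are handled by normalized
#' convolution (smoothing the finite values and renormalizing by the smoothed
#' in-mask indicator) and the result records `smoothed_fwhm_mm`.
#'
#' @param x a 3D array with a `grid` attribute, or a `conn_map`.
#' @param fwhm_mm full width at half maximum of the kernel, mm (> 0).
#' @param grid required when `x` is a bare array without a grid attribute.
#' @return Same type as the input, smoothed.
#' @export
gaussian_smooth <- function(x, fwhm_mm, grid = NULL) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  if (inherits(x, "conn_map")) {
    dat <- x$data
    ok <- is.finite(dat)
    filled <- ifelse(ok, dat, 0)
    sm <- gaussian_smooth(structure(filled, grid = x$grid), fwhm_mm)
    wt <- gaussian_smooth(structure(array(as.numeric(ok), dim(dat)),
                                    grid = x$grid), fwhm_mm)
    out <- array(NA_real_, dim(dat))
    out[ok] <- sm[ok] / wt[ok]
    if (x$scale == "pearson_r") out <- pmin(pmax(out, -1), 1)
    return(conn_map(out, x$grid, x$seed_label, x$scale, fwhm_mm,
                    x$subject_id, x$visit_index))
  }
  g <- if (!is.null(grid)) grid else attr(x, "grid")
  if (is.null(g)) stop("supply a grid for bare arrays")
  out <- unclass(x)
  for (ax in 1:3) {
    kern <- gaussian_kernel_1d(fwhm_mm, g$voxel_size_mm[ax])
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    back <- order(perm)
    out <- aperm(conv_axis1(aperm(out, perm), kern), back)
  }
  attr(out, "grid") <- g
  out
}
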