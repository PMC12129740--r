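#' Positive-voxel network connectivity index
#'
#' Mean of the strictly positive Fisher-z values inside the mask.  This is
#' the scalar proxy for a participant's global network connectivity: negative
#' values are excluded as non-meaningful noise, and extraction is only valid
#' on unsmoothed maps (a smoothed input is a contract error, not a warning).
#'
#' @param map an unsmoothed `conn_map` on the `fisher_z` scale.
#' @param mask binary volume (typically a [participant_mask()]).
#' @return Mean of positive in-mask values, or `NA` (with a message) when no
#'   positive voxels exist.
#' @export
positive_mean <- function(map, mask) {
  stopifnot(inherits(map, "conn_map"))
  if (!is.null(map$smoothed_fwhm_mm))
    stop("positive_mean requires an unsmoothed map (got ",
         map$smoothed_fwhm_mm, " mm smoothing)")
  check_same_grid(map$data, mask, "map vs mask")
  v <- map$data[mask > 0]
  v <- v[is.finite(v) & v > 0]
  if (length(v) == 0L) {
    message("no positive in-mask voxels; index is missing")
    return(NA_real_)
  }
  mean(v)
}

#' Plain masked mean of an image
#'
#' Signed mean over the mask; used for PET-like images where negative values
#' are meaningful.
#'
#' @param image 3D volume.
#' @param mask non-empty binary volume on the same grid.
#' @return Scalar mean.
#' @export
masked_mean <- function(image, mask) {
  check_same_grid(image, mask, "image vs mask")
  if (!any(mask > 0)) stop("mask is empty")
  mean(image[mask > 0])
}

#' Amyloid positivity threshold from a young-adult SUVR distribution
#'
#' The 99.9th percentile (linear interpolation between closest ranks,
#' `quantile` type 7) of the supplied young-adult SUVR values.
#'
#' @param young_suvrs numeric vector (>= 2 values).
#' @param percentile percentile in (0, 100\].
#' @return Scalar threshold.
#' @export
abeta_threshold <- function(young_suvrs, percentile = 99.9) {
  young_suvrs <- young_suvrs[!is.na(young_suvrs)]
  if (length(young_suvrs) < 2L) stop("need at least 2 SUVR values")
  unname(quantile(young_suvrs, percentile / 100, type = 7))
}

#' Baseline amyloid status from per-visit SUVRs
#'
#' Positive/negative classification at baseline: if a baseline scan exists
#' (months == 0), status is positive iff its SUVR >= threshold.  Without a
#' baseline scan, the participant is negative when every later SUVR is below
#' threshold; a supra-threshold later scan with no baseline is undetermined
#' (the later positivity cannot be dated back to baseline).
#'
#' @param suvr per-visit SUVR values (NA = no scan at that visit).
#' @param months visit times in months from baseline.
#' @param threshold positivity threshold (see [abeta_threshold()]).
#' @return `"positive"`, `"negative"` or `"undetermined"`.
#' @export
abeta_status <- function(suvr, months, threshold) {
  stopifnot(length(suvr) == length(months), length(suvr) >= 1L)
  ok <- !is.na(suvr)
  if (!any(ok)) return("undetermined")
  base <- ok & months == 0
  if (any(base)) {
    return(if (suvr[which(base)[1]] >= threshold) "positive" else "negative")
  }
  if (all(suvr[ok] < threshold)) "negative" else "undetermined"
}

#' Head-size normalization of a regional volume
#'
#' `raw_mm3 / (tiv_mm3 * 1000)`; both inputs must be positive.
#'
#' @param raw_mm3 regional volume, mm^3 (anterior + posterior parts already
#'   summed upstream).
#' @param tiv_mm3 total intracranial volume, mm^3.
#' @return Dimensionless normalized volume.
#' @export
normalize_volume <- function(raw_mm3, tiv_mm3) {
  if (any(raw_mm3 <= 0) || any(tiv_mm3 <= 0))
    stop("raw volume and TIV must be > 0")
  raw_mm3 / (tiv_mm3 * 1000)
}
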