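#' Threshold-free cluster enhancement
#'
#' Integrates cluster support across all thresholds:
#' \deqn{TFCE(v) = \sum_{h = dh, 2dh, \dots}^{\max} e(h, v)^E \, h^H \, dh}
#' where `e(h, v)` is the size of the connected component containing `v`
#' among voxels with value >= h.  Negative and zero voxels score 0, and a
#' map with no positive values returns all zeros.
#'
#' @param stat_map finite 3D array (e.g. a t-map).
#' @param E,H extent and height exponents (0.5 and 2, the cited tool's
#'   defaults; not stated in the source procedure).
#' @param dh threshold step; `NULL` uses `max(stat_map)/100` (100 steps).
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @return 3D array of TFCE scores.
#' @export
tfce <- function(stat_map, E = 0.5, H = 2.0, dh = NULL,
                 connectivity = c(26, 18, 6)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]),
                                       c("26", "18", "6")))
  d <- dim(stat_map)
  if (length(d) != 3L) stop("stat_map must be 3D")
  out <- .tfce_cpp(as.numeric(stat_map), as.integer(d), E, H,
                   if (is.null(dh)) -1 else dh, connectivity)
  attr(out, "grid") <- attr(stat_map, "grid")
  out
}

sign_matrix <- function(n, n_perm, seed) {
  if (2^n <= 4096 && n_perm >= 2^n) {
    # exhaustive enumeration of all sign patterns (identity included)
    s <- matrix(1, 2^n, n)
    for (j in seq_len(n))
      s[bitwAnd(0:(2^n - 1), bitwShiftL(1L, j - 1L)) > 0, j] <- -1
    list(signs = s, exhaustive = TRUE)
  } else {
    s <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                n_perm, n))
    list(signs = s, exhaustive = FALSE)
  }
}

perm_t_stats <- function(X, signs) {
  # X: n x V; one-sample t per voxel for every row of sign flips.
  # Sum of squares is invariant under sign flipping, so all permutation
  # t-maps come from a single matrix product.
  n <- nrow(X)
  ssq <- colSums(X^2)
  M <- (signs %*% X) / n                      # perms x V of means
  V <- (rep(1, nrow(signs)) %o% ssq - n * M^2) / (n - 1)
  V[V < 0] <- 0
  SD <- sqrt(V / n)
  SD[SD < 1e-10] <- 1e-10                     # degenerate zero-variance voxels
  M / SD
}

#' One-sample sign-flip permutation t-test with TFCE and FWE correction
#'
#' Computes the voxelwise one-sample t statistic over subjects, enhances it
#' with [tfce()], and builds the max-statistic null distribution by randomly
#' flipping the sign of each subject's map.  When `2^n <= 4096` and `n_perm`
#' covers it, all sign patterns are enumerated exhaustively (p-values are
#' then multiples of `1/2^n`); otherwise `n_perm` random flips are drawn and
#' p-values use the +1-smoothed estimator `(1 + #{null >= obs})/(n_perm + 1)`.
#' The test is one-sided (greater), matching the mask-building procedure's
#' search for positively connected voxels.
#'
#' @param maps list of 3D subject maps (or `conn_map`s) on one grid.
#' @param analysis_mask binary volume restricting the test.
#' @param n_perm requested number of permutations.
#' @param alpha FWE level for the significance mask.
#' @param seed integer RNG seed for the sign flips.
#' @param E,H,connectivity,dh TFCE settings, see [tfce()].
#' @return Object of class `perm_result`: `t_map`, `tfce_map`, `p_fwe_map`,
#'   `sig_mask`, `null_max`, `n_perm_used`, `alpha`, `side`.
#' @export
one_sample_perm_test <- function(maps, analysis_mask, n_perm = 1000,
                                 alpha = 0.05, seed = 1L, E = 0.5, H = 2.0,
                                 connectivity = 26, dh = NULL) {
  arrs <- lapply(maps, function(m) if (inherits(m, "conn_map")) m$data else m)
  n <- length(arrs)
  if (n < 5L) stop("need at least 5 subject maps")
  if (n_perm < 100) warning("fewer than 100 permutations gives coarse p-values")
  grid <- attr(analysis_mask, "grid")
  shp <- dim(arrs[[1]])
  for (m in arrs) if (!identical(dim(m), shp)) stop("maps are not on one grid")
  if (!identical(dim(analysis_mask), shp)) stop("mask is not on the maps' grid")
  msel <- as.logical(analysis_mask > 0)
  X <- do.call(rbind, lapply(arrs, function(m) {
    v <- m[msel]
    v[!is.finite(v)] <- 0
    v
  }))
  sm <- sign_matrix(n, n_perm, seed)
  n_used <- nrow(sm$signs)

  to_vol <- function(v) { a <- array(0, shp); a[msel] <- v; a }
  t_obs <- perm_t_stats(X, matrix(1, 1, n))[1, ]
  tfce_obs <- tfce(to_vol(t_obs), E, H, dh, connectivity)

  Tperm <- perm_t_stats(X, sm$signs)
  null_max <- vapply(seq_len(n_used), function(i) {
    max(tfce(to_vol(Tperm[i, ]), E, H, dh, connectivity))
  }, numeric(1))

  obs_in <- tfce_obs[msel]
  # #{null_max >= o} via a sorted null (findInterval counts null_max < o)
  exceed <- n_used - findInterval(obs_in, sort(null_max), left.open = TRUE)
  p_in <- if (sm$exhaustive) pmax(exceed, 1) / n_used
          else (1 + exceed) / (n_used + 1)
  p_map <- array(1, shp)
  p_map[msel] <- p_in
  sig <- array(0, shp)
  sig[msel] <- as.numeric(p_in < alpha)
  attr(p_map, "grid") <- grid
  attr(sig, "grid") <- grid
  structure(list(t_map = to_vol(t_obs), tfce_map = tfce_obs,
                 p_fwe_map = p_map, sig_mask = sig, null_max = null_max,
                 n_perm_used = n_used, alpha = alpha, side = "greater",
                 exhaustive = sm$exhaustive, grid = grid),
            class = "perm_result")
}

#' Paired sign-flip permutation t-test
#'
#' Tests `a > b` by applying the one-sample machinery to the per-subject
#' difference maps `a - b`.
#'
#' @param maps_a,maps_b paired lists of subject maps (same subjects, same
#'   order).
#' @inheritParams one_sample_perm_test
#' @return A `perm_result` for the contrast `a > b`.
#' @export
paired_perm_test <- function(maps_a, maps_b, analysis_mask, n_perm = 1000,
                             alpha = 0.05, seed = 1L, E = 0.5, H = 2.0,
                             connectivity = 26, dh = NULL) {
  if (length(maps_a) != length(maps_b))
    stop("paired map lists have different lengths")
  g <- function(m) if (inherits(m, "conn_map")) m$data else m
  diffs <- Map(function(a, b) g(a) - g(b), maps_a, maps_b)
  one_sample_perm_test(diffs, analysis_mask, n_perm, alpha, seed, E, H,
                       connectivity, dh)
}

#' Combine permutation results into AT and PM network masks
#'
#' The anterior-temporal mask keeps voxels significant in both the perirhinal
#' one-sample test and the perirhinal-greater-than-parahippocampal paired
#' test; the posterior-medial mask is the overlap of the parahippocampal
#' one-sample and parahippocampal-greater-than-perirhinal paired results.
#' Because the two paired contrasts are opposite one-sided tests, the default
#' intersection rule makes AT and PM disjoint by construction.  `combine =
#' "union"` is exposed for the AT rule since the source wording ("combining")
#' is ambiguous there; intersection is the default by symmetry with PM.
#'
#' @param prc_onesample,phc_onesample,prc_gt_phc,phc_gt_prc `perm_result`s on
#'   one grid.
#' @param combine_at `"intersection"` (default) or `"union"` for the AT rule.
#' @return Object of class `group_mask_set`: binary `at_mask`, `pm_mask`, and
#'   `provenance`.
#' @export
build_network_masks <- function(prc_onesample, phc_onesample, prc_gt_phc,
                                phc_gt_prc,
                                combine_at = c("intersection", "union")) {
  combine_at <- match.arg(combine_at)
  res <- list(prc_onesample, phc_onesample, prc_gt_phc, phc_gt_prc)
  shp <- dim(res[[1]]$sig_mask)
  for (r in res) if (!identical(dim(r$sig_mask), shp))
    stop("permutation results are not on one grid")
  at <- if (combine_at == "intersection")
    prc_onesample$sig_mask * prc_gt_phc$sig_mask
  else pmin(prc_onesample$sig_mask + prc_gt_phc$sig_mask, 1)
  pm <- phc_onesample$sig_mask * phc_gt_prc$sig_mask
  if (sum(at) == 0) warning("AT mask is empty (one-sample voxels: ",
                            sum(prc_onesample$sig_mask), ", paired voxels: ",
                            sum(prc_gt_phc$sig_mask), ")")
  if (sum(pm) == 0) warning("PM mask is empty (one-sample voxels: ",
                            sum(phc_onesample$sig_mask), ", paired voxels: ",
                            sum(phc_gt_prc$sig_mask), ")")
  grid <- res[[1]]$grid
  attr(at, "grid") <- grid
  attr(pm, "grid") <- grid
  structure(list(at_mask = at, pm_mask = pm,
                 provenance = list(combine_at = combine_at,
                                   n_perm = vapply(res, `[[`, 0, "n_perm_used"),
                                   alpha = vapply(res, `[[`, 0, "alpha"))),
            class = "group_mask_set")
}

#' Participant-specific network mask
#'
#' Group mask restricted to the participant's grey matter (probability >=
#' `gm_threshold`) with all seed voxels removed to prevent autocorrelation
#' with the seed's own series.
#'
#' @param group_mask binary network mask.
#' @param gm_prob participant grey-matter probability volume.
#' @param gm_threshold probability cut (default 0.5).
#' @param seeds list of binary seed volumes to remove.
#' @return Binary volume; empty results trigger a warning.
#' @export
participant_mask <- function(group_mask, gm_prob, gm_threshold = 0.5,
                             seeds = list()) {
  grid <- check_same_grid(group_mask, gm_prob, "group mask vs grey matter")
  m <- (group_mask > 0) & (gm_prob >= gm_threshold)
  for (s in seeds) {
    check_same_grid(group_mask, s, "group mask vs seed")
    m <- m & !(s > 0)
  }
  if (!any(m)) warning("participant mask is empty; extraction will be missing")
  out <- array(as.numeric(m), dim = grid$shape)
  attr(out, "grid") <- grid
  out
}

#' Split a network mask by a parcellation
#'
#' Intersects the mask with every positive label and keeps regions of
#' interest with at least `min_voxels` voxels (inclusive), ordered by label
#' id.
#'
#' @param network_mask binary volume.
#' @param labels integer label volume (0 = background).
#' @param min_voxels minimum ROI size, default 100.
#' @return Named list (`roi_<id>`) of binary ROI masks.
#' @export
split_by_parcellation <- function(network_mask, labels, min_voxels = 100) {
  grid <- check_same_grid(network_mask, labels, "mask vs parcellation")
  ids <- sort(unique(labels[labels > 0 & network_mask > 0]))
  out <- list()
  for (id in ids) {
    m <- (labels == id) & (network_mask > 0)
    if (sum(m) >= min_voxels) {
      v <- array(as.numeric(m), dim = grid$shape)
      attr(v, "grid") <- grid
      out[[paste0("roi_", id)]] <- v
    }
  }
  out
}

#' Dice overlap coefficient between two binary volumes
#'
#' `2|a n b| / (|a| + |b|)`.  Two empty masks are defined as Dice 1 with a
#' warning.
#'
#' @param a,b binary volumes on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, "dice inputs")
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a > 0 & b > 0) / (na + nb)
}
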