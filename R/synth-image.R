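#' Deterministic ROI layout for synthetic runs
#'
#' Places four disjoint cuboid regions on the grid: a perirhinal (PRC) seed,
#' a parahippocampal (PHC) seed, an anterior-temporal (AT) network and a
#' posterior-medial (PM) network, plus one CSF slab (bottom slice) and one
#' white-matter slab (top slice) used for nuisance structure.  Layout is a
#' pure function of the grid, so every module sees the same geometry.
#'
#' @param grid a [volume_grid()]; must be at least 12 x 12 x 6 voxels.
#' @return List of logical 3D arrays: `seed_prc`, `seed_phc`, `at`, `pm`,
#'   `csf`, `wm`, plus `labels`, an integer parcellation volume subdividing
#'   each network into two label ids (AT: 1, 2; PM: 3, 4).
#' @export
roi_layout <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  n <- grid$shape
  if (any(n < c(12L, 12L, 6L)))
    stop("grid too small to hold the four disjoint ROIs (need >= 12x12x6)")
  rng <- function(a, b, len) max(1L, round(a * len)):min(len, round(b * len))
  cub <- function(xs, ys, zs) {
    m <- array(FALSE, n)
    m[xs, ys, zs] <- TRUE
    m
  }
  interior_z <- rng(0.3, 0.7, n[3])
  lay <- list(
    seed_prc = cub(rng(0.06, 0.24, n[1]), rng(0.06, 0.24, n[2]), interior_z),
    seed_phc = cub(rng(0.76, 0.94, n[1]), rng(0.06, 0.24, n[2]), interior_z),
    at       = cub(rng(0.06, 0.38, n[1]), rng(0.50, 0.82, n[2]), interior_z),
    pm       = cub(rng(0.62, 0.94, n[1]), rng(0.50, 0.82, n[2]), interior_z),
    csf      = cub(seq_len(n[1]), seq_len(n[2]), 1L),
    wm       = cub(seq_len(n[1]), seq_len(n[2]), n[3]))
  ov <- lay$seed_prc + lay$seed_phc + lay$at + lay$pm
  if (max(ov) > 1L) stop("grid too small: ROI layout overlaps")
  # parcellation: split each network into two labels at its median x slice
  labels <- array(0L, n)
  split_labels <- function(mask, lab_lo, lab_hi) {
    idx <- which(mask)
    xs <- arrayInd(idx, n)[, 1]
    labels[idx[xs <= stats::median(xs)]] <<- lab_lo
    labels[idx[xs > stats::median(xs)]] <<- lab_hi
  }
  split_labels(lay$at, 1L, 2L)
  split_labels(lay$pm, 3L, 4L)
  lay$labels <- labels
  for (nm in c("seed_prc", "seed_phc", "at", "pm", "csf", "wm"))
    attr(lay[[nm]], "grid") <- grid
  attr(lay$labels, "grid") <- grid
  lay
}

#' Construct a BOLD run object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param grid a [volume_grid()] matching `dim(data)[1:3]`.
#' @param tr_s repetition time in seconds.
#' @param subject_id,visit_index,sequence_variant identifiers.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, grid, tr_s, subject_id = "S0001", visit_index = 1L,
                     sequence_variant = 0L) {
  stopifnot(length(dim(data)) == 4L, tr_s > 0, dim(data)[4] >= 2L)
  if (!identical(dim(data)[1:3], grid$shape)) stop("data does not match grid shape")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  attr(data, "grid") <- grid
  structure(list(data = data, grid = grid, tr_s = tr_s, subject_id = subject_id,
                 visit_index = visit_index,
                 sequence_variant = as.integer(sequence_variant)),
            class = "bold_run")
}

#' @method print bold_run
#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run %s, %d volumes, TR %.3f s, subject %s visit %d>\n",
              paste(x$grid$shape, collapse = "x"), dim(x$data)[4], x$tr_s,
              x$subject_id, x$visit_index))
  invisible(x)
}

#' Generate a synthetic BOLD run with planted network structure
#'
#' Two latent time courses drive the planted networks: seed voxels carry the
#' latent course plus small idiosyncratic noise, and each network voxel mixes
#' the latent course with unit white noise so that the population correlation
#' between the seed-mean series and the network voxel equals the requested
#' loading.  On top of the signal model, configurable nuisance is added:
#' voxelwise linear drift, a global component over the brain, white-matter and
#' CSF components in their slabs, and a motion-coupled component.  Motion is a
#' slow random walk (translations mm, rotations degrees).
#'
#' @param subject_loadings named numeric, `c(at = , pm = )`, each in
#'   \[0, 0.999\]: target seed-to-network-voxel correlation.
#' @param grid a [volume_grid()].
#' @param n_volumes number of time points (>= 20).
#' @param tr_s repetition time, seconds.
#' @param seed integer RNG seed.
#' @param nuisance_scale multiplier on all nuisance components (0 gives the
#'   pure signal model under which the loading calibration is exact).
#' @param subject_id,visit_index,sequence_variant passed to [bold_run()].
#' @return List: `run` ([bold_run]), `motion` (t x 6 matrix), `seg`
#'   (probability volumes `gm_t1`, `gm_t2star`, `wm`, `csf`, `brain_mask`),
#'   `seeds` (binary `prc`, `phc` volumes), `labels` (parcellation volume),
#'   `layout` (the [roi_layout()]).
#' @export
generate_run <- function(subject_loadings = c(at = 0.6, pm = 0.6), grid,
                         n_volumes = 120L, tr_s = 2.382, seed = 1L,
                         nuisance_scale = 1, subject_id = "S0001",
                         visit_index = 1L, sequence_variant = 0L) {
  lam <- as.numeric(subject_loadings[c("at", "pm")])
  if (any(is.na(lam))) stop("subject_loadings must be named c(at=, pm=)")
  if (any(lam < 0 | lam >= 1)) stop("loadings must lie in [0, 1)")
  if (n_volumes < 20L) stop("n_volumes must be >= 20")
  lay <- roi_layout(grid)
  nt <- as.integer(n_volumes)
  nv <- prod(grid$shape)
  with_seed(seed, {
    u_at <- rnorm(nt); u_pm <- rnorm(nt)
    dat <- matrix(rnorm(nv * nt), nrow = nv)   # voxels x time, unit noise
    seed_noise_sd <- 0.1
    fill_net <- function(dat, seedvox, netvox, u, lambda) {
      k <- sum(seedvox)
      dat[seedvox, ] <- rep(u, each = k) + seed_noise_sd * dat[seedvox, ]
      # corr(seed mean, a*u + b*noise) = a / sqrt(1 + sd^2/k); solve for a
      a <- lambda * sqrt(1 + seed_noise_sd^2 / k)
      b <- sqrt(max(0, 1 - a^2))
      m <- sum(netvox)
      dat[netvox, ] <- a * rep(u, each = m) + b * dat[netvox, ]
      dat
    }
    dat <- fill_net(dat, lay$seed_prc, lay$at, u_at, lam[1])
    dat <- fill_net(dat, lay$seed_phc, lay$pm, u_pm, lam[2])

    trans <- apply(matrix(rnorm(nt * 3, 0, 0.02), nt), 2, cumsum)
    rot <- apply(matrix(rnorm(nt * 3, 0, 0.01), nt), 2, cumsum)
    motion <- cbind(trans, rot)
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    if (nuisance_scale > 0) {
      tt <- seq_len(nt) - (nt + 1) / 2
      drift <- runif(nv, -0.5, 0.5) * nuisance_scale
      g <- rnorm(nt) * 0.5 * nuisance_scale
      wmc <- rnorm(nt) * 0.7 * nuisance_scale
      csfc <- rnorm(nt) * 0.7 * nuisance_scale
      msig <- scale(motion[, 1] + motion[, 4])[, 1] * 0.3 * nuisance_scale
      dat <- dat + outer(drift, tt / nt) + rep(g + msig, each = nv)
      dat[lay$wm, ] <- dat[lay$wm, ] + rep(wmc, each = sum(lay$wm))
      dat[lay$csf, ] <- dat[lay$csf, ] + rep(csfc, each = sum(lay$csf))
    }
    arr <- array(dat, dim = c(grid$shape, nt))
    run <- bold_run(arr, grid, tr_s, subject_id, visit_index, sequence_variant)

    mk <- function(vals) { v <- array(vals, grid$shape); attr(v, "grid") <- grid; v }
    gm <- mk(0.9); gm[lay$csf] <- 0.02; gm[lay$wm] <- 0.02
    wm <- mk(0.05); wm[lay$wm] <- 0.95
    csf <- mk(0.05); csf[lay$csf] <- 0.95
    gm2 <- mk(0.85); gm2[lay$csf] <- 0.02; gm2[lay$wm] <- 0.02
    brain <- mk(1)
    seg <- list(gm_t1 = gm, gm_t2star = gm2, wm = wm, csf = csf,
                brain_mask = brain)
    seeds <- list(prc = mk(as.numeric(lay$seed_prc)),
                  phc = mk(as.numeric(lay$seed_phc)))
    list(run = run, motion = motion, seg = seg, seeds = seeds,
         labels = lay$labels, layout = lay)
  })
}

#' Write a motion trace as a 6-column TSV
#' @param motion t x 6 matrix (translations mm, rotations degrees).
#' @param path file path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
}
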