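# Independent brute-force oracles and small fixture builders used across the
# suite.  These deliberately share no code with the package implementations.

# Per-threshold connected-component TFCE: label components from scratch at
# every threshold with a BFS and accumulate extent^E * height^H * dh.
brute_tfce <- function(m, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  d <- dim(m)
  mx <- max(m)
  if (mx <= 0) return(array(0, d))
  if (is.null(dh)) dh <- mx / 100
  K <- floor(mx / dh + 1e-9)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(nbr))
  nbr <- nbr[ord > 0 & ord <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  lin <- function(ijk) (ijk[3] - 1) * d[1] * d[2] + (ijk[2] - 1) * d[1] + ijk[1]
  out <- array(0, d)
  for (k in seq_len(K)) {
    h <- dh * k
    act <- m >= h
    lab <- array(0L, d)
    cur <- 0L
    for (i0 in which(act)) {
      if (lab[i0] > 0L) next
      cur <- cur + 1L
      queue <- i0
      lab[i0] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        ijk <- arrayInd(v, d)[1, ]
        for (r in seq_len(nrow(nbr))) {
          nb <- ijk + nbr[r, ]
          if (all(nb >= 1) && all(nb <= d)) {
            li <- lin(nb)
            if (act[li] && lab[li] == 0L) { lab[li] <- cur; queue <- c(queue, li) }
          }
        }
      }
    }
    if (cur > 0L) {
      sz <- tabulate(lab[lab > 0L])
      sel <- lab > 0L
      out[sel] <- out[sel] + sz[lab[sel]]^E * h^H * dh
    }
  }
  out
}

# Hand-stepped Holm step-down: sort, walk down rejecting while
# p_(i) <= alpha / (m - i + 1); adjusted values by the running-max rule.
brute_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- run
  }
  list(adjusted = adj, reject = adj < alpha)
}

# Textbook Pearson correlation from explicit sums.
brute_cor <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Brute-force 3D Gaussian convolution (truncated at 4 sigma, reflective
# boundary) evaluated voxel by voxel.
brute_gauss3d <- function(vol, fwhm_mm, voxel_mm) {
  d <- dim(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  radius <- max(1L, ceiling(4 * sigma))
  w1 <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  reflect <- function(i, n) {
    m <- (i - 1) %% (2 * n)
    ifelse(m < n, m + 1, 2 * n - m)
  }
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (a in -radius:radius) for (b in -radius:radius) for (cc in -radius:radius) {
      acc <- acc + w1[a + radius + 1] * w1[b + radius + 1] * w1[cc + radius + 1] *
        vol[reflect(x + a, d[1]), reflect(y + b, d[2]), reflect(z + cc, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# Small-grid helpers
tiny_grid <- function(shape = c(5, 5, 5), vox = 3) volume_grid(shape, rep(vox, 3))

as_vol <- function(values, grid) {
  v <- array(values, dim = grid$shape)
  attr(v, "grid") <- grid
  v
}

# Minimal cohort rows with every column plant_effects may touch
toy_cohort <- function(age = c(20, 80)) {
  n <- length(age)
  data.frame(subject_id = sprintf("S%02d", seq_len(n)), visit_index = 1L,
             group = "CU-young", age_years = age, sex = "F",
             education_years = 12, months_from_baseline = 0,
             sequence_variant = 0L, amyloid_suvr = 1.1, fdg_suvr = 1.3,
             hippo_volume_raw = 6500, tiv = 1.45e6, mmse = 29, mdrs = 140,
             months_to_dementia = NA_real_, mean_fd = 0.1,
             stringsAsFactors = FALSE)
}
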