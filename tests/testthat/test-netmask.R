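test_that("tfce matches the hand-summed single-voxel series", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  # sum_{k=1..10} 1^0.5 * (0.1 k)^2 * 0.1 = 0.385
  expect_equal(tfce(m, dh = 0.1)[3, 3, 3], sum((0.1 * (1:10))^2 * 0.1))
  expect_equal(tfce(m, dh = 0.1)[3, 3, 3], 0.385)
  expect_equal(tfce(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)),
               ignore_attr = TRUE)
  expect_equal(tfce(array(-1, c(4, 4, 4))), array(0, c(4, 4, 4)),
               ignore_attr = TRUE)
})

test_that("tfce equals the brute-force per-threshold labeller", {
  set.seed(21)
  for (conn in c(26, 18, 6)) {
    for (i in 1:4) {
      m <- array(rnorm(125), c(5, 5, 5))
      expect_lt(max(abs(tfce(m, connectivity = conn) -
                          brute_tfce(pmax(m, 0), connectivity = conn))), 1e-8)
    }
  }
  # sparse maps with plateaus (exact ties across voxels)
  m <- array(0, c(5, 5, 5)); m[1:2, 1, 1] <- 0.5; m[4:5, 5, 5] <- 0.5
  expect_lt(max(abs(tfce(m) - brute_tfce(m))), 1e-12)
})

test_that("tfce is symmetric across equal blobs and monotone under scaling", {
  m <- array(0, c(8, 8, 4))
  m[2:3, 2:3, 2] <- 1
  m[6:7, 6:7, 3] <- 1
  v <- tfce(m)
  expect_equal(v[2:3, 2:3, 2], v[6:7, 6:7, 3])
  expect_equal(length(unique(round(v[m > 0], 12))), 1L)

  set.seed(8)
  m2 <- array(pmax(rnorm(125), 0), c(5, 5, 5))
  base <- tfce(m2, dh = max(m2) / 50)
  for (s in c(1.5, 2, 10))
    expect_true(all(tfce(m2 * s, dh = max(m2) * s / 50) >= base - 1e-12))
})

null_maps <- function(n, shape, sd = 1, seed = 1) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, lapply(seq_len(n), function(i)
    array(rnorm(prod(shape), 0, sd), shape)))
}

test_that("one-sample permutation test separates signal from null", {
  shape <- c(10, 10, 6)
  mask <- array(1, shape); attr(mask, "grid") <- volume_grid(shape)

  # planted blob on weak noise: blob voxels are significant
  set.seed(30)
  maps <- lapply(1:12, function(i) {
    a <- array(rnorm(prod(shape), 0, 0.1), shape)
    a[3:6, 3:6, 2:4] <- a[3:6, 3:6, 2:4] + 1
    a
  })
  r <- one_sample_perm_test(maps, mask, n_perm = 500, seed = 1)
  blob <- array(FALSE, shape); blob[3:6, 3:6, 2:4] <- TRUE
  expect_true(all(r$sig_mask[blob] == 1))
  expect_true(all(r$p_fwe_map >= 1 / (r$n_perm_used + 1)))

  # a constant blob (zero variance) is still detected, not an error
  cmaps <- lapply(1:8, function(i) {
    a <- array(0, shape); a[3:6, 3:6, 2:4] <- 5; a
  })
  rc <- one_sample_perm_test(cmaps, mask, n_perm = 1000, seed = 2)
  expect_true(all(rc$sig_mask[blob] == 1))

  expect_error(one_sample_perm_test(maps[1:3], mask, 100, seed = 1), "at least 5")
  expect_warning(one_sample_perm_test(maps, mask, n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("small samples enumerate all sign patterns exhaustively", {
  shape <- c(6, 6, 4)
  mask <- array(1, shape); attr(mask, "grid") <- volume_grid(shape)
  maps <- null_maps(8, shape, seed = 13)
  r <- one_sample_perm_test(maps, mask, n_perm = 1000, seed = 5)
  expect_true(r$exhaustive)
  expect_equal(r$n_perm_used, 256L)
  pv <- r$p_fwe_map[mask > 0] * 256
  expect_true(all(abs(pv - round(pv)) < 1e-9))
  # exhaustive p-values do not depend on the RNG seed
  r2 <- one_sample_perm_test(maps, mask, n_perm = 1000, seed = 99)
  expect_equal(r$p_fwe_map, r2$p_fwe_map)
})

test_that("permutation p-values are reproducible and order-invariant", {
  shape <- c(6, 6, 4)
  mask <- array(1, shape); attr(mask, "grid") <- volume_grid(shape)
  maps <- null_maps(12, shape, seed = 17)
  r1 <- one_sample_perm_test(maps, mask, n_perm = 200, seed = 3)
  r2 <- one_sample_perm_test(maps, mask, n_perm = 200, seed = 3)
  expect_equal(r1$p_fwe_map, r2$p_fwe_map)
  # permuting subject order leaves observed t and TFCE untouched
  r3 <- one_sample_perm_test(maps[sample(12)], mask, n_perm = 200, seed = 3)
  expect_equal(r1$t_map, r3$t_map)
  expect_equal(r1$tfce_map, r3$tfce_map)
})

test_that("paired test is the one-sample test of differences", {
  shape <- c(8, 8, 4)
  mask <- array(1, shape); attr(mask, "grid") <- volume_grid(shape)
  a <- null_maps(10, shape, sd = 0.1, seed = 23)
  expect_equal(sum(paired_perm_test(a, a, mask, 300, seed = 1)$sig_mask), 0)

  blob <- array(0, shape); blob[2:4, 2:4, 2:3] <- 1
  b <- lapply(a, function(m) m + blob)
  fwd <- paired_perm_test(b, a, mask, 300, seed = 1)
  rev <- paired_perm_test(a, b, mask, 300, seed = 1)
  expect_true(all(fwd$sig_mask[blob > 0] == 1))
  expect_equal(sum(rev$sig_mask), 0)
  # swapping the pair mirrors the observed t-map
  expect_equal(fwd$t_map, -rev$t_map)
  expect_error(paired_perm_test(a, a[1:5], mask, 100), "lengths")
})

fake_perm_result <- function(sig, grid) {
  attr(sig, "grid") <- grid
  structure(list(t_map = sig, tfce_map = sig, p_fwe_map = 1 - sig,
                 sig_mask = sig, null_max = numeric(), n_perm_used = 100L,
                 alpha = 0.05, side = "greater", exhaustive = FALSE,
                 grid = grid), class = "perm_result")
}

test_that("network masks follow the one-sample-and-paired intersection rule", {
  g <- tiny_grid(c(6, 6, 2))
  z <- array(0, g$shape)
  left <- z; left[1:3, , ] <- 1
  right <- z; right[4:6, , ] <- 1
  all1 <- z + 1

  ms <- build_network_masks(fake_perm_result(all1, g), fake_perm_result(all1, g),
                            fake_perm_result(left, g), fake_perm_result(right, g))
  expect_equal(unclass(ms$at_mask), left, ignore_attr = TRUE)
  expect_equal(unclass(ms$pm_mask), right, ignore_attr = TRUE)
  expect_equal(sum(ms$at_mask * ms$pm_mask), 0)   # disjoint by construction

  # one-sample significant everywhere, paired nowhere -> both masks empty
  # (one warning per mask)
  expect_warning(expect_warning(
    e <- build_network_masks(fake_perm_result(all1, g), fake_perm_result(all1, g),
                             fake_perm_result(z, g), fake_perm_result(z, g)),
    "AT mask is empty"), "PM mask is empty")
  expect_equal(sum(e$at_mask) + sum(e$pm_mask), 0)

  # union option for the AT rule
  u <- suppressWarnings(
    build_network_masks(fake_perm_result(left, g), fake_perm_result(z, g),
                        fake_perm_result(right, g), fake_perm_result(z, g),
                        combine_at = "union"))
  expect_equal(sum(u$at_mask), 72)
})

test_that("participant mask applies grey matter and seed removal", {
  g <- tiny_grid(c(10, 10, 1))
  group <- as_vol(0, g); group[1:10, 1:10, 1] <- 1   # 100 voxels
  seed1 <- as_vol(0, g); seed1[1:5, 1, 1] <- 1
  seed2 <- as_vol(0, g); seed2[6:10, 1, 1] <- 1      # 10 seed voxels total
  gm <- as_vol(1, g)
  pm <- participant_mask(group, gm, seeds = list(seed1, seed2))
  expect_equal(sum(pm), 90)
  expect_equal(sum(pm * seed1), 0)

  expect_equal(unclass(participant_mask(group, gm)), unclass(group),
               ignore_attr = TRUE)
  expect_warning(p0 <- participant_mask(group, as_vol(0, g)), "empty")
  expect_equal(sum(p0), 0)
  # gm threshold is inclusive at 0.5
  expect_equal(sum(participant_mask(group, as_vol(0.5, g))), 100)
})

test_that("parcellation split enforces the minimum ROI size inclusively", {
  g <- tiny_grid(c(10, 10, 3))
  labels <- as_vol(0, g)
  labels[, , 1] <- 1                  # 100 in-mask voxels
  labels[100 + (1:99)] <- 2           # 99 voxels in slice 2
  mask <- as_vol(0, g); mask[, , 1:2] <- 1
  rois <- split_by_parcellation(mask, labels, min_voxels = 100)
  expect_named(rois, "roi_1")
  expect_equal(sum(rois$roi_1), 100)
  expect_equal(split_by_parcellation(as_vol(0, g), labels), list())
  # ordering and multiple labels
  labels[, , 3] <- 3
  mask3 <- as_vol(1, g)
  rois3 <- split_by_parcellation(mask3, labels, min_voxels = 50)
  expect_equal(names(rois3), c("roi_1", "roi_2", "roi_3"))
})

test_that("dice matches counting arithmetic", {
  g <- tiny_grid(c(5, 2, 1))
  a <- as_vol(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), g)
  b <- as_vol(c(1, 1, 0, 0, 1, 1, 1, 1, 0, 0), g)
  expect_equal(dice(a, b), 2 * 2 / (4 + 6))       # 0.4
  expect_equal(dice(a, a), 1)
  disj <- as_vol(c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0), g)
  expect_equal(dice(a, disj), 0)
  expect_warning(d0 <- dice(as_vol(0, g), as_vol(0, g)), "empty")
  expect_equal(d0, 1)
})
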