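test_that("framewise displacement follows the arc-length convention", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m)$fd_series, rep(0, 10))
  expect_equal(framewise_displacement(m)$mean_fd, 0)

  m1 <- m; m1[5:10, 1] <- 1                     # single 1 mm step
  fd <- framewise_displacement(m1)$fd_series
  expect_equal(fd[5], 1.0)
  expect_equal(fd[-5], rep(0, 9))

  m2 <- m; m2[5:10, 4] <- 1                     # single 1 degree step
  expect_equal(framewise_displacement(m2)$fd_series[5], 50 * pi / 180)
  expect_equal(framewise_displacement(m2, sphere_radius_mm = 100)$fd_series[5],
               100 * pi / 180)

  # invariance to a constant offset on all parameters
  m3 <- matrix(rnorm(60), 10, 6)
  expect_equal(framewise_displacement(m3)$fd_series,
               framewise_displacement(m3 + 5)$fd_series)

  expect_error(framewise_displacement(matrix(c(NaN, rep(0, 11)), 2, 6)),
               "finite")
  expect_error(framewise_displacement(m[0, , drop = FALSE]), "empty")
})

test_that("motion QC applies the translation and rotation exclusion rules", {
  m <- matrix(0, 20, 6)
  expect_equal(motion_qc(m)$decision, "retain")

  mt <- m; mt[10, 2] <- 3.1
  q <- motion_qc(mt)
  expect_equal(q$decision, "exclude")
  expect_equal(q$reasons, "translation")
  expect_equal(motion_qc(m + cbind(matrix(0, 20, 1), matrix(0, 20, 5)) * 0,
                         max_translation_mm = 3)$decision, "retain")

  mr <- m; mr[, 5] <- 1.6                       # mean abs Euler angle 1.6 deg
  q2 <- motion_qc(mr)
  expect_equal(q2$decision, "exclude")
  expect_equal(q2$reasons, "rotation")

  mb <- mt; mb[, 5] <- 1.6
  expect_setequal(motion_qc(mb)$reasons, c("translation", "rotation"))
})

test_that("motion QC is monotone under trace scaling", {
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rnorm(120, 0, runif(1, 0.1, 2)), 20, 6)
    excl <- motion_qc(m)$decision == "exclude"
    for (s in c(1.5, 3, 10)) {
      excl_s <- motion_qc(m * s)$decision == "exclude"
      expect_true(!excl || excl_s,
                  info = "scaling up never flips exclude to retain")
    }
  }
})

make_run <- function(series_list, tr = 2.382) {
  nt <- length(series_list[[1]])
  g <- volume_grid(c(length(series_list), 1, 1))
  arr <- array(0, c(length(series_list), 1, 1, nt))
  for (i in seq_along(series_list)) arr[i, 1, 1, ] <- series_list[[i]]
  bold_run(arr, g, tr)
}

power_in <- function(x) sum(abs(fft(x))^2)

test_that("bandpass keeps in-band and rejects out-of-band power", {
  nt <- 256; tr <- 2.382
  tt <- (seq_len(nt) - 1) * tr
  expect_equal(as.vector(bandpass(make_run(list(rep(5, nt))))$data),
               rep(0, nt), tolerance = 1e-10)

  s_in <- sin(2 * pi * 0.04 * tt)
  out_in <- as.vector(bandpass(make_run(list(s_in)))$data)
  expect_gte(power_in(out_in) / power_in(s_in), 0.95)

  s_out <- sin(2 * pi * 0.15 * tt)
  out_out <- as.vector(bandpass(make_run(list(s_out)))$data)
  expect_lte(power_in(out_out) / power_in(s_out), 0.05)

  set.seed(1)
  noise <- rnorm(nt)
  filtered <- as.vector(bandpass(make_run(list(noise)))$data)
  expect_lt(abs(mean(filtered)), 1e-10)

  expect_error(bandpass(make_run(list(noise)), high_hz = 0.3), "Nyquist")
  expect_error(bandpass(make_run(list(noise)), low_hz = 0.1, high_hz = 0.05),
               "low_hz")
})

test_that("confound extraction computes tissue means and first differences", {
  g <- volume_grid(c(4, 4, 4))
  nt <- 30
  arr <- array(7, c(4, 4, 4, nt))
  run <- bold_run(arr, g, 2.0)
  seg <- list(wm = as_vol(1, g), csf = as_vol(1, g), brain_mask = as_vol(1, g))
  motion <- matrix(0, nt, 6)
  cs <- extract_confounds(run, seg, motion)
  expect_equal(unname(cs$columns[, "wm_mean"]), rep(7, nt))
  expect_equal(unname(cs$columns[, "d_wm"]), rep(0, nt))
  expect_equal(cs$mean_fd, 0)
  expect_equal(colnames(cs$columns)[1:6],
               c("wm_mean", "csf_mean", "global_mean", "d_wm", "d_csf",
                 "d_global"))

  # first difference of (1,3,6) is (0,2,3): plant it in the WM mean
  arr2 <- array(rep(c(1, 3, 6), each = 64), c(4, 4, 4, 3))
  run2 <- bold_run(arr2, g, 2.0)
  cs2 <- extract_confounds(run2, seg, matrix(0, 3, 6))
  expect_equal(unname(cs2$columns[, "d_wm"]), c(0, 2, 3))

  seg_empty <- seg; seg_empty$wm <- as_vol(0.5, g)
  expect_error(extract_confounds(run, seg_empty, motion), "tissue_threshold")
})

test_that("nuisance regression residualizes against confounds", {
  g <- volume_grid(c(3, 1, 1))
  nt <- 60
  set.seed(2)
  wm <- rnorm(nt)
  e <- rnorm(nt, 0, 0.1)
  arr <- array(0, c(3, 1, 1, nt))
  arr[1, 1, 1, ] <- wm                 # equal to a confound column
  arr[2, 1, 1, ] <- 2 * wm + e         # planted linear dependence
  arr[3, 1, 1, ] <- rnorm(nt) + 3
  run <- bold_run(arr, g, 2.0)
  cols <- cbind(wm_mean = wm, csf_mean = rnorm(nt), global_mean = rnorm(nt),
                d_wm = c(0, diff(wm)), d_csf = rnorm(nt), d_global = rnorm(nt),
                matrix(rnorm(6 * nt), nt, 6,
                       dimnames = list(NULL, paste0("motion_", 1:6))))
  conf <- structure(list(columns = cols, fd_series = rep(0, nt), mean_fd = 0),
                    class = "confound_set")
  res <- nuisance_regression(run, conf)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-8)
  expect_lt(abs(cor(res$data[2, 1, 1, ], wm)), 1e-6)
  # residuals orthogonal to every retained regressor
  X <- cbind(1, cols)
  dots <- abs(crossprod(X, res$data[3, 1, 1, ]))
  expect_lt(max(dots) / sqrt(sum(res$data[3, 1, 1, ]^2)), 1e-6)

  # all-zero confounds are pruned; residuals are the demeaned input
  conf0 <- conf; conf0$columns <- cols * 0
  expect_warning(res0 <- nuisance_regression(run, conf0), "collinear")
  expect_equal(res0$data[3, 1, 1, ], arr[3, 1, 1, ] - mean(arr[3, 1, 1, ]),
               tolerance = 1e-10)
})

test_that("filtering run and confounds identically keeps residuals in band", {
  g <- volume_grid(c(2, 2, 2))
  nt <- 128; tr <- 2.382
  set.seed(9)
  arr <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  run <- bold_run(arr, g, tr)
  motion <- matrix(cumsum(rnorm(nt * 6, 0, 0.01)), nt, 6)
  seg <- list(wm = as_vol(1, g), csf = as_vol(1, g), brain_mask = as_vol(1, g))
  fr <- bandpass(run)
  conf <- filter_confounds(extract_confounds(run, seg, motion), tr)
  res <- suppressWarnings(nuisance_regression(fr, conf))
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  inband <- freqs >= 0.01 & freqs <= 0.08
  for (i in 1:2) {
    sp <- abs(fft(res$data[i, 1, 1, ]))^2
    expect_lt(sum(sp[!inband]) / sum(sp), 0.01)
  }
})

test_that("motion TSV round-trips", {
  m <- matrix(rnorm(30), 5, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_motion(m, p)
  expect_equal(read_motion(p), m, tolerance = 1e-12)
})
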