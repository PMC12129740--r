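test_that("holm matches the hand-stepped examples and the brute-force oracle", {
  h1 <- holm(c(0.01, 0.04))
  expect_equal(h1$adjusted, c(0.02, 0.04))
  expect_equal(h1$reject, c(TRUE, TRUE))

  h2 <- holm(c(0.03, 0.04))
  expect_equal(h2$adjusted, c(0.06, 0.06))
  expect_equal(h2$reject, c(FALSE, FALSE))

  expect_equal(holm(0.04)$adjusted, 0.04)   # m = 1 is the identity
  expect_error(holm(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(14)
  for (i in 1:50) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    got <- holm(p)
    want <- brute_holm(p)
    expect_equal(got$adjusted, want$adjusted)
    expect_equal(got$reject, want$reject)
  }
})

test_that("holm rejects at least as much as Bonferroni", {
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(2:10, 1))
    rej_holm <- holm(p)$reject
    rej_bonf <- p.adjust(p, "bonferroni") < 0.05
    expect_true(all(rej_holm[rej_bonf]))
  }
})

test_that("group ranking codes the Alzheimer's continuum order", {
  expect_equal(rank_groups(c("CU-young", "AD")), c(1L, 6L))
  expect_equal(rank_groups(c("AD", "CU-young")), c(6L, 1L))
  expect_equal(rank_groups(c("CU-middle", "CU-oldneg", "CU-oldpos", "MCI")),
               2:5)
  expect_error(rank_groups("controls"), "unknown group")
  expect_warning(rank_groups(c("MCI", "MCI")), "identical")
})

test_that("LMM on one observation per subject reproduces the OLS F oracle", {
  set.seed(16)
  n <- 60
  dat <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    x = rnorm(n), gfac = sample(c("a", "b", "c"), n, TRUE))
  dat$y <- 0.5 * dat$x + 0.3 * (dat$gfac == "b") + rnorm(n, 0, 0.4)
  fit <- fit_lmm(dat, model_spec("y", c("x", "gfac")))
  ols <- stats::anova(lm(y ~ gfac + x, data = dat))
  # with a single visit each, random-intercept variance collapses and
  # Satterthwaite F equals the OLS sequential F for the last-entered term
  expect_equal(fit$f_tests$F[fit$f_tests$term == "x"],
               ols["x", "F value"], tolerance = 1e-3)
  ols2 <- stats::anova(lm(y ~ x + gfac, data = dat))
  expect_equal(fit$f_tests$F[fit$f_tests$term == "gfac"],
               ols2["gfac", "F value"], tolerance = 1e-3)
  b <- fit$coefficients
  expect_true(all(b$ci_lo <= b$estimate & b$estimate <= b$ci_hi))
})

test_that("LMM recovers a planted slope and flags degenerate outcomes", {
  cfg <- cohort_config(group_sizes = c("CU-young" = 80, "CU-middle" = 60,
                                       "CU-oldneg" = 60))
  cc <- generate_cohort(cfg, seed = 21)$cohort
  fit <- fit_lmm(cc, model_spec("pm_index", c("age_years", "sex",
                                              "education_years")))
  est <- fit$coefficients[fit$coefficients$term == "age_years", ]
  expect_lt(abs(est$estimate - (-0.0007)), 4 * est$se)
  expect_equal(fit$n_subjects, 200)

  cc$flat <- 0
  dfit <- fit_lmm(cc, model_spec("flat", "age_years"))
  expect_true(dfit$degenerate)
  expect_equal(dfit$coefficients$estimate, c(0, 0))

  expect_error(fit_lmm(cc, model_spec("nope", "age_years")), "missing column")
})

test_that("interaction models auto-select type III with sum contrasts", {
  expect_equal(model_spec("y", c("g*t"))$ftest_type, "III")
  expect_equal(model_spec("y", c("g", "t"))$ftest_type, "II")
  expect_error(model_spec("y", "g*t", ftest_type = "II"), "type III")

  cfg <- cohort_config(group_sizes = c("CU-oldneg" = 40, "MCI" = 20, "AD" = 20))
  cc <- generate_cohort(cfg, seed = 22)$cohort
  fit <- fit_lmm(cc, model_spec("at_index", c("group*months_from_baseline",
                                              "sex")))
  expect_true("group:months_from_baseline" %in% fit$f_tests$term)
})

test_that("ranked-group smooth reports edf near 1 for linear truths", {
  # a single draw can show chance nonlinearity in the per-rank noise means,
  # so the linear-limit property is asserted on the median over replicates
  set.seed(23)
  n <- 240
  sims <- replicate(41, {
    rank <- sample(1:6, n, TRUE)
    base <- data.frame(group_rank = rank,
                       y_lin = 0.02 * rank + rnorm(n, 0, 0.01),
                       y_const = 0.1 + rnorm(n, 0, 0.05))
    c(lin = fit_gam_ranked(base, "y_lin", "group_rank", k = 6)$edf,
      const = fit_gam_ranked(base, "y_const", "group_rank", k = 6)$edf)
  })
  expect_gte(median(sims["lin", ]), 1)
  expect_lte(median(sims["lin", ]), 1.2)
  expect_lte(median(sims["const", ]), 1.2)

  rank <- sample(1:6, n, TRUE)
  base <- data.frame(group_rank = rank)
  base$y_quad <- 0.02 * (rank - 3.5)^2 + rnorm(n, 0, 0.005)
  f_quad <- fit_gam_ranked(base, "y_quad", "group_rank", k = 6)
  expect_gt(f_quad$edf, 1.5)

  base$y_lin <- 0.02 * rank + rnorm(n, 0, 0.01)
  expect_error(fit_gam_ranked(base[base$group_rank %in% 1:2, ], "y_lin",
                              "group_rank"), "3 distinct")
  expect_warning(fit_gam_ranked(base[base$group_rank %in% 1:4, ], "y_lin",
                                "group_rank", k = 6), "reducing basis")
})

test_that("ANCOVA contrasts recover planted group offsets and adjust for covariates", {
  set.seed(24)
  n <- 75
  dat <- data.frame(group = rep(c("CU-oldneg", "MCI", "AD"), each = 25),
                    age_years = rnorm(n, 70, 5), sex = sample(c("F", "M"), n, TRUE),
                    education_years = rnorm(n, 12, 3))
  dat$y <- 0.15 + 0.04 * (dat$group == "MCI") + rnorm(n, 0, 0.03)
  f <- ancova_pairwise(dat, "y", "group",
                       c("age_years", "sex", "education_years"))
  ctr <- f$contrasts
  mci_ad <- ctr[grepl("MCI", ctr$contrast) & grepl("AD", ctr$contrast), ]
  expect_lt(abs(abs(mci_ad$estimate) - 0.04), 2.5 * mci_ad$SE)
  expect_equal(nrow(ctr), 3)

  # identical groups: contrast near zero
  dat$y0 <- rnorm(n, 0.2, 0.03)
  f0 <- ancova_pairwise(dat, "y0", "group",
                        c("age_years", "sex", "education_years"))
  expect_true(all(abs(f0$contrasts$estimate) < 3 * f0$contrasts$SE))

  # an offset fully explained by a covariate vanishes after adjustment
  dat2 <- dat
  dat2$age_years <- 60 + 10 * (dat2$group == "MCI") + rnorm(n, 0, 0.5)
  dat2$y2 <- 0.002 * dat2$age_years + rnorm(n, 0, 0.002)
  f2 <- ancova_pairwise(dat2, "y2", "group",
                        c("age_years", "sex", "education_years"))
  mci2 <- f2$contrasts[grepl("MCI", f2$contrasts$contrast), ]
  expect_true(all(abs(mci2$estimate) < 3 * mci2$SE))
})

test_that("analysis suite assembles the declared design families", {
  cfg <- cohort_config(group_sizes = c("CU-young" = 25, "CU-middle" = 15,
                                       "CU-oldneg" = 25, "CU-oldpos" = 6,
                                       "MCI" = 15, "AD" = 12),
                       at_terms = c("age", "group"), pm_terms = "age")
  cc <- generate_cohort(cfg, seed = 31)$cohort
  out <- run_analysis_suite(cc)
  res <- out$results
  # the association family is exactly 2 networks x 5 features = 10 tests
  assoc <- res[res$family == "associations", ]
  expect_equal(nrow(assoc), 10)
  expect_true(all(is.finite(assoc$p_holm)))
  expect_true(all(assoc$p_holm >= assoc$p - 1e-12))
  expect_true(all(c("age", "stage", "converter", "gam_ranked") %in% res$family))

  # restricting families runs exactly the requested designs
  only_age <- run_analysis_suite(cc, families = "age")
  expect_equal(unique(only_age$results$family), "age")

  expect_error(run_analysis_suite(cc[, setdiff(names(cc), "at_index")]),
               "at_index")
})

test_that("suite variants add FD adjustment and the both-network model", {
  cfg <- cohort_config(group_sizes = c("CU-young" = 30, "CU-oldneg" = 30))
  cc <- generate_cohort(cfg, seed = 32)$cohort
  out <- run_analysis_suite(cc, families = "age", fd_adjust = TRUE,
                            both_networks = TRUE)
  expect_true("age_both_networks" %in% out$results$design)
  f <- out$fits$age_at_index
  expect_true("mean_fd" %in% f$coefficients$term)
  fb <- out$fits$age_both_networks
  expect_true(any(grepl("network", fb$f_tests$term)))
})
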