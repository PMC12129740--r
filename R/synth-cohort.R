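#' @useDynLib mtlnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile coef anova sd lm as.formula
#'   model.matrix complete.cases p.adjust qt confint fft resid
NULL

GROUP_LEVELS <- c("CU-young", "CU-middle", "CU-oldneg", "CU-oldpos", "MCI", "AD")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Default planted effect sizes
#'
#' Linear effects planted on the network connectivity indexes by the
#' synthetic-cohort generator.  Slopes are in Fisher-z units per unit of the
#' predictor: per year of age, per SUVR unit (amyloid, glucose metabolism),
#' per standard deviation of normalized hippocampal volume, per cognition
#' point (MMSE, MDRS), per month of delay to dementia onset.  Group offsets
#' shift the anterior-temporal index for the impaired stages.
#'
#' @return Named list of effect sizes.
#' @export
default_effect_params <- function() {
  list(
    at_intercept = 0.15,
    pm_intercept = 0.20,
    age_at       = 0.0003,
    age_pm       = -0.0007,
    amyloid      = 0.1601,
    fdg          = -0.1013,
    hippo        = -0.0694,
    mmse         = -0.0047,
    mdrs         = -0.0018,
    delay        = -0.0136,
    group_mci    = 0.0416,
    group_ad     = 0.0375
  )
}

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the source cohort structure: six groups along the
#' Alzheimer's continuum with the study's group sizes, baseline age ranges,
#' education, cognition and visit-count distributions; visits spaced about
#' 18 months apart; amyloid and FDG PET restricted to participants over 60;
#' 18 of 26 MCI patients converting to dementia within 0--85 months.
#'
#' @param group_sizes named integer vector over the six group levels.
#' @param age_ranges named list of c(min, max) baseline age per group.
#' @param effect_params planted effects, see [default_effect_params()].
#' @param at_terms,pm_terms character vectors naming which effects enter the
#'   planted anterior-temporal / posterior-medial indexes.  Recognised terms:
#'   `"age"`, `"amyloid"`, `"fdg"`, `"hippo"`, `"mmse"`, `"mdrs"`, `"delay"`,
#'   `"group"`.
#' @param noise_sd residual SD of the emitted indexes around their planted
#'   linear predictor (visit-level Gaussian noise).  The source data do not
#'   report a within-subject index variance; 0.05 is a free default.
#' @param subject_sd SD of a per-subject random intercept added to both
#'   indexes (0 disables it).
#' @param visit_spacing_months,visit_jitter_sd mean and SD of the inter-visit
#'   interval.
#' @param fd_means named numeric vector of group mean framewise displacement
#'   (mm).
#' @param hippo_ref_mean,hippo_ref_sd reference mean/SD used to standardize
#'   normalized hippocampal volume before applying the `hippo` effect.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("CU-young" = 85, "CU-middle" = 60,
                                          "CU-oldneg" = 56, "CU-oldpos" = 8,
                                          "MCI" = 26, "AD" = 26),
                          age_ranges = list("CU-young"  = c(19.5, 39.9),
                                            "CU-middle" = c(40.0, 59.6),
                                            "CU-oldneg" = c(60.0, 84.6),
                                            "CU-oldpos" = c(60.0, 84.6),
                                            "MCI"       = c(60.7, 85.0),
                                            "AD"        = c(51.7, 84.1)),
                          effect_params = default_effect_params(),
                          at_terms = c("age"),
                          pm_terms = c("age"),
                          noise_sd = 0.05,
                          subject_sd = 0,
                          visit_spacing_months = 18,
                          visit_jitter_sd = 4,
                          fd_means = c("CU-young" = 0.12, "CU-middle" = 0.14,
                                       "CU-oldneg" = 0.17, "CU-oldpos" = 0.18,
                                       "MCI" = 0.20, "AD" = 0.22),
                          hippo_ref_mean = HIPPO_NORM_REF_MEAN,
                          hippo_ref_sd = HIPPO_NORM_REF_SD) {
  if (length(group_sizes) == 0L) stop("empty cohort configuration")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% GROUP_LEVELS))
    stop("group_sizes must be named with levels among: ",
         paste(GROUP_LEVELS, collapse = ", "))
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  for (g in names(group_sizes)) {
    r <- age_ranges[[g]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2])
      stop("invalid age range for group ", g)
  }
  known <- c("age", "amyloid", "fdg", "hippo", "mmse", "mdrs", "delay", "group")
  bad <- setdiff(c(at_terms, pm_terms), known)
  if (length(bad)) stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  structure(list(group_sizes = group_sizes, age_ranges = age_ranges,
                 effect_params = effect_params,
                 at_terms = at_terms, pm_terms = pm_terms,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 visit_spacing_months = visit_spacing_months,
                 visit_jitter_sd = visit_jitter_sd, fd_means = fd_means,
                 hippo_ref_mean = hippo_ref_mean, hippo_ref_sd = hippo_ref_sd),
            class = "cohort_config")
}

rnorm_clamp <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

# Group-conditional marginal distributions for covariates and biomarkers.
# Means/SDs/ranges follow the study's demographics table; the young-adult
# amyloid SD is calibrated so that the 99.9th-percentile (type-7) threshold
# computed from a 45-subject young sample -- in effect the sample maximum,
# ~2.2 SD above the mean -- lands near the positivity threshold of 1.31.
group_marginals <- function(group) {
  switch(group,
    "CU-young"  = list(edu = c(13.9, 2.9, 9, 20),  mmse = c(29.4, 0.7, 27, 30),
                       mdrs = c(142.2, 2.4, 132, 144), visits = c(0.2, 0.8, 0),
                       suvr = c(1.10, 0.095), fdg = c(1.40, 0.10),
                       hippo = c(6800, 550), pet = FALSE),
    "CU-middle" = list(edu = c(13.9, 2.9, 9, 20),  mmse = c(29.4, 0.7, 27, 30),
                       mdrs = c(142.2, 2.4, 132, 144), visits = c(0.2, 0.8, 0),
                       suvr = c(1.12, 0.095), fdg = c(1.38, 0.10),
                       hippo = c(6600, 550), pet = FALSE),
    "CU-oldneg" = list(edu = c(12.1, 3.7, 7, 20),  mmse = c(28.8, 1.2, 26, 30),
                       mdrs = c(141.2, 2.7, 130, 144), visits = c(0.12, 0.46, 0.42),
                       suvr = c(1.15, 0.06), fdg = c(1.32, 0.10),
                       hippo = c(6200, 600), pet = TRUE),
    "CU-oldpos" = list(edu = c(12.1, 3.7, 7, 20),  mmse = c(28.8, 1.2, 26, 30),
                       mdrs = c(141.2, 2.7, 130, 144), visits = c(0.12, 0.46, 0.42),
                       suvr = c(1.50, 0.12), fdg = c(1.28, 0.10),
                       hippo = c(6000, 600), pet = TRUE),
    "MCI"       = list(edu = c(11.8, 4.3, 6, 20),  mmse = c(26.6, 1.7, 22, 30),
                       mdrs = c(132.3, 5.6, 122, 142), visits = c(0.3, 0.5, 0.2),
                       suvr = c(1.55, 0.15), fdg = c(1.18, 0.10),
                       hippo = c(5400, 650), pet = TRUE),
    "AD"        = list(edu = c(11.5, 3.6, 7, 20),  mmse = c(20.6, 4.9, 12, 29),
                       mdrs = c(118.2, 10.8, 101, 139), visits = c(0.4, 0.6, 0),
                       suvr = c(1.65, 0.18), fdg = c(1.08, 0.10),
                       hippo = c(4900, 650), pet = TRUE),
    stop("unknown group: ", group))
}

empty_cohort <- function() {
  data.frame(subject_id = character(), visit_index = integer(),
             group = character(), age_years = numeric(), sex = character(),
             education_years = numeric(), months_from_baseline = numeric(),
             sequence_variant = integer(), amyloid_suvr = numeric(),
             fdg_suvr = numeric(), hippo_volume_raw = numeric(),
             tiv = numeric(), mmse = numeric(), mdrs = numeric(),
             months_to_dementia = numeric(), mean_fd = numeric(),
             at_true = numeric(), pm_true = numeric(),
             at_index = numeric(), pm_index = numeric(),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort table with known ground truth
#'
#' Table-mode generation: emits a long-format per-visit cohort table whose
#' `at_index` / `pm_index` columns equal a planted linear predictor (see
#' [plant_effects()]) plus Gaussian noise, together with a `ground_truth`
#' record of every planted parameter.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return List with elements `cohort` (data.frame, one row per visit) and
#'   `truth` (class `ground_truth`).
#' @examples
#' cg <- generate_cohort(cohort_config(group_sizes = c("CU-young" = 5)), seed = 1)
#' head(cg$cohort)
#' @export
generate_cohort <- function(config, seed) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  sizes <- config$group_sizes
  if (sum(sizes) == 0L) {
    truth <- structure(list(at_voxels = integer(), pm_voxels = integer(),
                            seed_prc = integer(), seed_phc = integer(),
                            loading_per_subject = data.frame(),
                            effect_params = config$effect_params,
                            at_terms = config$at_terms, pm_terms = config$pm_terms,
                            noise_sd = config$noise_sd, rng_seed = seed),
                       class = "ground_truth")
    return(list(cohort = empty_cohort(), truth = truth))
  }
  cohort <- with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in names(sizes)) {
      n <- sizes[[g]]
      if (n == 0L) next
      m <- group_marginals(g)
      ar <- config$age_ranges[[g]]
      for (i in seq_len(n)) {
        sid <- sid + 1L
        nv <- sample(1:3, 1L, prob = m$visits)
        age0 <- runif(1, ar[1], ar[2])
        sex <- if (runif(1) < 0.5) "F" else "M"
        edu <- rnorm_clamp(1, m$edu[1], m$edu[2], m$edu[3], m$edu[4])
        seqv <- if (g %in% c("CU-young", "CU-middle") && runif(1) < 0.075) 1L else 0L
        tiv <- rnorm(1, 1.45e6, 1.1e5)
        hippo0 <- rnorm(1, m$hippo[1], m$hippo[2])
        suvr0 <- if (g == "CU-oldneg") {
          min(rnorm(1, m$suvr[1], m$suvr[2]), 1.30)
        } else if (m$pet) {
          max(rnorm(1, m$suvr[1], m$suvr[2]), 1.32)
        } else rnorm(1, m$suvr[1], m$suvr[2])
        # young/middle-aged adults carry florbetapir SUVRs too (the
        # positivity threshold is defined on the under-40 distribution)
        fdg0 <- rnorm(1, m$fdg[1], m$fdg[2])
        mmse0 <- rnorm_clamp(1, m$mmse[1], m$mmse[2], m$mmse[3], m$mmse[4])
        mdrs0 <- rnorm_clamp(1, m$mdrs[1], m$mdrs[2], m$mdrs[3], m$mdrs[4])
        converter <- g == "MCI" && runif(1) < 18 / 26
        onset <- if (converter) runif(1, 0, 85) else NA_real_
        tvis <- c(0, cumsum(pmax(
          rnorm(2, config$visit_spacing_months, config$visit_jitter_sd), 6)))[1:nv]
        fd <- pmax(rnorm(nv, config$fd_means[[g]], 0.04), 0.02)
        rows[[sid]] <- data.frame(
          subject_id = sprintf("S%04d", sid), visit_index = seq_len(nv),
          group = g, age_years = age0 + tvis / 12, sex = sex,
          education_years = edu, months_from_baseline = tvis,
          sequence_variant = seqv,
          amyloid_suvr = suvr0 + rnorm(nv, 0, 0.02),
          fdg_suvr = fdg0 + rnorm(nv, 0, 0.02),
          hippo_volume_raw = hippo0 - (if (g %in% c("MCI", "AD")) 25 else 8) *
            tvis / 12 + rnorm(nv, 0, 40),
          tiv = tiv,
          mmse = pmin(pmax(mmse0 - (if (g %in% c("MCI", "AD")) 0.8 else 0.05) *
                             tvis / 12 + rnorm(nv, 0, 0.3), 0), 30),
          mdrs = pmin(pmax(mdrs0 - (if (g %in% c("MCI", "AD")) 2 else 0.2) *
                             tvis / 12 + rnorm(nv, 0, 0.8), 0), 144),
          months_to_dementia = if (converter) pmax(onset - tvis, 0) else NA_real_,
          mean_fd = fd, stringsAsFactors = FALSE)
      }
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    cohort <- plant_effects(cohort, config$effect_params,
                            at_terms = config$at_terms, pm_terms = config$pm_terms,
                            hippo_ref_mean = config$hippo_ref_mean,
                            hippo_ref_sd = config$hippo_ref_sd)
    usubj <- unique(cohort$subject_id)
    ranef <- rnorm(length(usubj), 0, config$subject_sd)
    names(ranef) <- usubj
    b <- ranef[cohort$subject_id]
    cohort$at_index <- cohort$at_true + b + rnorm(nrow(cohort), 0, config$noise_sd)
    cohort$pm_index <- cohort$pm_true + b + rnorm(nrow(cohort), 0, config$noise_sd)
    cohort
  })
  truth <- structure(list(at_voxels = integer(), pm_voxels = integer(),
                          seed_prc = integer(), seed_phc = integer(),
                          loading_per_subject = data.frame(),
                          effect_params = config$effect_params,
                          at_terms = config$at_terms, pm_terms = config$pm_terms,
                          noise_sd = config$noise_sd, rng_seed = seed),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Plant linear effects into a cohort table
#'
#' Writes deterministic `at_true` / `pm_true` columns as an exactly linear
#' function of the selected predictors:
#' \deqn{at\_true = \beta_0 + \beta_{age,AT} \cdot age + \beta_{A\beta} \cdot
#'   SUVR + \dots}
#' The mapping is invertible given `effects`: regressing `at_true` on the
#' selected design recovers the coefficients to machine precision.
#' Hippocampal volume enters on a standardized scale,
#' `(raw/(TIV*1000) - hippo_ref_mean)/hippo_ref_sd`, with fixed reference
#' constants so the mapping does not depend on the realized sample.
#' Terms whose predictor is missing for a row contribute 0 for that row.
#'
#' @param cohort data.frame with covariate columns populated.
#' @param effects named list of effect sizes, see [default_effect_params()].
#' @param at_terms,pm_terms which terms enter each index.
#' @param hippo_ref_mean,hippo_ref_sd standardization constants.
#' @return `cohort` with `at_true` and `pm_true` columns added.
#' @export
plant_effects <- function(cohort, effects = default_effect_params(),
                          at_terms = c("age"), pm_terms = c("age"),
                          hippo_ref_mean = HIPPO_NORM_REF_MEAN, hippo_ref_sd = HIPPO_NORM_REF_SD) {
  known <- c("age", "amyloid", "fdg", "hippo", "mmse", "mdrs", "delay", "group")
  bad <- setdiff(c(at_terms, pm_terms), known)
  if (length(bad)) stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  need <- setdiff(names(default_effect_params()), names(effects))
  if (length(need)) stop("effects is missing: ", paste(need, collapse = ", "))
  z <- function(x) ifelse(is.na(x), 0, x)
  term_val <- function(term, which) {
    if (term == "hippo") {
      hippo_z <- (cohort$hippo_volume_raw / (cohort$tiv * 1000) -
                    hippo_ref_mean) / hippo_ref_sd
      return(effects$hippo * z(hippo_z))
    }
    switch(term,
      age     = (if (which == "at") effects$age_at else effects$age_pm) *
                  cohort$age_years,
      amyloid = effects$amyloid * z(cohort$amyloid_suvr),
      fdg     = effects$fdg * z(cohort$fdg_suvr),
      mmse    = effects$mmse * cohort$mmse,
      mdrs    = effects$mdrs * cohort$mdrs,
      delay   = effects$delay * z(cohort$months_to_dementia),
      group   = effects$group_mci * (cohort$group == "MCI") +
                effects$group_ad * (cohort$group == "AD"))
  }
  at <- rep(effects$at_intercept, nrow(cohort))
  for (tm in at_terms) at <- at + term_val(tm, "at")
  pm <- rep(effects$pm_intercept, nrow(cohort))
  for (tm in pm_terms) pm <- pm + term_val(tm, "pm")
  cohort$at_true <- at
  cohort$pm_true <- pm
  cohort
}

#' Write / read a cohort table as TSV
#'
#' Tab-separated, UTF-8, `.` decimal separator, `NA` for missing.
#' @param cohort data.frame as produced by [generate_cohort()].
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
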