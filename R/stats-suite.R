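# Fixed normative reference used to standardize normalized hippocampal
# volume on both the generator and analysis sides (dimensionless scale of
# raw_mm3/(TIV_mm3 * 1000)).
HIPPO_NORM_REF_MEAN <- 4.5e-6
HIPPO_NORM_REF_SD <- 6e-7

#' Standardized normalized hippocampal volume
#'
#' [normalize_volume()] followed by standardization against the package's
#' fixed normative reference (so the scale does not depend on the realized
#' sample and planted effects are recoverable on the same scale).
#'
#' @param raw_mm3,tiv_mm3 see [normalize_volume()].
#' @return z-scored normalized volume.
#' @export
hippo_volume_z <- function(raw_mm3, tiv_mm3) {
  (normalize_volume(raw_mm3, tiv_mm3) - HIPPO_NORM_REF_MEAN) / HIPPO_NORM_REF_SD
}

suite_subsets <- list(
  age = c("CU-young", "CU-middle", "CU-oldneg"),
  older = c("CU-oldneg", "CU-oldpos", "MCI", "AD"))

assoc_features <- c(amyloid = "amyloid_suvr", fdg = "fdg_suvr",
                    hippo = "hippo_z", mmse = "mmse", mdrs = "mdrs")

#' Run the full statistical design suite on a cohort table
#'
#' Assembles and fits the study designs on a long-format cohort table:
#' \describe{
#'   \item{age}{AT and PM connectivity on age among cognitively unimpaired,
#'     amyloid-negative adults, adjusting for sex, education and the fMRI
#'     sequence variant; longitudinal LMM with random intercepts.}
#'   \item{stage}{baseline ANCOVA across the older groups with pairwise
#'     estimated-marginal-mean contrasts, plus a longitudinal time-by-group
#'     interaction LMM (type III).}
#'   \item{associations}{time-adjusted LMMs of each network index on each
#'     Alzheimer's feature (amyloid SUVR, FDG SUVR, standardized hippocampal
#'     volume, MMSE, MDRS) in participants over 60 — a family of 10 tests
#'     corrected with Holm-Bonferroni.}
#'   \item{converter}{AT and PM connectivity on months to dementia onset
#'     among MCI converters.}
#'   \item{gam_ranked}{baseline ranked-group smooths (k = 6) for each
#'     network, reporting effective degrees of freedom.}
#' }
#' Optional variants rerun designs adjusted for mean framewise displacement
#' (`fd_adjust`) and fit the age model with both networks simultaneously via
#' a network-by-age interaction (`both_networks`).
#'
#' @param table cohort data.frame (see [generate_cohort()] for the schema).
#' @param families character vector choosing designs.
#' @param fd_adjust,both_networks logical variant switches.
#' @param holm_alpha family-wise level for the association family.
#' @return List: `results` (tidy data.frame: family, design, outcome, term,
#'   estimate, ci_lo, ci_hi, F, df_num, df_den, p, p_holm) and `fits`
#'   (named list of `model_fit`s).
#' @export
run_analysis_suite <- function(table,
                               families = c("age", "stage", "associations",
                                            "converter", "gam_ranked"),
                               fd_adjust = FALSE, both_networks = FALSE,
                               holm_alpha = 0.05) {
  families <- match.arg(families, several.ok = TRUE)
  need <- c("subject_id", "group", "age_years", "sex", "education_years",
            "months_from_baseline", "at_index", "pm_index")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("cohort table is missing column(s) required by the suite: ",
         paste(miss, collapse = ", "))
  tab <- table
  if (all(c("hippo_volume_raw", "tiv") %in% names(tab)))
    tab$hippo_z <- ifelse(is.na(tab$hippo_volume_raw) | is.na(tab$tiv),
                          NA_real_,
                          hippo_volume_z(pmax(tab$hippo_volume_raw, 1e-9),
                                         pmax(tab$tiv, 1e-9)))
  covars <- c("sex", "education_years", "age_years")
  if (fd_adjust) covars <- c(covars, "mean_fd")
  fits <- list()
  rows <- list()
  add_row <- function(family, design, outcome, term, fitobj,
                      coef_term = term, f_term = term) {
    co <- fitobj$coefficients
    ft <- fitobj$f_tests
    ci <- co[match(coef_term, co$term), , drop = FALSE]
    fr <- if (!is.null(ft)) ft[match(f_term, ft$term), , drop = FALSE] else NULL
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, design = design, outcome = outcome, term = term,
      estimate = if (nrow(ci)) ci$estimate else NA_real_,
      ci_lo = if (nrow(ci)) ci$ci_lo else NA_real_,
      ci_hi = if (nrow(ci)) ci$ci_hi else NA_real_,
      F = if (!is.null(fr) && nrow(fr)) fr$F else NA_real_,
      df_num = if (!is.null(fr) && nrow(fr)) fr$df_num else NA_real_,
      df_den = if (!is.null(fr) && nrow(fr)) fr$df_den else NA_real_,
      p = if (!is.null(fr) && nrow(fr)) fr$p else
        if (nrow(ci)) ci$p else NA_real_,
      p_holm = NA_real_, stringsAsFactors = FALSE)
  }

  if ("age" %in% families) {
    sub <- tab[tab$group %in% suite_subsets$age, , drop = FALSE]
    terms <- c("age_years", "sex", "education_years", "sequence_variant",
               if (fd_adjust) "mean_fd")
    for (net in c("at_index", "pm_index")) {
      f <- fit_lmm(sub, model_spec(net, terms))
      fits[[paste0("age_", net)]] <- f
      add_row("age", "age_lmm", net, "age_years", f)
    }
    if (both_networks) {
      long <- rbind(
        transform(sub, index = sub$at_index, network = "AT"),
        transform(sub, index = sub$pm_index, network = "PM"))
      f <- fit_lmm(long, model_spec("index",
                                    c("network*age_years", "sex",
                                      "education_years", "sequence_variant",
                                      if (fd_adjust) "mean_fd")))
      fits$age_both_networks <- f
      add_row("age", "age_both_networks", "index", "network:age_years", f,
              coef_term = NA_character_)
    }
  }

  if ("stage" %in% families) {
    sub <- tab[tab$group %in% suite_subsets$older, , drop = FALSE]
    base <- sub[sub$visit_index == 1, , drop = FALSE]
    for (net in c("at_index", "pm_index")) {
      f <- ancova_pairwise(base, net, "group",
                           c("age_years", "sex", "education_years",
                             if (fd_adjust) "mean_fd"))
      fits[[paste0("stage_baseline_", net)]] <- f
      add_row("stage", "stage_ancova", net, "group", f,
              coef_term = NA_character_)
      for (i in seq_len(nrow(f$contrasts))) {
        ctr <- f$contrasts[i, ]
        rows[[length(rows) + 1L]] <- data.frame(
          family = "stage", design = "stage_posthoc", outcome = net,
          term = as.character(ctr$contrast), estimate = ctr$estimate,
          ci_lo = NA_real_, ci_hi = NA_real_, F = NA_real_,
          df_num = NA_real_, df_den = ctr$df, p = ctr$p.value,
          p_holm = NA_real_, stringsAsFactors = FALSE)
      }
      fl <- fit_lmm(sub, model_spec(net, c("group*months_from_baseline",
                                           covars)))
      fits[[paste0("stage_long_", net)]] <- fl
      add_row("stage", "stage_time_by_group", net,
              "group:months_from_baseline", fl, coef_term = NA_character_)
    }
  }

  if ("associations" %in% families) {
    sub <- tab[tab$group %in% suite_subsets$older, , drop = FALSE]
    fam_idx <- integer()
    for (net in c("at_index", "pm_index")) {
      for (feat in names(assoc_features)) {
        col <- assoc_features[[feat]]
        if (!col %in% names(sub)) next
        f <- fit_lmm(sub, model_spec(net, c(col, "months_from_baseline",
                                            covars)))
        fits[[paste0("assoc_", net, "_", feat)]] <- f
        add_row("associations", paste0("assoc_", feat), net, col, f)
        fam_idx <- c(fam_idx, length(rows))
      }
    }
    if (length(fam_idx)) {
      ps <- vapply(rows[fam_idx], function(r) r$p, numeric(1))
      hb <- holm(ps, holm_alpha)
      for (i in seq_along(fam_idx)) rows[[fam_idx[i]]]$p_holm <- hb$adjusted[i]
    }
  }

  if ("converter" %in% families &&
      "months_to_dementia" %in% names(tab) &&
      any(!is.na(tab$months_to_dementia))) {
    sub <- tab[!is.na(tab$months_to_dementia), , drop = FALSE]
    for (net in c("at_index", "pm_index")) {
      f <- fit_lmm(sub, model_spec(net, c("months_to_dementia", covars)))
      fits[[paste0("converter_", net)]] <- f
      add_row("converter", "delay_to_onset", net, "months_to_dementia", f)
    }
  }

  if ("gam_ranked" %in% families) {
    base <- tab[tab$visit_index == 1, , drop = FALSE]
    base$group_rank <- rank_groups(base$group)
    if (length(unique(base$group_rank)) >= 3) {
      for (net in c("at_index", "pm_index")) {
        f <- fit_gam_ranked(base, net, "group_rank", k = 6)
        fits[[paste0("gam_", net)]] <- f
        rows[[length(rows) + 1L]] <- data.frame(
          family = "gam_ranked", design = "ranked_smooth", outcome = net,
          term = "s(group_rank)", estimate = f$edf, ci_lo = NA_real_,
          ci_hi = NA_real_, F = f$f_tests$F[1], df_num = f$f_tests$df_num[1],
          df_den = f$f_tests$df_den[1], p = f$f_tests$p[1], p_holm = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, fits = fits)
}
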