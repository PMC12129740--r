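#' Declare a mixed-model specification
#'
#' Uniform declarative contract for the longitudinal models: outcome,
#' ordered fixed-effect terms (interactions written `a:b` or `a*b`), a
#' by-subject random intercept, REML estimation, and the F-test type
#' (type III is required, and auto-selected, when an interaction is present;
#' type II otherwise).
#'
#' @param outcome outcome column name.
#' @param fixed_terms character vector of fixed-effect terms.
#' @param random_intercept_by grouping column for the random intercept.
#' @param ftest_type `"II"` or `"III"`; `NULL` auto-selects from the terms.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed_terms,
                       random_intercept_by = "subject_id",
                       ftest_type = NULL) {
  has_int <- any(grepl("[:*]", fixed_terms))
  if (is.null(ftest_type)) ftest_type <- if (has_int) "III" else "II"
  ftest_type <- match.arg(ftest_type, c("II", "III"))
  if (has_int && ftest_type != "III")
    stop("interaction terms require type III F-tests")
  structure(list(outcome = outcome, fixed_terms = fixed_terms,
                 random_intercept_by = random_intercept_by,
                 estimation = "REML", ftest_type = ftest_type),
            class = "model_spec")
}

vars_in_terms <- function(terms) unique(unlist(strsplit(terms, "[:*]")))

new_model_fit <- function(coefficients, f_tests, n_subjects, n_obs,
                          converged = TRUE, degenerate = FALSE, edf = NULL,
                          fit = NULL, emmeans = NULL, contrasts = NULL) {
  structure(list(coefficients = coefficients, f_tests = f_tests,
                 n_subjects = n_subjects, n_observations = n_obs,
                 converged = converged, degenerate = degenerate, edf = edf,
                 fit = fit, emmeans = emmeans, contrasts = contrasts),
            class = "model_fit")
}

#' @method print model_fit
#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: %d subjects, %d observations%s%s>\n",
              x$n_subjects, x$n_observations,
              if (!x$converged) ", NOT converged" else "",
              if (x$degenerate) ", degenerate" else ""))
  print(x$coefficients, digits = 4)
  if (!is.null(x$f_tests) && nrow(x$f_tests)) {
    cat("F-tests:\n"); print(x$f_tests, digits = 4)
  }
  invisible(x)
}

#' Fit a linear mixed model with by-subject random intercepts
#'
#' REML fit (via \pkg{lmerTest}) of `outcome ~ fixed terms + (1 | subject)`,
#' with 95% confidence intervals from the Satterthwaite-df t distribution and
#' type II/III F-tests with Satterthwaite denominator degrees of freedom.
#' Type III tests use sum-to-zero contrasts for factors.  Rows with missing
#' values in any used column are dropped.  A constant outcome yields a
#' degenerate flagged fit (all slopes 0) rather than an error; convergence
#' or singularity problems are flagged, not silenced.
#'
#' @param table long-format cohort data.frame.
#' @param spec a [model_spec()].
#' @return A `model_fit`: `coefficients` (term, estimate, se, df, ci_lo,
#'   ci_hi, t, p), `f_tests` (term, F, df_num, df_den, p), counts and flags.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(spec$outcome, vars_in_terms(spec$fixed_terms),
            spec$random_intercept_by)
  miss <- setdiff(used, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dat <- table[complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  if (length(unique(dat[[spec$random_intercept_by]])) < 2L)
    stop("need at least 2 subjects")
  for (v in names(dat)) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  if (spec$ftest_type == "III") {
    for (v in names(dat))
      if (is.factor(dat[[v]]) && v != spec$random_intercept_by)
        stats::contrasts(dat[[v]]) <- stats::contr.sum(nlevels(dat[[v]]))
  }
  n_subj <- length(unique(dat[[spec$random_intercept_by]]))

  if (stats::sd(dat[[spec$outcome]]) == 0) {
    co <- data.frame(term = c("(Intercept)", spec$fixed_terms),
                     estimate = c(dat[[spec$outcome]][1],
                                  rep(0, length(spec$fixed_terms))),
                     se = 0, df = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    return(new_model_fit(co, NULL, n_subj, nrow(dat), converged = TRUE,
                         degenerate = TRUE))
  }

  fml <- as.formula(paste(spec$outcome, "~",
                          paste(spec$fixed_terms, collapse = " + "),
                          "+ (1 |", spec$random_intercept_by, ")"))
  converged <- TRUE
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = dat, REML = TRUE, control = ctrl),
    warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (lme4::isSingular(fit, tol = 1e-5)) converged <- converged  # singular fits
  # are retained (random-intercept variance at 0 is legitimate, e.g. one
  # observation per subject) but exposed via lme4 diagnostics on $fit

  sc <- stats::coef(summary(fit))  # Estimate, SE, df (Satterthwaite), t, p
  df <- sc[, "df"]
  co <- data.frame(term = rownames(sc), estimate = sc[, "Estimate"],
                   se = sc[, "Std. Error"], df = df,
                   ci_lo = sc[, "Estimate"] - qt(0.975, df) * sc[, "Std. Error"],
                   ci_hi = sc[, "Estimate"] + qt(0.975, df) * sc[, "Std. Error"],
                   t = sc[, "t value"], p = sc[, "Pr(>|t|)"],
                   stringsAsFactors = FALSE, row.names = NULL)
  ft <- suppressMessages(stats::anova(
    fit, type = if (spec$ftest_type == "III") 3 else 2, ddf = "Satterthwaite"))
  f_tests <- data.frame(term = rownames(ft), F = ft[, "F value"],
                        df_num = ft[, "NumDF"], df_den = ft[, "DenDF"],
                        p = ft[, "Pr(>F)"], stringsAsFactors = FALSE,
                        row.names = NULL)
  new_model_fit(co, f_tests, n_subj, nrow(dat), converged = converged,
                fit = fit)
}

#' Rank Alzheimer's-continuum groups
#'
#' Orders the six cohort groups along the continuum — young, middle-aged,
#' older amyloid-negative, older amyloid-positive, MCI, AD-dementia — and
#' codes them 1 to 6.
#'
#' @param labels character vector of group labels.
#' @return Integer vector of ranks (order-free: permuting input rows never
#'   changes a label's code).
#' @export
rank_groups <- function(labels) {
  bad <- setdiff(unique(labels), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  r <- match(labels, GROUP_LEVELS)
  if (length(labels) > 1L && length(unique(labels)) == 1L)
    warning("all group labels identical; rank column is constant")
  r
}

#' Ranked-group additive model at baseline
#'
#' Penalized-spline smooth of the outcome on the group rank (basis dimension
#' `k`, default 6), fitted by REML with \pkg{mgcv}.  A linear truth yields an
#' effective degrees of freedom (edf) near 1.  `k` is reduced (with a
#' warning) when fewer distinct ranks than `k` are available.
#'
#' @param table baseline cohort rows.
#' @param outcome outcome column name.
#' @param rank_column ordinal group-rank column (see [rank_groups()]).
#' @param k smooth basis dimension.
#' @param covariates optional additional linear covariate columns.
#' @return A `model_fit` with `edf` set.
#' @export
fit_gam_ranked <- function(table, outcome, rank_column = "group_rank", k = 6,
                           covariates = NULL) {
  used <- c(outcome, rank_column, covariates)
  miss <- setdiff(used, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dat <- table[complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  for (v in names(dat)) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  nr <- length(unique(dat[[rank_column]]))
  if (nr < 3L) stop("need at least 3 distinct rank values for a smooth")
  if (nr < k) {
    warning("reducing basis dimension k from ", k, " to ", nr,
            " (distinct ranks)")
    k <- nr
  }
  fml <- as.formula(paste(outcome, "~ s(", rank_column, ", k =", k, ")",
                          if (length(covariates))
                            paste("+", paste(covariates, collapse = " + "))
                          else ""))
  fit <- mgcv::gam(fml, data = dat, method = "REML")
  s <- summary(fit)
  co <- data.frame(term = rownames(s$p.table), estimate = s$p.table[, 1],
                   se = s$p.table[, 2], df = NA_real_,
                   ci_lo = s$p.table[, 1] - 1.96 * s$p.table[, 2],
                   ci_hi = s$p.table[, 1] + 1.96 * s$p.table[, 2],
                   t = s$p.table[, 3], p = s$p.table[, 4],
                   stringsAsFactors = FALSE, row.names = NULL)
  ft <- data.frame(term = rownames(s$s.table), F = s$s.table[, "F"],
                   df_num = s$s.table[, "edf"], df_den = s$residual.df,
                   p = s$s.table[, "p-value"], stringsAsFactors = FALSE,
                   row.names = NULL)
  new_model_fit(co, ft, n_subjects = nrow(dat), n_obs = nrow(dat),
                edf = unname(sum(s$edf)), fit = fit)
}

#' Baseline ANCOVA with pairwise estimated-marginal-mean contrasts
#'
#' Cross-sectional covariate-adjusted group comparison: a linear model of the
#' outcome on group plus covariates, group means estimated at the covariate
#' means (\pkg{emmeans}), and all pairwise contrasts as independent t-tests
#' with unadjusted p-values (matching the post hoc reporting convention).
#'
#' @param table baseline rows (one per subject).
#' @param outcome,group,covariates column names.
#' @return A `model_fit` whose `emmeans` and `contrasts` elements hold the
#'   adjusted means and pairwise tests; `f_tests` holds the group F-test.
#' @export
ancova_pairwise <- function(table, outcome, group = "group",
                            covariates = c("age_years", "sex",
                                           "education_years")) {
  used <- c(outcome, group, covariates)
  miss <- setdiff(used, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  dat <- table[complete.cases(table[, used, drop = FALSE]), used, drop = FALSE]
  for (v in names(dat)) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  tab <- table(dat[[group]])
  if (sum(tab >= 2) < 2) stop("need >= 2 groups with >= 2 members")
  fml <- as.formula(paste(outcome, "~", group, "+",
                          paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = dat)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop("singular design; aliased terms: ",
         paste(rownames(al), collapse = ", "))
  aov_tab <- stats::anova(fit)
  gi <- match(group, rownames(aov_tab))
  f_tests <- data.frame(term = group, F = aov_tab[gi, "F value"],
                        df_num = aov_tab[gi, "Df"],
                        df_den = aov_tab["Residuals", "Df"],
                        p = aov_tab[gi, "Pr(>F)"], stringsAsFactors = FALSE)
  emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", group)))
  ctr <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  sc <- stats::coef(summary(fit))
  co <- data.frame(term = rownames(sc), estimate = sc[, 1], se = sc[, 2],
                   df = fit$df.residual,
                   ci_lo = sc[, 1] - qt(0.975, fit$df.residual) * sc[, 2],
                   ci_hi = sc[, 1] + qt(0.975, fit$df.residual) * sc[, 2],
                   t = sc[, 3], p = sc[, 4], stringsAsFactors = FALSE,
                   row.names = NULL)
  new_model_fit(co, f_tests, n_subjects = nrow(dat), n_obs = nrow(dat),
                fit = fit, emmeans = as.data.frame(emm), contrasts = ctr)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values via the step-down procedure
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j))` (delegated to
#' [stats::p.adjust()]), with rejection flags at `alpha`, returned in input
#' order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise error level.
#' @return List: `adjusted` (same order as input), `reject` (logical).
#' @export
holm <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = !is.na(adj) & adj < alpha)
}
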