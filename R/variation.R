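#' Fit a random-intercept logistic regression
#'
#' Maximum-likelihood fit of
#' \deqn{\mathrm{logit}\, P(y_{ig}=1) = x_{ig}'\beta + b_g, \quad
#'       b_g \sim N(0, \sigma_b^2)}
#' for a binary outcome clustered in groups (here: patients within GPs),
#' by Laplace approximation (default) or adaptive Gauss-Hermite quadrature.
#' Rows with any missing outcome or covariate are removed first (listwise
#' deletion). Predicted per-cluster intercepts are the conditional modes of
#' \eqn{b_g} at the ML estimates.
#'
#' @param data Data frame containing the outcome, covariates and cluster id.
#' @param outcome Name of the binary (logical/0-1) outcome column.
#' @param fixed_effects Character vector of covariate column names (may be
#'   empty for an intercept-only model). Covariates that are constant after
#'   listwise deletion are dropped with a message.
#' @param cluster Name of the cluster id column.
#' @param nagq Number of adaptive Gauss-Hermite nodes; 1 = Laplace.
#' @return Object of class `fitted_cluster_model`: `beta` (log-odds scale),
#'   `beta_cov`, `sigma2_b`, `intercepts` (named per-cluster conditional
#'   modes), `loglik`, `n_obs`, `n_clusters`, `dropped_covariates`, and the
#'   underlying `lme4` fit as `fit`.
#' @export
fit_random_intercept_logistic <- function(data, outcome, fixed_effects = character(),
                                          cluster = "gp_id", nagq = 1L) {
  cols <- c(outcome, fixed_effects, cluster)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort_ckdqi("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (!nrow(d)) abort_ckdqi("no complete rows after listwise deletion")
  y <- d[[outcome]]
  if (is.logical(y)) d[[outcome]] <- as.integer(y)
  if (!all(d[[outcome]] %in% c(0L, 1L))) abort_ckdqi("outcome must be binary")
  if (length(unique(d[[cluster]])) < 2L) {
    abort_ckdqi("at least 2 clusters are required")
  }
  dropped <- character()
  for (v in fixed_effects) {
    if (length(unique(d[[v]])) < 2L) dropped <- c(dropped, v)
  }
  fixed_effects <- setdiff(fixed_effects, dropped)
  rhs <- paste(c(if (length(fixed_effects)) fixed_effects else "1",
                 sprintf("(1 | %s)", cluster)), collapse = " + ")
  form <- as.formula(paste(outcome, "~", rhs))
  fit <- tryCatch(
    lme4::glmer(form, data = d, family = binomial(), nAGQ = nagq,
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
    error = function(e) abort_ckdqi("mixed-model fit failed: %s",
                                    conditionMessage(e))
  )
  vc <- lme4::VarCorr(fit)
  sigma2_b <- as.numeric(vc[[cluster]][1, 1])
  re <- lme4::ranef(fit)[[cluster]]
  intercepts <- setNames(re[["(Intercept)"]], rownames(re))
  structure(list(
    beta = lme4::fixef(fit),
    beta_cov = as.matrix(stats::vcov(fit)),
    sigma2_b = sigma2_b,
    intercepts = intercepts,
    loglik = as.numeric(logLik(fit)),
    n_obs = nrow(d),
    n_clusters = length(intercepts),
    dropped_covariates = dropped,
    nagq = nagq,
    fit = fit
  ), class = "fitted_cluster_model")
}

#' @export
print.fitted_cluster_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_cluster_model> %d obs in %d clusters; sigma2_b = %.4f, logLik = %.2f\n",
    x$n_obs, x$n_clusters, x$sigma2_b, x$loglik))
  print(round(x$beta, 4))
  invisible(x)
}

#' Odds ratios with Wald 95% confidence intervals
#'
#' @param model A `fitted_cluster_model`.
#' @return Tibble `term`, `or`, `ci_low`, `ci_high` (ORs are `exp(beta)`;
#'   CIs use `exp(beta +/- 1.959964 * SE)`).
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "fitted_cluster_model"))
  se <- sqrt(diag(model$beta_cov))
  z <- qnorm(0.975)
  tibble::tibble(
    term = names(model$beta),
    or = exp(unname(model$beta)),
    ci_low = exp(unname(model$beta) - z * se),
    ci_high = exp(unname(model$beta) + z * se)
  )
}

#' Latent-scale intraclass correlation for logistic models
#'
#' Under the latent-response formulation of the random-intercept logistic
#' model the residual variance is \eqn{\pi^2/3}, so the share of latent
#' outcome variance attributable to the cluster is
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \pi^2/3)}.
#'
#' @param sigma2_b Random-intercept variance (>= 0).
#' @return The ICC in `[0, 1)`.
#' @export
icc_latent <- function(sigma2_b) {
  if (any(!is.finite(sigma2_b)) || any(sigma2_b < 0)) {
    abort_ckdqi("sigma2_b must be non-negative")
  }
  sigma2_b / (sigma2_b + pi^2 / 3)
}

#' Range odds ratio over the central 90% of cluster intercepts
#'
#' \eqn{rOR = e^{q_{95} - q_{05}}} where \eqn{q_{05}} and \eqn{q_{95}} are
#' the empirical 5th and 95th percentiles of the predicted cluster
#' intercepts (linear interpolation between order statistics). Using the
#' central 90% rather than the full range reduces the influence of outlier
#' clusters; the result is the odds multiplier between a 95th- and a
#' 5th-percentile cluster and is >= 1 by construction.
#'
#' @param intercepts Numeric vector of predicted cluster intercepts
#'   (length >= 2).
#' @return The range odds ratio.
#' @export
range_or <- function(intercepts) {
  intercepts <- intercepts[!is.na(intercepts)]
  if (length(intercepts) < 2L) abort_ckdqi("need at least 2 cluster intercepts")
  q <- quantile(intercepts, c(0.05, 0.95), names = FALSE, type = 7)
  exp(q[2] - q[1])
}

#' Model-row table for one quality indicator
#'
#' Joins a QI's per-patient achievement flags (denominator members only)
#' with patient- and GP-level covariates, recoding them as the modelling
#' factors: patient gender (female reference; "other" gender excluded from
#' model rows), patient age category at index, condition flags, GP gender,
#' GP age category and practice urbanity.
#'
#' @param qi_result A `qi_result`.
#' @param covariates Tibble from [build_covariate_table()].
#' @return Tibble of model rows with column `achieved` and covariates.
#' @export
model_rows <- function(qi_result, covariates) {
  stopifnot(inherits(qi_result, "qi_result"))
  flags <- qi_result$flags
  rows <- flags[flags$in_denominator, c("patient_id", "gp_id", "achieved")]
  rows <- dplyr::left_join(rows, covariates, by = "patient_id")
  rows <- rows[is.na(rows$patient_gender) |
                 rows$patient_gender != "other", ]
  rows$patient_gender <- factor(rows$patient_gender,
                                levels = c("female", "male"))
  rows
}

PATIENT_FIXED <- c("patient_gender", "patient_age_cat", "has_diabetes",
                   "has_hypertension", "has_ecvd")
GP_FIXED <- c("gp_gender", "gp_age_cat", "urban_location")

#' Analyse GP-level variation in one quality indicator
#'
#' Fits two random-intercept logistic models for indicator achievement:
#' the full model (patient and GP fixed effects) from which odds ratios are
#' reported, and the null model (GP-level fixed effects omitted so that GP
#' influence loads entirely on the random intercept) from which the
#' latent-scale ICC and the range odds ratio are computed.
#'
#' @param qi_result A `qi_result`.
#' @param covariates Tibble from [build_covariate_table()].
#' @param nagq Quadrature nodes passed to
#'   [fit_random_intercept_logistic()].
#' @return Object of class `variation_summary`: `qi_id`,
#'   `achievement_rate`, `or_table` (full model), `icc`, `ror` (null
#'   model), `sigma2_b_null`, and both fitted models.
#' @export
analyse_qi_variation <- function(qi_result, covariates, nagq = 1L) {
  rows <- model_rows(qi_result, covariates)
  if (!nrow(rows)) abort_ckdqi("empty denominator for QI %d", qi_result$qi_id)
  fixed_full <- intersect(c(PATIENT_FIXED, GP_FIXED), names(rows))
  fixed_null <- intersect(PATIENT_FIXED, names(rows))
  full <- fit_random_intercept_logistic(rows, "achieved", fixed_full,
                                        cluster = "gp_id", nagq = nagq)
  null <- fit_random_intercept_logistic(rows, "achieved", fixed_null,
                                        cluster = "gp_id", nagq = nagq)
  structure(list(
    qi_id = qi_result$qi_id,
    achievement_rate = qi_result$achievement_rate,
    or_table = odds_ratios(full),
    icc = icc_latent(null$sigma2_b),
    ror = range_or(null$intercepts),
    sigma2_b_null = null$sigma2_b,
    full_model = full,
    null_model = null
  ), class = "variation_summary")
}

#' @export
print.variation_summary <- function(x, ...) {
  cat(sprintf("<variation_summary> QI %d: rate %.1f%%, rOR %.1f, ICC %.2f\n",
              x$qi_id, x$achievement_rate, x$ror, x$icc))
  invisible(x)
}

#' Assemble the patient/GP covariate table used by the variation models
#'
#' @param dataset An `emr_dataset`.
#' @param cohort A cohort tibble ([build_rf_cohort()] or
#'   [build_ckd_cohort()]) supplying index dates and condition flags.
#' @param patient_age_breaks Left-closed cut points for the patient age
#'   category at index (default `c(65, 80)` giving `<65`, `65-79`, `>=80`).
#' @param gp_age_breaks Cut points for GP age at the study window start
#'   (default `c(45, 60)`).
#' @return Tibble keyed by `patient_id` with the modelling covariates.
#' @export
build_covariate_table <- function(dataset, cohort,
                                  patient_age_breaks = c(65, 80),
                                  gp_age_breaks = c(45, 60)) {
  pat <- dataset$patients
  gp <- dataset$gps
  out <- cohort[c("patient_id", "gp_id", "index_date")]
  out <- dplyr::left_join(out, pat[c("patient_id", "gender", "birth_year")],
                          by = "patient_id")
  age <- age_at(out$birth_year, out$index_date)
  out$patient_age_cat <- cut(age, breaks = c(-Inf, patient_age_breaks, Inf),
                             right = FALSE)
  out$patient_gender <- out$gender
  gp_age <- age_at(gp$birth_year, dataset$study_window[1])
  gp_tab <- tibble::tibble(
    gp_id = gp$gp_id,
    gp_gender = ifelse(gp$gender %in% c("female", "male"), gp$gender,
                       NA_character_),
    gp_age_cat = cut(gp_age, breaks = c(-Inf, gp_age_breaks, Inf),
                     right = FALSE),
    urban_location = gp$urban_location
  )
  gp_tab$gp_gender <- factor(gp_tab$gp_gender, levels = c("female", "male"))
  out <- dplyr::left_join(out, gp_tab, by = "gp_id")
  cond_cols <- intersect(c("has_diabetes", "has_hypertension", "has_ecvd"),
                         names(cohort))
  if (length(cond_cols)) {
    out <- dplyr::left_join(out, cohort[c("patient_id", cond_cols)],
                            by = "patient_id")
  }
  out[c("patient_id", "patient_gender", "patient_age_cat", cond_cols,
        "gp_gender", "gp_age_cat", "urban_location")]
}
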