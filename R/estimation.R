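#' Covariate sets for the adjusted models
#'
#' The full adjustment set contains sociodemographic characteristics (age,
#' gender, education, city size, living situation), depression risk factors
#' (depression history, pregnancy, breastfeeding), baseline EQ-5D-5L index
#' and PHQ-9 score, and baseline healthcare service use (in-patient days,
#' GP visits, number of medications, sick-leave days). The payer-perspective
#' scenario drops baseline sick-leave days. Subgroup analyses drop
#' pregnancy, breastfeeding and living situation (too few observations per
#' stratum) and use a binarised city-size variable.
#'
#' @param perspective `"societal"` or `"payer"`.
#' @param subgroup logical; reduced subgroup covariate set?
#' @return character vector of model terms.
#' @export
model_covariates <- function(perspective = "societal", subgroup = FALSE) {
  covs <- c("age", "gender", "education_ge10y", "city_size",
            "living_situation", "eq5d_T0", "phq9_T0", "depression_history",
            "pregnancy", "breastfeeding", "bl_inpatient_days",
            "bl_gp_visits", "bl_medication_count", "bl_sick_days")
  if (perspective == "payer") covs <- setdiff(covs, "bl_sick_days")
  if (subgroup) {
    covs <- setdiff(covs, c("pregnancy", "breastfeeding",
                            "living_situation", "city_size"))
    covs <- c(covs, "city_binary")
  }
  covs
}

# drop covariate terms that are constant (or empty-level factors) in df;
# keeps mixed-model design matrices full rank in small subgroups
.prune_covariates <- function(df, covariates) {
  keep <- vapply(covariates, function(v) {
    x <- df[[v]]
    if (is.factor(x)) x <- droplevels(x)
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1L))
  covariates[keep]
}

.arm_terms <- c("armgp", "armgp_plus_patient")

.fit_terms <- function(coefs, ses, dfres) {
  terms <- intersect(.arm_terms, names(coefs))
  est <- coefs[terms]; se <- ses[terms]
  data.frame(term = terms, estimate = unname(est), se = unname(se),
             df = dfres,
             p = 2 * stats::pt(abs(est / se), dfres, lower.tail = FALSE),
             row.names = NULL)
}

#' Linear mixed model for effect outcomes (QALYs, DFDs, net benefit)
#'
#' REML fit with random intercepts for general practices nested in study
#' centres; fixed effects are the two intervention-arm contrasts against the
#' no-feedback reference plus the adjustment covariates. Wald tests use a
#' residual degrees-of-freedom approximation (n minus number of fixed
#' effects), declared in the result metadata.
#'
#' @param df completed analysis table with the outcome column.
#' @param outcome outcome column name.
#' @param covariates character vector of covariate terms (pruned of
#'   constant columns automatically).
#' @param reml logical, REML (default) or ML.
#' @return object of class `fit_result` with elements `terms` (data.frame:
#'   term, estimate, se, df, p), `family`, `method`, `converged`,
#'   `varcomp`.
#' @export
fit_effect_model <- function(df, outcome, covariates = model_covariates(),
                             reml = TRUE) {
  covariates <- .prune_covariates(df, covariates)
  fml <- stats::as.formula(paste(
    outcome, "~ arm +", paste(c(covariates, "(1 | centre_id / practice_id)"),
                              collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- names(cf)
  dfres <- nrow(df) - length(cf)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(terms = .fit_terms(cf, se, dfres), family = "linear",
                 method = "lmm-reml",
                 converged = TRUE,
                 singular = lme4::isSingular(fit),
                 varcomp = vc[, c("grp", "vcov")],
                 df_method = "residual (n - p)"),
            class = "fit_result")
}

#' Gamma log-link mixed model for cost aggregates
#'
#' Generalised linear mixed model with a gamma distribution and log link,
#' random intercepts for practices nested in centres. Zero cost totals are
#' shifted to `zero_offset` Euro (gamma support excludes zero); the number
#' of affected rows is recorded. If the mixed-model optimiser fails, the
#' documented fallback is a gamma GLM with practice-clustered (sandwich)
#' standard errors, tagged in `method`.
#'
#' @inheritParams fit_effect_model
#' @param zero_offset Euro value replacing exact zeros.
#' @return `fit_result`; `terms$estimate` is on the log scale, with
#'   `ratio` columns giving the exponentiated arm cost ratio.
#' @export
fit_cost_model <- function(df, outcome, covariates = model_covariates(),
                           zero_offset = 0.5) {
  covariates <- .prune_covariates(df, covariates)
  y <- df[[outcome]]
  if (any(y < 0)) stop("cost outcome must be non-negative")
  nzero <- sum(y == 0)
  df$.y <- ifelse(y == 0, zero_offset, y)
  fml <- stats::as.formula(paste(
    ".y ~ arm +", paste(c(covariates, "(1 | centre_id / practice_id)"),
                        collapse = " + ")))
  fit <- tryCatch(suppressMessages(suppressWarnings(
    glmmTMB::glmmTMB(fml, data = df, family = Gamma(link = "log")))),
    error = function(e) NULL)
  ok <- !is.null(fit) && isTRUE(fit$sdr$pdHess) &&
    all(is.finite(sqrt(diag(stats::vcov(fit)$cond))))
  if (ok) {
    cf <- glmmTMB::fixef(fit)$cond
    se <- sqrt(diag(stats::vcov(fit)$cond))
    method <- "gamma-glmm"
    vc <- tryCatch({
      v <- glmmTMB::VarCorr(fit)$cond
      data.frame(grp = names(v),
                 vcov = vapply(v, function(x) x[1L], numeric(1L)))
    }, error = function(e) NULL)
  } else {
    fml2 <- stats::reformulate(c("arm", covariates), response = ".y")
    fit <- stats::glm(fml2, data = df, family = Gamma(link = "log"))
    V <- sandwich::vcovCL(fit, cluster = df$practice_id)
    cf <- stats::coef(fit)
    se <- sqrt(diag(V))
    method <- "gamma-glm-clustered"
    vc <- NULL
  }
  dfres <- nrow(df) - length(cf)
  terms <- .fit_terms(cf, se, dfres)
  terms$ratio <- exp(terms$estimate)
  structure(list(terms = terms, family = "gamma-log", method = method,
                 converged = all(is.finite(terms$se)) && all(terms$se > 0),
                 n_zero_shifted = nzero, varcomp = vc,
                 df_method = "residual (n - p)"),
            class = "fit_result")
}

#' Two-part (zero-inflated gamma) model for single cost categories
#'
#' Occurrence (any cost) is modelled by a logistic mixed model and the
#' positive-cost intensity by a gamma log-link mixed model, both with
#' practices nested in centres. The marginal arm effect on the log mean,
#' `log[(p_arm * mu_arm) / (p_ref * mu_ref)]`, combines both parts with a
#' delta-method standard error; occurrence probabilities are evaluated at
#' the average observed linear predictor of the reference arm.
#'
#' @inheritParams fit_effect_model
#' @return `fit_result` with `parts` holding the occurrence and intensity
#'   fits; `terms` carries the marginal log-ratio per arm contrast.
#' @export
fit_zi_cost_model <- function(df, outcome, covariates = model_covariates()) {
  covariates <- .prune_covariates(df, covariates)
  y <- df[[outcome]]
  if (any(y < 0)) stop("cost outcome must be non-negative")
  df$.pos <- as.numeric(y > 0)
  pos_by_arm <- tapply(df$.pos, df$arm, mean)
  separation <- any(pos_by_arm %in% c(0, 1))
  if (all(y > 0)) {
    fit <- fit_cost_model(df, outcome, covariates)
    fit$family <- "zero-inflated-gamma-log"
    fit$note <- "no zeros: collapses to the gamma model"
    return(fit)
  }

  occ_fml <- stats::as.formula(paste(
    ".pos ~ arm +", paste(c(covariates, "(1 | centre_id / practice_id)"),
                          collapse = " + ")))
  occ <- tryCatch(suppressMessages(suppressWarnings(
    glmmTMB::glmmTMB(occ_fml, data = df, family = stats::binomial()))),
    error = function(e) NULL)
  occ_ok <- !is.null(occ) && isTRUE(occ$sdr$pdHess) &&
    all(is.finite(diag(as.matrix(stats::vcov(occ)$cond))))
  if (!occ_ok) {
    occ <- stats::glm(stats::reformulate(c("arm", covariates),
                                         response = ".pos"),
                      data = df, family = stats::binomial())
    Vocc <- sandwich::vcovCL(occ, cluster = df$practice_id)
    cf_occ <- stats::coef(occ)
    eta_occ <- stats::predict(occ, type = "link")
  } else {
    Vocc <- as.matrix(stats::vcov(occ)$cond)
    cf_occ <- glmmTMB::fixef(occ)$cond
    eta_occ <- stats::predict(occ, type = "link")
  }

  dpos <- df[y > 0, , drop = FALSE]
  int <- fit_cost_model(dpos, outcome,
                        .prune_covariates(dpos, covariates))

  # marginal log ratio: delta method around the reference-arm mean linear
  # predictor eta0 of the occurrence part
  ref_rows <- df$arm == "none"
  eta0 <- mean(eta_occ[ref_rows])
  terms <- int$terms
  for (i in seq_len(nrow(terms))) {
    tm <- terms$term[i]
    b_occ <- cf_occ[[tm]]
    v_occ <- Vocc[tm, tm]
    p0 <- stats::plogis(eta0)
    p1 <- stats::plogis(eta0 + b_occ)
    grad <- 1 - p1  # d log p1 / d b_occ
    terms$estimate[i] <- log(p1 / p0) + terms$estimate[i]
    terms$se[i] <- sqrt(terms$se[i]^2 + grad^2 * v_occ)
    terms$p[i] <- 2 * stats::pt(abs(terms$estimate[i] / terms$se[i]),
                                terms$df[i], lower.tail = FALSE)
  }
  terms$ratio <- exp(terms$estimate)
  structure(list(terms = terms, family = "zero-inflated-gamma-log",
                 method = paste0(if (occ_ok) "logistic-glmm" else
                   "logistic-glm-clustered", " + ", int$method),
                 converged = all(is.finite(terms$se)) && all(terms$se > 0),
                 separation_warning = separation,
                 parts = list(occurrence = list(coef = cf_occ, vcov = Vocc),
                              intensity = int),
                 df_method = "residual (n - p)"),
            class = "fit_result")
}

#' Pool fits across imputations with Rubin's rules
#'
#' Pools each arm contrast over M fits: pooled estimate is the mean of the
#' per-imputation estimates; total variance is the within-imputation
#' variance plus (1 + 1/M) times the between-imputation variance. Degrees
#' of freedom follow the Barnard-Rubin small-sample adjustment; confidence
#' intervals and two-sided p-values use the t reference.
#'
#' @param fits list of `fit_result` objects from the same model
#'   specification on M imputed datasets.
#' @param conf_level confidence level.
#' @return data.frame of class `pooled_estimate`: one row per arm contrast
#'   with `estimate`, `within`, `between`, `total_var`, `se`, `df`, `p`,
#'   `ci_low`, `ci_high` (plus `ratio` columns for log-scale families).
#' @export
rubin_pool <- function(fits, conf_level = 0.95) {
  stopifnot(length(fits) >= 1L)
  usable <- vapply(fits, function(f)
    isTRUE(f$converged) && all(is.finite(f$terms$se)) &&
      all(f$terms$se > 0), logical(1L))
  if (!all(usable)) {
    if (!any(usable)) stop("no converged fits to pool")
    warning(sum(!usable), " non-converged fit(s) excluded from pooling")
    fits <- fits[usable]
  }
  fam <- unique(vapply(fits, `[[`, character(1L), "family"))
  if (length(fam) != 1L)
    stop("cannot pool fits with heterogeneous specifications")
  terms <- fits[[1L]]$terms$term
  if (!all(vapply(fits, function(f)
    identical(f$terms$term, terms), logical(1L))))
    stop("cannot pool fits with heterogeneous specifications")
  M <- length(fits)
  out <- lapply(terms, function(tm) {
    est <- vapply(fits, function(f)
      f$terms$estimate[f$terms$term == tm], numeric(1L))
    se <- vapply(fits, function(f)
      f$terms$se[f$terms$term == tm], numeric(1L))
    nu_com <- mean(vapply(fits, function(f)
      f$terms$df[f$terms$term == tm], numeric(1L)))
    qbar <- mean(est)
    wbar <- mean(se^2)
    b <- if (M > 1L) stats::var(est) else 0
    total <- wbar + (1 + 1 / M) * b
    if (M > 1L && b > 0) {
      lam <- (1 + 1 / M) * b / total
      df_old <- (M - 1) / lam^2
      df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lam)
      dfree <- 1 / (1 / df_old + 1 / df_obs)
    } else {
      dfree <- nu_com
    }
    se_p <- sqrt(total)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfree)
    data.frame(term = tm, estimate = qbar, within = wbar, between = b,
               total_var = total, se = se_p, df = dfree,
               p = 2 * stats::pt(abs(qbar / se_p), dfree,
                                 lower.tail = FALSE),
               ci_low = qbar - tcrit * se_p, ci_high = qbar + tcrit * se_p)
  })
  out <- do.call(rbind, out)
  if (fam %in% c("gamma-log", "zero-inflated-gamma-log")) {
    out$ratio <- exp(out$estimate)
    out$ratio_ci_low <- exp(out$ci_low)
    out$ratio_ci_high <- exp(out$ci_high)
  }
  attr(out, "family") <- fam
  attr(out, "M") <- M
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

#' Baseline balance diagnostics between study arms
#'
#' Regresses each baseline variable on the arm indicators: ordinary least
#' squares for continuous variables, binary logistic regression for binary
#' variables and multinomial logistic regression for categorical variables
#' with more than two levels. P-values are reported for each intervention
#' arm against the no-feedback reference.
#'
#' @param tab analysis table (baseline columns observed).
#' @return data.frame: variable, model type, p-value per intervention arm.
#' @export
baseline_balance <- function(tab) {
  continuous <- c("age", "bl_inpatient_days", "bl_medication_count",
                  "bl_gp_visits", "bl_sick_days", "eq5d_T0", "phq9_T0")
  binary <- c("insurance_plan", "education_ge10y", "native_speaker",
              "smoker", "depression_history", "addiction")
  categorical <- c("gender", "city_size", "living_situation")
  rows <- list()
  for (v in continuous) {
    fit <- stats::lm(stats::reformulate("arm", response = v), data = tab)
    cf <- summary(fit)$coefficients
    rows[[v]] <- data.frame(variable = v, model = "ols",
                            p_gp = cf[.arm_terms[1L], 4L],
                            p_gp_plus_patient = cf[.arm_terms[2L], 4L])
  }
  for (v in binary) {
    if (length(unique(tab[[v]])) < 2L) {
      rows[[v]] <- data.frame(variable = v, model = "logistic",
                              p_gp = NA_real_, p_gp_plus_patient = NA_real_)
      next
    }
    fit <- stats::glm(stats::reformulate("arm", response = v), data = tab,
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    rows[[v]] <- data.frame(variable = v, model = "logistic",
                            p_gp = cf[.arm_terms[1L], 4L],
                            p_gp_plus_patient = cf[.arm_terms[2L], 4L])
  }
  for (v in categorical) {
    x <- droplevels(factor(tab[[v]]))
    if (nlevels(x) < 2L) {
      rows[[v]] <- data.frame(variable = v, model = "multinomial",
                              p_gp = NA_real_, p_gp_plus_patient = NA_real_)
      next
    }
    if (nlevels(x) == 2L) {
      fit <- stats::glm(x ~ arm, data = tab, family = stats::binomial())
      cf <- summary(fit)$coefficients
      rows[[v]] <- data.frame(variable = v, model = "logistic",
                              p_gp = cf[.arm_terms[1L], 4L],
                              p_gp_plus_patient = cf[.arm_terms[2L], 4L])
      next
    }
    fit <- nnet::multinom(x ~ arm, data = tab, trace = FALSE)
    cf <- summary(fit)$coefficients
    se <- summary(fit)$standard.errors
    # joint Wald test per arm contrast across the outcome equations
    pvals <- vapply(.arm_terms, function(tm) {
      zet <- cf[, tm] / se[, tm]
      stats::pchisq(sum(zet^2), df = length(zet), lower.tail = FALSE)
    }, numeric(1L))
    rows[[v]] <- data.frame(variable = v, model = "multinomial",
                            p_gp = pvals[1L],
                            p_gp_plus_patient = pvals[2L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
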