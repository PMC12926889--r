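#' Willingness-to-pay grid
#'
#' Default grids: EUR 0 to 160,000 per QALY in 10,000 steps (17 points) and
#' EUR 0 to 200 per depression-free day in steps of 20 (11 points).
#'
#' @param effect `"QALY"` or `"DFD"`.
#' @param lambda optional custom strictly increasing grid.
#' @return list with `lambda` and `effect`.
#' @export
wtp_grid <- function(effect = c("QALY", "DFD"), lambda = NULL) {
  effect <- match.arg(effect)
  if (is.null(lambda))
    lambda <- if (effect == "QALY") seq(0, 160000, by = 10000) else
      seq(0, 200, by = 20)
  if (length(lambda) == 0L) stop("WTP grid must not be empty")
  if (any(diff(lambda) <= 0)) stop("WTP grid must be strictly increasing")
  list(lambda = lambda, effect = effect)
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost incremental cost (EUR), intervention minus comparator.
#' @param delta_effect incremental effect (effect units).
#' @return list of class `icer_result`: `delta_cost`, `delta_effect`,
#'   `icer` (`NA` when the effect increment is zero) and `quadrant` in
#'   {`intervention dominant`, `intervention dominated`, `trade-off NE`,
#'   `trade-off SW`, `cost-minimisation`}.
#' @export
icer <- function(delta_cost, delta_effect) {
  quadrant <- if (delta_effect == 0) {
    "cost-minimisation"
  } else if (delta_cost <= 0 && delta_effect >= 0) {
    "intervention dominant"
  } else if (delta_cost >= 0 && delta_effect <= 0) {
    "intervention dominated"
  } else if (delta_cost > 0 && delta_effect > 0) {
    "trade-off NE"
  } else {
    "trade-off SW"
  }
  structure(list(
    delta_cost = delta_cost, delta_effect = delta_effect,
    icer = if (delta_effect == 0) NA_real_ else delta_cost / delta_effect,
    quadrant = quadrant), class = "icer_result")
}

#' Per-participant net monetary benefit
#'
#' @param cost Euro cost.
#' @param effect health effect (QALYs or DFDs).
#' @param lambda willingness to pay per effect unit (>= 0).
#' @return `lambda * effect - cost`.
#' @export
net_benefit <- function(cost, effect, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda * effect - cost
}

#' Cost-effectiveness probability from a net-benefit regression
#'
#' Converts the arm coefficient and its two-sided p-value into the
#' probability that the intervention's incremental net benefit is positive:
#' `1 - p/2` when the coefficient is positive, `p/2` when negative, and 0.5
#' at exactly zero.
#'
#' @param coefficient pooled net-benefit arm coefficient.
#' @param p_value two-sided p-value in (0, 1].
#' @return probability in (0, 1).
#' @export
ce_probability <- function(coefficient, p_value) {
  if (any(p_value <= 0 | p_value > 1)) stop("p_value must be in (0, 1]")
  ifelse(coefficient > 0, 1 - p_value / 2,
         ifelse(coefficient < 0, p_value / 2, 0.5))
}

#' Cost-effectiveness acceptability curves by net-benefit regression
#'
#' For each willingness-to-pay value, computes the per-participant net
#' monetary benefit in every imputed dataset, fits the linear mixed-effects
#' net-benefit regression (same covariates and random structure as the
#' effect models), pools the arm coefficients with Rubin's rules and maps
#' pooled coefficient and p-value to a cost-effectiveness probability with
#' the half-p rule. Comparisons are pairwise against the no-feedback arm.
#'
#' @param tabs list of completed analysis tables with outcome columns (an
#'   `imputation_stack$imputations` after [derive_outcomes()], or a list of
#'   length one for complete-case analyses).
#' @param grid a [wtp_grid()].
#' @param cost_col,effect_col outcome column names.
#' @param covariates adjustment covariate terms.
#' @return data.frame of class `ceac_curve`: lambda, term, coefficient, se,
#'   p, probability.
#' @export
ceac <- function(tabs, grid, cost_col = "cost_societal",
                 effect_col = "qaly", covariates = model_covariates()) {
  rows <- list()
  for (lam in grid$lambda) {
    fits <- lapply(tabs, function(tt) {
      tt$.nb <- net_benefit(tt[[cost_col]], tt[[effect_col]], lam)
      fit_effect_model(tt, ".nb", covariates)
    })
    pooled <- rubin_pool(fits)
    rows[[as.character(lam)]] <- data.frame(
      lambda = lam, term = pooled$term, coefficient = pooled$estimate,
      se = pooled$se, p = pooled$p,
      probability = ce_probability(pooled$estimate, pooled$p))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "effect") <- grid$effect
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Unadjusted ICERs from raw arm means
#'
#' Per-participant costs and effects are averaged across imputations, then
#' aggregated to arm means; pairwise increments and dominance
#' classifications are reported for every arm pair.
#'
#' @inheritParams ceac
#' @return data.frame: comparison, arm means, increments, icer, quadrant.
#' @export
unadjusted_icers <- function(tabs, cost_col = "cost_societal",
                             effect_col = "qaly") {
  # arm means per imputed dataset, averaged across imputations (robust to
  # imputation-specific subgroup membership, e.g. the imputed MINI flag)
  mc <- rowMeans(sapply(tabs, function(tt)
    tapply(tt[[cost_col]], tt$arm, mean)))
  me <- rowMeans(sapply(tabs, function(tt)
    tapply(tt[[effect_col]], tt$arm, mean)))
  pairs <- list(c("gp", "none"), c("gp_plus_patient", "none"),
                c("gp_plus_patient", "gp"))
  out <- lapply(pairs, function(pr) {
    ic <- icer(mc[[pr[1L]]] - mc[[pr[2L]]], me[[pr[1L]]] - me[[pr[2L]]])
    data.frame(comparison = paste(pr[1L], "vs", pr[2L]),
               cost_1 = mc[[pr[1L]]], cost_0 = mc[[pr[2L]]],
               effect_1 = me[[pr[1L]]], effect_0 = me[[pr[2L]]],
               delta_cost = ic$delta_cost, delta_effect = ic$delta_effect,
               icer = ic$icer, quadrant = ic$quadrant)
  })
  do.call(rbind, out)
}

#' Scenario configuration
#'
#' @param scenario one of `base_societal`, `payer`, `complete_case`, `dfd`.
#' @return list of class `scenario_config` with `scenario`, `perspective`,
#'   `cost_col`, `effect_col`, `covariates`, `grid`.
#' @export
scenario_config <- function(scenario = c("base_societal", "payer",
                                         "complete_case", "dfd")) {
  scenario <- match.arg(scenario)
  perspective <- if (scenario == "payer") "payer" else "societal"
  list2 <- list(
    scenario = scenario, perspective = perspective,
    cost_col = if (scenario == "payer") "cost_payer" else "cost_societal",
    effect_col = if (scenario == "dfd") "dfd" else "qaly",
    covariates = model_covariates(perspective),
    grid = wtp_grid(if (scenario == "dfd") "DFD" else "QALY"))
  class(list2) <- "scenario_config"
  list2
}

# completed+derived tables for a scenario; complete_case filters the
# original (missing) table to rows with fully observed societal costs and
# QALY inputs
.scenario_tables <- function(stack, scenario, fixtures, tab_missing = NULL) {
  if (scenario$scenario == "complete_case") {
    if (is.null(tab_missing))
      stop("complete_case scenario needs the pre-imputation table")
    cols <- setdiff(imputable_columns(tab_missing), "mini_depression_T1")
    keep <- rowSums(is.na(tab_missing[, cols])) == 0L
    if (!any(keep)) stop("complete_case scenario has no eligible participants")
    list(derive_outcomes(tab_missing[keep, , drop = FALSE], fixtures))
  } else {
    lapply(stack$imputations, derive_outcomes, fixtures = fixtures)
  }
}

#' Run one analysis scenario end to end
#'
#' Produces the scenario's adjusted estimates (gamma log-link mixed models
#' for societal/payer/direct costs, a two-part model for indirect costs,
#' linear mixed models for the effect measure), unadjusted ICERs from raw
#' arm means, and CEACs over the scenario's willingness-to-pay grid, all
#' pooled across imputations and compared pairwise against no feedback.
#'
#' @param stack `imputation_stack` over the analysis table.
#' @param scenario a [scenario_config()] (or its name).
#' @param fixtures costing fixtures from [make_fixtures()].
#' @param tab_missing pre-imputation analysis table (required for the
#'   complete-case scenario).
#' @param ceac_curves logical; compute CEACs (the expensive part)?
#' @return list of class `scenario_result`: `scenario`, `estimates`
#'   (Table-2-style data.frame), `icers`, `ceac`, `n`.
#' @export
run_scenario <- function(stack, scenario = "base_societal",
                         fixtures = make_fixtures(), tab_missing = NULL,
                         ceac_curves = TRUE) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  tabs <- .scenario_tables(stack, scenario, fixtures, tab_missing)
  covs <- scenario$covariates

  outcomes <- list(
    list(col = scenario$cost_col, family = "gamma"),
    list(col = "cost_direct", family = "gamma"),
    list(col = "cost_indirect", family = "zi-gamma"),
    list(col = scenario$effect_col, family = "linear"))
  if (scenario$scenario == "payer")
    outcomes[[3L]] <- NULL  # indirect costs are outside the payer perspective

  estimates <- list()
  for (oc in outcomes) {
    fits <- lapply(tabs, function(tt) switch(
      oc$family,
      gamma = fit_cost_model(tt, oc$col, covs),
      `zi-gamma` = fit_zi_cost_model(tt, oc$col, covs),
      linear = fit_effect_model(tt, oc$col, covs)))
    pooled <- rubin_pool(fits)
    pooled$outcome <- oc$col
    pooled$family <- attr(pooled, "family")
    pooled <- as.data.frame(pooled)
    for (cc in c("ratio", "ratio_ci_low", "ratio_ci_high"))
      if (is.null(pooled[[cc]])) pooled[[cc]] <- NA_real_
    estimates[[oc$col]] <- pooled
  }
  estimates <- do.call(rbind, estimates)
  rownames(estimates) <- NULL

  res <- list(
    scenario = scenario$scenario,
    estimates = estimates,
    icers = unadjusted_icers(tabs, scenario$cost_col, scenario$effect_col),
    ceac = if (ceac_curves)
      ceac(tabs, scenario$grid, scenario$cost_col, scenario$effect_col,
           covs) else NULL,
    n = nrow(tabs[[1L]]))
  class(res) <- "scenario_result"
  res
}

#' Subpopulation analyses
#'
#' Splits every imputed dataset by the levels of a baseline category
#' (gender, depression history, addiction, or MINI-confirmed depression at
#' one month) and reruns the scenario pipeline per level with the reduced
#' subgroup covariate set (no pregnancy, breastfeeding or living situation;
#' binarised city size). Empty levels are skipped with a warning. When
#' splitting on the MINI flag, each imputed dataset uses its own imputed
#' flag values.
#'
#' @param stack `imputation_stack`.
#' @param variable splitting variable: `gender`, `depression_history`,
#'   `addiction` or `mini_depression_T1`.
#' @param scenario scenario name or [scenario_config()].
#' @param fixtures costing fixtures.
#' @param ceac_curves logical.
#' @return named list of `scenario_result`, one per level.
#' @export
run_subgroup <- function(stack, variable, scenario = "base_societal",
                         fixtures = make_fixtures(), ceac_curves = TRUE) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  scenario$covariates <- model_covariates(scenario$perspective,
                                          subgroup = TRUE)
  scenario$covariates <- setdiff(scenario$covariates, variable)
  lv <- stack$imputations[[1L]][[variable]]
  levels <- if (is.logical(lv)) c(TRUE, FALSE) else levels(droplevels(
    factor(lv)))
  out <- list()
  for (l in levels) {
    sub <- stack
    sub$imputations <- lapply(stack$imputations, function(tt) {
      tt <- tt[!is.na(tt[[variable]]) & tt[[variable]] == l, , drop = FALSE]
      tt$city_binary <- tt$city_size == "city"
      tt
    })
    sizes <- vapply(sub$imputations, nrow, integer(1L))
    if (any(sizes < 10L)) {
      warning("subgroup level ", l, " of ", variable,
              " is empty or too small; skipped")
      next
    }
    out[[as.character(l)]] <- run_scenario(sub, scenario, fixtures,
                                           ceac_curves = ceac_curves)
  }
  out
}
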