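#' Missingness diagnostics for an analysis table
#'
#' Reports per-variable missing fractions, counts of distinct missingness
#' patterns over the outcome blocks, and logistic regressions of outcome
#' missingness (12-month costs, QALYs) on fully observed baseline
#' predictors, mirroring the diagnostics used to argue for a
#' missing-at-random mechanism.
#'
#' @param tab analysis table (possibly with missing values).
#' @return list of class `missingness_report` with `fractions` (named
#'   vector), `patterns` (data.frame of pattern string and count),
#'   `regressions` (data.frame: outcome, predictor, odds ratio, CI, p;
#'   empty if nothing is missing), and `n`.
#' @export
missingness_diagnostics <- function(tab) {
  cols <- imputable_columns(tab)
  fractions <- vapply(tab[cols], function(x) mean(is.na(x)), numeric(1L))

  blocks <- c(outer(c("eq5d", "phq9", "sick_days"), c("T1", "T2", "T3"),
                    paste, sep = "_"), "mini_depression_T1")
  pat <- apply(!is.na(tab[, intersect(blocks, names(tab))]), 1L, paste0,
               collapse = "")
  patterns <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(patterns)[2L] <- "count"

  regressions <- data.frame()
  if (any(fractions > 0)) {
    miss_qaly <- is.na(tab$eq5d_T1) | is.na(tab$eq5d_T2) | is.na(tab$eq5d_T3)
    costcols <- grep("_(T1|T2|T3)$", cols, value = TRUE)
    costcols <- setdiff(costcols, grep("^(eq5d|phq9)_", costcols,
                                       value = TRUE))
    miss_cost <- rowSums(is.na(tab[, costcols])) > 0
    preds <- c("native_speaker", "smoker", "eq5d_T0", "phq9_T0",
               "bl_gp_visits", "addiction")
    for (oc in c("cost", "qaly")) {
      y <- if (oc == "cost") miss_cost else miss_qaly
      if (all(y) || all(!y)) next
      fit <- stats::glm(
        stats::reformulate(preds, response = "y"),
        data = cbind(y = y, tab[preds]), family = stats::binomial())
      cf <- summary(fit)$coefficients[-1L, , drop = FALSE]
      regressions <- rbind(regressions, data.frame(
        outcome = oc, predictor = rownames(cf),
        odds_ratio = exp(cf[, 1L]),
        ci_low = exp(cf[, 1L] - 1.96 * cf[, 2L]),
        ci_high = exp(cf[, 1L] + 1.96 * cf[, 2L]),
        p = cf[, 4L], row.names = NULL))
    }
  }
  structure(list(fractions = fractions, patterns = patterns,
                 regressions = regressions, n = nrow(tab)),
            class = "missingness_report")
}

# complete-data design matrix of baseline predictors used in every
# conditional imputation model; centre ids enter as fixed dummies
.imp_base_design <- function(tab) {
  covs <- c("arm", "centre_id", "age", "gender", "education_ge10y",
            "city_size", "living_situation", "insurance_plan",
            "native_speaker", "smoker", "depression_history", "addiction",
            "pregnancy", "breastfeeding", "bl_gp_visits",
            "bl_inpatient_days", "bl_medication_count", "bl_sick_days",
            "eq5d_T0", "phq9_T0")
  stats::model.matrix(stats::reformulate(covs), data = tab)
}

# one Bayesian-draw PMM step for a numeric variable
.pmm_draw <- function(y, X, mis, k = 5L) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(1e-6, p)
  Xty <- crossprod(Xo, yo)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  resid <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  beta_star <- beta_hat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2)
  pred_obs <- drop(Xo %*% beta_hat)
  pred_mis <- drop(X[mis, , drop = FALSE] %*% beta_star)
  pmm_match(pred_mis, pred_obs, yo, as.integer(k))
}

# logistic draw for a binary variable
.logit_draw <- function(y, X, mis) {
  obs <- !mis
  fit <- suppressWarnings(stats::glm.fit(X[obs, , drop = FALSE],
                                         as.numeric(y[obs]),
                                         family = stats::binomial()))
  qr_ <- fit$qr
  keep <- qr_$pivot[seq_len(qr_$rank)]
  Xk <- X[obs, keep, drop = FALSE]
  w <- fit$weights
  V <- tryCatch(solve(crossprod(Xk * sqrt(w)) + diag(1e-8, length(keep))),
                error = function(e) diag(1e-2, length(keep)))
  beta <- fit$coefficients[keep]
  beta_star <- MASS::mvrnorm(1L, beta, V)
  pr <- stats::plogis(drop(X[mis, keep, drop = FALSE] %*% beta_star))
  stats::runif(sum(mis)) < pr
}

#' Multiple imputation by chained equations
#'
#' Produces M completed copies of the analysis table by iterating
#' variable-by-variable conditional imputation: predictive-mean matching
#' with Bayesian parameter draws and k nearest donors for numeric and count
#' variables (imputed values are always observed donor values, so type
#' invariants hold by construction), and posterior logistic draws for the
#' binary MINI flag. Conditional models use all baseline covariates, arm,
#' centre dummies, baseline scores, and the same variable at the other
#' follow-up time points. Variables are visited in order of ascending
#' missing fraction.
#'
#' @param tab analysis table with missing follow-up values; design columns
#'   (arm, cluster ids) and baseline fields must be complete.
#' @param M number of imputed datasets.
#' @param iterations chained-equation sweeps per imputation.
#' @param seed integer seed (deterministic stack).
#' @param k donors for predictive-mean matching.
#' @return object of class `imputation_stack`: list with `imputations`
#'   (list of M completed tables), `method` (named per-variable), `M`,
#'   `iterations`, `seed` and `trace` (chain mean/variance of imputed
#'   values per iteration, for convergence checks).
#' @export
mice_impute <- function(tab, M = 20L, iterations = 10L, seed = 1L, k = 5L) {
  design <- c("arm", "centre_id", "practice_id")
  if (anyNA(tab[design])) stop("design variables (arm, cluster ids) must be complete")
  base_cols <- setdiff(names(tab), imputable_columns(tab))
  if (anyNA(tab[base_cols])) stop("baseline fields must be complete")
  vars <- imputable_columns(tab)
  miss <- vapply(tab[vars], anyNA, logical(1L))
  vars <- vars[miss]
  if (length(vars) == 0L)
    return(structure(list(imputations = rep(list(tab), M),
                          method = character(), M = as.integer(M),
                          iterations = as.integer(iterations),
                          seed = as.integer(seed),
                          trace = NULL), class = "imputation_stack"))
  frac <- vapply(tab[vars], function(x) mean(is.na(x)), numeric(1L))
  vars <- vars[order(frac)]
  method <- stats::setNames(
    ifelse(vars == "mini_depression_T1", "logreg", "pmm"), vars)

  X0 <- .imp_base_design(tab)
  mis_idx <- lapply(tab[vars], is.na)
  set.seed(stage_seed(seed, "impute"))

  imputations <- vector("list", M)
  trace <- vector("list", M)
  for (m in seq_len(M)) {
    cur <- tab
    # initial fill: random draws from the observed margins
    for (v in vars) {
      mi <- mis_idx[[v]]
      cur[[v]][mi] <- sample(tab[[v]][!mi], sum(mi), replace = TRUE)
    }
    tr <- list()
    for (it in seq_len(iterations)) {
      for (v in vars) {
        mi <- mis_idx[[v]]
        sib <- .sibling_columns(v, names(tab))
        X <- if (length(sib)) cbind(X0, as.matrix(
          data.matrix(cur[sib]))) else X0
        if (method[[v]] == "logreg") {
          cur[[v]][mi] <- .logit_draw(cur[[v]], X, mi)
        } else {
          cur[[v]][mi] <- .pmm_draw(cur[[v]], X, mi, k = k)
        }
      }
      tr[[it]] <- vapply(vars, function(v)
        c(mean = mean(as.numeric(cur[[v]][mis_idx[[v]]])),
          var = stats::var(as.numeric(cur[[v]][mis_idx[[v]]]))),
        numeric(2L))
    }
    # PMM donors are observed values; restore integer storage where the
    # source column was integer
    for (v in vars)
      if (is.integer(tab[[v]])) cur[[v]] <- as.integer(round(cur[[v]]))
    imputations[[m]] <- cur
    trace[[m]] <- tr
  }
  structure(list(imputations = imputations, method = method,
                 M = as.integer(M), iterations = as.integer(iterations),
                 seed = as.integer(seed), trace = trace),
            class = "imputation_stack")
}

# same variable at the other follow-up time points
.sibling_columns <- function(v, all_names) {
  if (v == "mini_depression_T1") return(character())
  stem <- sub("_(T1|T2|T3)$", "", v)
  setdiff(grep(paste0("^", stem, "_(T1|T2|T3)$"), all_names, value = TRUE),
          v)
}

#' @export
print.imputation_stack <- function(x, ...) {
  cat(sprintf("imputation stack: M = %d, iterations = %d, seed = %d\n",
              x$M, x$iterations, x$seed))
  cat(sprintf("variables imputed: %d\n", length(x$method)))
  invisible(x)
}
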