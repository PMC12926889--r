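#' Synthetic three-arm trial configuration
#'
#' Defines the data-generating conditions for a synthetic stand-in of a
#' three-arm, practice-in-centre clustered randomised trial of depression
#' screening feedback: 329 participants per arm across 64 general practices
#' nested in 5 study centres; adults screening at least moderately depressed
#' (baseline PHQ-9 >= 10, mean about 13.5); baseline EQ-5D-5L index mean
#' about 0.675; right-skewed two-part resource-use costs; and a
#' missing-at-random follow-up missingness mechanism targeting 20% of
#' outcome values.
#'
#' @param n_per_arm participants per arm.
#' @param n_centres number of study centres.
#' @param n_practices number of general practices (nested in centres).
#' @param arm_effects named list with entries `none`, `gp`,
#'   `gp_plus_patient`, each a list with `utility` (additive shift on the
#'   latent EQ-5D index trajectory from the first follow-up on, utility
#'   units) and `cost_ratio` (multiplicative shift on latent resource-use
#'   intensity). Defaults are null effects.
#' @param cost_params data.frame with columns `category`, `p_zero` (window
#'   zero probability), `shape` (gamma shape of the participant intensity
#'   multiplier) and `annual_mean` (expected annual units among users).
#' @param missing_rate_target overall proportion of follow-up outcome values
#'   set missing by [apply_missingness()].
#' @param p_diverse frequency of the diverse gender category.
#' @param effect_modifier optional list(`variable`, `level`, `utility`,
#'   `cost_ratio`) adding a stratum-specific intervention effect (applied on
#'   top of `arm_effects` in both intervention arms for participants with
#'   `variable == level`).
#' @param seed master seed; generation, missingness and imputation use
#'   deterministic substreams derived from it.
#' @return object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 329L, n_centres = 5L, n_practices = 64L,
                         arm_effects = NULL, cost_params = NULL,
                         missing_rate_target = 0.20, p_diverse = 0.008,
                         effect_modifier = NULL, seed = 1L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1)
    stop("invalid config field: n_per_arm")
  if (!is.numeric(n_centres) || n_centres < 1)
    stop("invalid config field: n_centres")
  if (!is.numeric(n_practices) || n_practices < n_centres)
    stop("invalid config field: n_practices")
  if (missing_rate_target < 0 || missing_rate_target >= 1)
    stop("invalid config field: missing_rate_target")
  if (is.null(arm_effects))
    arm_effects <- list(none = list(utility = 0, cost_ratio = 1),
                        gp = list(utility = 0, cost_ratio = 1),
                        gp_plus_patient = list(utility = 0, cost_ratio = 1))
  if (!identical(sort(names(arm_effects)), sort(trial_arms())))
    stop("invalid config field: arm_effects (need exactly the 3 arms)")
  if (is.null(cost_params)) cost_params <- default_cost_params()
  if (any(cost_params$p_zero < 0 | cost_params$p_zero > 1))
    stop("invalid config field: cost_params$p_zero")
  if (any(cost_params$shape <= 0) || any(cost_params$annual_mean < 0))
    stop("invalid config field: cost_params")
  structure(
    list(n_per_arm = as.integer(n_per_arm), n_centres = as.integer(n_centres),
         n_practices = as.integer(n_practices), arm_effects = arm_effects,
         cost_params = cost_params,
         missing_rate_target = missing_rate_target, p_diverse = p_diverse,
         effect_modifier = effect_modifier, seed = as.integer(seed)),
    class = "trial_config")
}

#' Arm labels (reference first)
#' @export
trial_arms <- function() c("none", "gp", "gp_plus_patient")

#' Default two-part intensity parameters per resource category
#' @export
default_cost_params <- function() {
  data.frame(
    category = cost_categories(),
    p_zero = c(0.15, 0.35, 0.75, 0.80, 0.55, 0.88, 0.25, 0.93),
    shape = c(1.2, 1.0, 1.5, 1.0, 0.8, 0.7, 1.2, 0.8),
    annual_mean = c(6, 4, 12, 5, 8, 8, 6, 40),
    stringsAsFactors = FALSE
  )
}

# deterministic substreams per pipeline stage
stage_seed <- function(master, stage) {
  offs <- c(generate = 101L, missing = 211L, impute = 307L, analysis = 401L,
            replicate = 503L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(master) %% 2000000000L) + offs[[stage]]
}

# number of ways k PHQ-9 items (0..3 each) sum to s; table rows k=0..9
.phq_ways <- local({
  w <- matrix(0, nrow = 10L, ncol = 28L)  # [k+1, s+1]
  w[1L, 1L] <- 1
  for (k in 1:9) for (s in 0:27) {
    v <- 0:min(3L, s)
    w[k + 1L, s + 1L] <- sum(w[k, s + 1L - v])
  }
  w
})

# sample item vectors uniformly among 9-tuples of 0..3 with the given totals
sample_phq_items <- function(totals) {
  n <- length(totals)
  out <- matrix(0L, n, 9L)
  for (i in seq_len(n)) {
    s <- totals[i]
    for (j in 1:9) {
      r <- 9L - j
      v <- 0:min(3L, s)
      wt <- .phq_ways[r + 1L, s + 1L - v]
      pick <- if (length(v) == 1L) v else
        sample(v, 1L, prob = wt / sum(wt))
      out[i, j] <- pick
      s <- s - pick
    }
  }
  out
}

# discretise a target utility index into a 5-digit state: each dimension
# receives a noisy share of the total decrement 1 - h and takes the level
# with the nearest decrement
.eq5d_shares <- c(mobility = 0.203, selfcare = 0.189, activity = 0.165,
                  pain = 0.2215, anxiety = 0.2215)

index_to_state <- function(h, value_set, sd_dim = 0.45) {
  n <- length(h)
  deficit <- pmax(0, 1 - h)
  dm <- matrix(value_set$decrement[order(match(value_set$dimension,
                                               eq5d_dimensions),
                                         value_set$level)],
               nrow = 5L, byrow = TRUE)
  lv <- matrix(1L, n, 5L)
  for (d in seq_len(5L)) {
    target <- deficit * .eq5d_shares[d] * exp(stats::rnorm(n, 0, sd_dim))
    lv[, d] <- max.col(-abs(outer(target, dm[d, ], "-")))
  }
  lv
}

#' Generate a complete synthetic trial dataset
#'
#' Produces one record per participant with arm assignment (1:1:1), cluster
#' ids, baseline covariates, four EQ-5D-5L assessments (as genuine 5-digit
#' states), four PHQ-9 assessments (as item vectors whose sums follow the
#' configured severity distribution, all baseline totals >= 10), per-window
#' resource-use counts from a two-part (zero / positive-count) process,
#' sick-leave days, informal-care hours and a 1-month MINI depression flag.
#' The latent health trajectory improves over follow-up in all arms; arm
#' effects shift it additively (utility) and scale cost intensity
#' multiplicatively.
#'
#' @param config a [trial_config()].
#' @return object of class `trial_data`: list with `baseline` (one row per
#'   participant) and `longitudinal` (one row per participant x time point)
#'   data.frames plus the generating `config`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(stage_seed(config$seed, "generate"))
  arms <- trial_arms()
  n <- 3L * config$n_per_arm
  vs <- default_value_set()

  # clusters: practices split across centres as evenly as possible
  practice_centre <- sort(rep_len(seq_len(config$n_centres),
                                  config$n_practices))
  practice <- sample(seq_len(config$n_practices), n, replace = TRUE)
  centre <- practice_centre[practice]
  arm <- sample(rep(arms, each = config$n_per_arm))

  # baseline covariates
  age <- round(pmin(85, pmax(18, stats::rnorm(n, 39.5, 15.3))))
  gender <- sample(c("female", "male", "diverse"), n, replace = TRUE,
                   prob = c(0.622, 1 - 0.622 - config$p_diverse,
                            config$p_diverse))
  education_ge10y <- stats::runif(n) < 0.60
  city_size <- sample(c("rural", "town", "city"), n, replace = TRUE,
                      prob = c(0.25, 0.40, 0.35))
  living_situation <- sample(c("alone", "partner", "family"), n,
                             replace = TRUE, prob = c(0.30, 0.40, 0.30))
  insurance_plan <- stats::runif(n) < 0.12
  native_speaker <- stats::runif(n) < 0.85
  smoker <- stats::runif(n) < 0.35
  depression_history <- stats::runif(n) < 0.50
  addiction <- stats::runif(n) < 0.15
  pregnancy <- gender == "female" & stats::runif(n) < 0.04
  breastfeeding <- gender == "female" & stats::runif(n) < 0.03
  bl_gp_visits <- stats::rpois(n, 3)
  bl_inpatient_days <- stats::rpois(n, 0.8) * (stats::runif(n) < 0.25)
  bl_medication_count <- stats::rpois(n, 2)
  bl_sick_days <- stats::rnbinom(n, size = 0.8, mu = 8)

  # shared latent health factor couples EQ-5D and PHQ-9
  z <- stats::rnorm(n)
  b_pr <- stats::rnorm(config$n_practices, 0, 0.02)[practice]
  b_ce <- stats::rnorm(config$n_centres, 0, 0.01)[centre]

  # baseline PHQ-9 total: screening truncates the latent severity
  # distribution at the inclusion threshold of 10; the latent location and
  # spread are calibrated so the post-screening totals have mean ~13.5 and
  # sd ~3.3
  phq0 <- round(6.6 - 3.0 * z + stats::rnorm(n, 0, 6.15))
  bad <- phq0 < 10 | phq0 > 27
  while (any(bad)) {
    phq0[bad] <- round(6.6 - 3.0 * z[bad] + stats::rnorm(sum(bad), 0, 6.15))
    bad <- phq0 < 10 | phq0 > 27
  }

  # latent utility trajectory; improvement in all arms, arm shift from T1 on
  improve <- c(T0 = 0, T1 = 0.05, T2 = 0.12, T3 = 0.175)
  u_shift <- vapply(config$arm_effects[arm], `[[`, numeric(1L), "utility")
  c_ratio <- vapply(config$arm_effects[arm], `[[`, numeric(1L), "cost_ratio")
  if (!is.null(config$effect_modifier)) {
    em <- config$effect_modifier
    covs <- data.frame(gender = gender,
                       depression_history = depression_history,
                       addiction = addiction, stringsAsFactors = FALSE)
    hit <- arm != "none" &
      as.character(covs[[em$variable]]) == as.character(em$level)
    u_shift[hit] <- u_shift[hit] + (em$utility %||% 0)
    c_ratio[hit] <- c_ratio[hit] * (em$cost_ratio %||% 1)
  }
  h0 <- 0.692 + 0.14 * z + b_pr + b_ce + stats::rnorm(n, 0, 0.215)

  times <- c("T0", "T1", "T2", "T3")
  phq_per_utility <- -20  # utility arm shifts propagate to the PHQ-9 scale
  drop_t <- c(T0 = 0, T1 = 1.5, T2 = 3.0, T3 = 4.0)

  long <- vector("list", length(times))
  phq_tot <- matrix(0L, n, 4L, dimnames = list(NULL, times))
  h_lat <- matrix(0, n, 4L, dimnames = list(NULL, times))
  for (t in seq_along(times)) {
    tm <- times[t]
    sh <- if (tm == "T0") 0 else u_shift
    h <- h0 + improve[tm] + sh + if (tm == "T0") 0 else
      stats::rnorm(n, 0, 0.11)
    h <- pmin(0.999, pmax(-0.6, h))
    h_lat[, t] <- h
    if (tm == "T0") {
      tot <- phq0
    } else {
      tot <- round(phq0 - drop_t[tm] + phq_per_utility * sh +
                     stats::rnorm(n, 0, 2.4))
      tot <- pmin(27L, pmax(0L, tot))
    }
    phq_tot[, t] <- tot
    lv <- index_to_state(h, vs)
    items <- sample_phq_items(tot)
    long[[t]] <- data.frame(
      participant_id = sprintf("ID%04d", seq_len(n)), time = tm,
      mobility = lv[, 1L], selfcare = lv[, 2L], activity = lv[, 3L],
      pain = lv[, 4L], anxiety = lv[, 5L],
      stats::setNames(as.data.frame(items), paste0("phq", 1:9)),
      stringsAsFactors = FALSE)
  }

  # follow-up resource use: two-part window-level counts
  frac <- c(T1 = 30, T2 = 150, T3 = 180) / 360
  cp <- config$cost_params
  health_mult <- exp(0.6 * (0.675 - h0))
  res <- list()
  for (ci in seq_len(nrow(cp))) {
    g <- stats::rgamma(n, shape = cp$shape[ci], rate = cp$shape[ci])
    for (w in c("T1", "T2", "T3")) {
      lam <- cp$annual_mean[ci] * frac[[w]] * g * c_ratio * health_mult
      pos <- stats::runif(n) >= cp$p_zero[ci]
      res[[paste(cp$category[ci], w, sep = ".")]] <-
        ifelse(pos, 1L + stats::rpois(n, lam), 0L)
    }
  }
  sick <- informal <- list()
  for (w in c("T1", "T2", "T3")) {
    lam_s <- 14 * frac[[w]] * exp(0.05 * (phq0 - 13.5)) * c_ratio
    pos <- stats::runif(n) >= 0.5
    sick[[w]] <- pmin(round(frac[[w]] * 360),
                      ifelse(pos, 1L + stats::rpois(n, lam_s), 0L))
    posi <- stats::runif(n) >= 0.85
    informal[[w]] <- ifelse(
      posi, round(stats::rgamma(n, 1.2, rate = 1.2 / (30 * frac[[w]] *
                                                        c_ratio)), 1), 0)
  }
  for (w in c("T1", "T2", "T3")) {
    i <- match(w, times)
    long[[i]][cost_categories()] <-
      res[paste(cost_categories(), w, sep = ".")]
    long[[i]]$sick_days <- sick[[w]]
    long[[i]]$informal_care_hours <- informal[[w]]
  }
  long[[1L]][c(cost_categories(), "sick_days", "informal_care_hours")] <- NA

  mini <- stats::runif(n) < stats::plogis(0.15 * (phq_tot[, "T1"] - 10))

  baseline <- data.frame(
    participant_id = sprintf("ID%04d", seq_len(n)),
    arm = factor(arm, levels = arms),
    centre_id = sprintf("C%d", centre),
    practice_id = sprintf("GP%02d", practice),
    age = age, gender = factor(gender,
                               levels = c("female", "male", "diverse")),
    education_ge10y = education_ge10y,
    city_size = factor(city_size, levels = c("rural", "town", "city")),
    living_situation = factor(living_situation,
                              levels = c("alone", "partner", "family")),
    insurance_plan = insurance_plan, native_speaker = native_speaker,
    smoker = smoker, depression_history = depression_history,
    addiction = addiction, pregnancy = pregnancy,
    breastfeeding = breastfeeding,
    bl_gp_visits = bl_gp_visits, bl_inpatient_days = as.integer(
      bl_inpatient_days),
    bl_medication_count = bl_medication_count, bl_sick_days = bl_sick_days,
    mini_depression_T1 = mini,
    stringsAsFactors = FALSE)

  structure(list(baseline = baseline,
                 longitudinal = do.call(rbind, long)[order(
                   rep(seq_len(n), length(times))), , drop = FALSE],
                 config = config),
            class = "trial_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected latent-scale QALY difference between two arms
#'
#' Closed-form expectation of the follow-up QALY difference implied by the
#' generator's latent trajectory model (arm utility shifts applying from the
#' first follow-up on, linear interpolation over 30/150/180-day segments).
#' The observed difference is attenuated slightly by the discretisation of
#' the latent index into 5-digit states.
#'
#' @param config a [trial_config()].
#' @param arm,reference arm labels.
#' @param reference_days,denominator as in [qaly_auc()].
#' @export
generator_expected_qaly_diff <- function(config, arm = "gp",
                                         reference = "none",
                                         reference_days = c(30, 150, 180),
                                         denominator = 365) {
  d <- config$arm_effects[[arm]]$utility -
    config$arm_effects[[reference]]$utility
  # shift absent at T0, full at T1..T3 under trapezoidal integration
  d * (reference_days[1] / 2 + sum(reference_days[-1])) / denominator
}

#' Impose missing-at-random follow-up missingness
#'
#' Sets post-baseline outcome blocks (EQ-5D state, PHQ-9 items, resource
#' use / sick days / informal care, each per follow-up time point, plus the
#' 1-month MINI flag) to missing via a logistic model on fully observed
#' baseline predictors: non-native speaker, smoker, baseline EQ-5D index,
#' baseline PHQ-9, baseline GP visits and addiction. The model intercept is
#' calibrated by bisection so the expected overall missing proportion equals
#' `config$missing_rate_target`. Baseline assessments, arm and cluster ids
#' are never missing.
#'
#' @param data a complete `trial_data` object.
#' @param config a [trial_config()]; defaults to the generating config.
#' @return `trial_data` with missing values; attribute `realized_missing`
#'   reports the achieved overall missing fraction over imputable cells.
#' @export
apply_missingness <- function(data, config = data$config) {
  stopifnot(inherits(data, "trial_data"))
  target <- config$missing_rate_target
  if (target == 0) return(data)
  set.seed(stage_seed(config$seed, "missing"))
  bl <- data$baseline
  lg <- data$longitudinal
  vs <- default_value_set()
  t0 <- lg[lg$time == "T0", ]
  t0 <- t0[match(bl$participant_id, t0$participant_id), ]
  eq0 <- score_eq5d_index(as.matrix(
    t0[, c("mobility", "selfcare", "activity", "pain", "anxiety")]), vs)
  phq0 <- score_phq9(as.matrix(t0[, paste0("phq", 1:9)]))

  lp <- (-0.5) * bl$native_speaker + 0.4 * bl$smoker - 0.8 * eq0 +
    0.06 * phq0 + 0.08 * bl$bl_gp_visits + 0.4 * bl$addiction
  # calibrate the intercept so mean missingness probability hits the target
  f <- function(a) mean(stats::plogis(a + lp)) - target
  lo <- -12; hi <- 8
  if (f(hi) < 0) {
    warning(sprintf(
      "missing_rate_target %.2f unreachable; achieved at most %.3f",
      target, target + f(hi)))
    alpha <- hi
  } else {
    alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  p <- stats::plogis(alpha + lp)

  n <- nrow(bl)
  blocks <- list(
    eq5d = c("mobility", "selfcare", "activity", "pain", "anxiety"),
    phq9 = paste0("phq", 1:9),
    resources = c(cost_categories(), "sick_days", "informal_care_hours"))
  # whole follow-up assessments go missing together (questionnaire not
  # returned); independent 20% per time point leaves about half of
  # participants with complete 12-month costs and QALYs
  for (w in c("T1", "T2", "T3")) {
    rows <- match(paste(bl$participant_id, w),
                  paste(lg$participant_id, lg$time))
    hit <- stats::runif(n) < p
    lg[rows[hit], unlist(blocks)] <- NA
  }
  bl$mini_depression_T1[stats::runif(n) < p] <- NA
  out <- structure(list(baseline = bl, longitudinal = lg, config = config),
                   class = "trial_data")
  tab <- analysis_table(out, vs)
  attr(out, "realized_missing") <-
    mean(is.na(tab[, imputable_columns(tab)]))
  out
}
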