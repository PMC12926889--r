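# shared fixtures: a small generated trial (cached per test session) and an
# outcome-level simulator used by the estimator-validation suites

small_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- trial_config(n_per_arm = 60L, n_practices = 20L, seed = 101L)
      cache <<- list(config = cfg,
                     complete = generate_trial(cfg))
      cache$missing <<- apply_missingness(cache$complete)
      cache$tab <<- analysis_table(cache$complete)
      cache$tab_missing <<- analysis_table(cache$missing)
    }
    cache
  }
})

# simulate clustered outcome data directly at the analysis-table level;
# used to validate estimators against known truths without the
# generator's discretisation layers
simulate_outcomes <- function(n = 900L, n_practices = 60L, n_centres = 5L,
                              qaly_shift_gp = 0, cost_ratio_gp = 1,
                              sd_practice = 0.02, sd_centre = 0.01,
                              sd_resid = 0.10, cost_shape = 2,
                              cost_mean = 2000, zero_prob = 0,
                              seed = 1L) {
  set.seed(seed)
  arms <- trial_arms()
  practice <- sample.int(n_practices, n, replace = TRUE)
  centre <- sort(rep_len(seq_len(n_centres), n_practices))[practice]
  arm <- factor(sample(rep_len(arms, n)), levels = arms)
  b_pr <- rnorm(n_practices, 0, sd_practice)[practice]
  b_ce <- rnorm(n_centres, 0, sd_centre)[centre]
  age <- round(rnorm(n, 40, 12))
  qaly <- 0.6 + qaly_shift_gp * (arm == "gp") + b_pr + b_ce +
    0.001 * (age - 40) + rnorm(n, 0, sd_resid)
  mu <- cost_mean * cost_ratio_gp^(arm == "gp") *
    exp(b_pr * 5 + b_ce * 5 + 0.002 * (age - 40))
  cost <- rgamma(n, shape = cost_shape, rate = cost_shape / mu)
  if (zero_prob > 0) cost[runif(n) < zero_prob] <- 0
  data.frame(
    participant_id = sprintf("S%04d", seq_len(n)), arm = arm,
    centre_id = sprintf("C%d", centre),
    practice_id = sprintf("GP%02d", practice),
    age = age, qaly = qaly, cost = cost)
}

# a fabricated fit_result for pooling-identity tests
fake_fit <- function(est, se, df = 100, family = "linear") {
  structure(list(
    terms = data.frame(term = "armgp", estimate = est, se = se, df = df,
                       p = 2 * stats::pt(abs(est / se), df,
                                         lower.tail = FALSE)),
    family = family, method = "fake", converged = TRUE),
    class = "fit_result")
}
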