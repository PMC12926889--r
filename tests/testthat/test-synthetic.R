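test_that("generation honours arm sizes, inclusion criterion and clusters", {
  st <- small_trial()
  tab <- st$tab
  expect_equal(nrow(tab), 180L)
  expect_equal(as.integer(table(tab$arm)), rep(60L, 3L))
  expect_true(all(tab$phq9_T0 >= 10))
  # every practice maps to exactly one centre
  map <- unique(tab[, c("practice_id", "centre_id")])
  expect_equal(anyDuplicated(map$practice_id), 0L)
  expect_false(anyNA(tab))
})

test_that("generation is deterministic and invalid configs are rejected", {
  cfg <- trial_config(n_per_arm = 25L, seed = 9L)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  expect_error(trial_config(n_per_arm = 0), "n_per_arm")
  expect_error(trial_config(missing_rate_target = 1.2),
               "missing_rate_target")
  expect_error(trial_config(arm_effects = list(a = 1)), "arm_effects")
  bad <- default_cost_params(); bad$p_zero[1] <- 1.5
  expect_error(trial_config(cost_params = bad), "p_zero")
})

test_that("latent health improves over follow-up in every arm", {
  tab <- small_trial()$tab
  for (a in trial_arms()) {
    sub <- tab[tab$arm == a, ]
    expect_gt(mean(sub$eq5d_T3), mean(sub$eq5d_T0))
    expect_lt(mean(sub$phq9_T3), mean(sub$phq9_T0))
  }
})

big_null <- NULL
get_big_null <- function() {
  if (is.null(big_null))
    big_null <<- analysis_table(generate_trial(
      trial_config(n_per_arm = 2000L, seed = 77L)))
  big_null
}

test_that("null arm effects give a null QALY difference (closed form)", {
  cfg <- trial_config(n_per_arm = 2000L, seed = 77L)
  expect_equal(generator_expected_qaly_diff(cfg), 0)
  tab <- derive_outcomes(get_big_null())
  m <- tapply(tab$qaly, tab$arm, mean)
  v <- tapply(tab$qaly, tab$arm, var)
  n <- tapply(tab$qaly, tab$arm, length)
  for (a in c("gp", "gp_plus_patient")) {
    se <- sqrt(v[[a]] / n[[a]] + v[["none"]] / n[["none"]])
    expect_lt(abs(m[[a]] - m[["none"]] - 0), 3.5 * se)
  }
})

test_that("two-part cost process reproduces the configured zero fractions", {
  tab <- get_big_null()
  cp <- default_cost_params()
  for (i in seq_len(nrow(cp))) {
    cells <- unlist(tab[paste(cp$category[i], c("T1", "T2", "T3"),
                              sep = "_")])
    p <- cp$p_zero[i]
    tol <- 4 * sqrt(p * (1 - p) / length(cells))
    expect_lt(abs(mean(cells == 0) - p), tol + 1e-12)
  }
})

test_that("nonzero utility shift moves QALYs by about its closed form", {
  eff <- list(none = list(utility = 0, cost_ratio = 1),
              gp = list(utility = 0.08, cost_ratio = 1),
              gp_plus_patient = list(utility = 0, cost_ratio = 1))
  cfg <- trial_config(n_per_arm = 1500L, arm_effects = eff, seed = 31L)
  tab <- derive_outcomes(analysis_table(generate_trial(cfg)))
  m <- tapply(tab$qaly, tab$arm, mean)
  expected <- generator_expected_qaly_diff(cfg, "gp")
  expect_equal(expected, 0.08 * 345 / 365)
  # discretisation attenuates the latent shift somewhat
  expect_gt(m[["gp"]] - m[["none"]], 0.5 * expected)
  expect_lt(m[["gp"]] - m[["none"]], 1.3 * expected)
})

test_that("missingness hits its target, spares design fields, and is MAR", {
  st <- small_trial()
  expect_identical(
    apply_missingness(st$complete,
                      trial_config(n_per_arm = 60L, n_practices = 20L,
                                   missing_rate_target = 0, seed = 101L)),
    st$complete)
  tabm <- st$tab_missing
  expect_false(anyNA(tabm[, c("arm", "centre_id", "practice_id", "age",
                              "eq5d_T0", "phq9_T0")]))

  td <- apply_missingness(generate_trial(trial_config(seed = 13L)))
  expect_lt(abs(attr(td, "realized_missing") - 0.20), 0.03)
})

test_that("the missingness model's coefficient signs are recoverable", {
  cfg <- trial_config(n_per_arm = 4000L, seed = 55L)
  td <- apply_missingness(generate_trial(cfg))
  tab <- analysis_table(td)
  rep <- missingness_diagnostics(tab)
  qq <- rep$regressions[rep$regressions$outcome == "qaly", ]
  or <- setNames(qq$odds_ratio, qq$predictor)
  expect_lt(or[["native_speakerTRUE"]], 1)
  expect_gt(or[["smokerTRUE"]], 1)
  expect_lt(or[["eq5d_T0"]], 1)
  expect_gt(or[["phq9_T0"]], 1)
  expect_gt(or[["bl_gp_visits"]], 1)
  expect_gt(or[["addictionTRUE"]], 1)
})

test_that("fixture tables satisfy their invariants and round-trip", {
  fx <- make_fixtures()
  expect_equal(score_eq5d_index("11111", fx$value_set), 1.0)
  expect_equal(score_eq5d_index("55555", fx$value_set), -0.661)
  expect_true(all(fx$unit_costs$unit_cost >= 0))
  expect_true(all(fx$unit_costs$price_year %in% fx$cpi$year))
  expect_true(all(fx$cpi$index > 0))
  dir <- withr::local_tempdir()
  write_fixtures(fx, dir)
  fx2 <- read_fixtures(dir)
  expect_equal(fx2$unit_costs, fx$unit_costs)
  expect_equal(fx2$labour$gross_day, fx$labour$gross_day)
})
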