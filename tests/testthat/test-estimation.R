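test_that("Rubin pooling reproduces the hand-computed identities", {
  # M identical fits: pooled result is the single fit, B = 0
  p1 <- rubin_pool(list(fake_fit(2, 0.5), fake_fit(2, 0.5)))
  expect_equal(p1$estimate, 2)
  expect_equal(p1$se, 0.5)
  expect_equal(p1$between, 0)
  # M = 2, estimates {1, 3}, each variance 1:
  # Qbar = 2, Wbar = 1, B = 2, T = 1 + 1.5 * 2 = 4, SE = 2
  p2 <- rubin_pool(list(fake_fit(1, 1), fake_fit(3, 1)))
  expect_equal(p2$estimate, 2)
  expect_equal(p2$within, 1)
  expect_equal(p2$between, 2)
  expect_equal(p2$total_var, 4)
  expect_equal(p2$se, 2)
  expect_true(p2$ci_low < 2 && 2 < p2$ci_high)
})

test_that("pooled intervals widen monotonically in the between-variance", {
  width <- sapply(c(0, 0.5, 1, 2), function(delta)
    diff(unlist(rubin_pool(list(fake_fit(2 - delta, 1),
                                fake_fit(2 + delta, 1)))[
                                  c("ci_low", "ci_high")])))
  expect_true(all(diff(width) > 0))
})

test_that("heterogeneous specifications cannot be pooled", {
  expect_error(rubin_pool(list(fake_fit(1, 1),
                               fake_fit(1, 1, family = "gamma-log"))),
               "heterogeneous")
})

test_that("with zero variance components the mixed fits match their fixed oracles", {
  # a draw with no configured cluster effects where the REML variance
  # estimates sit exactly on the zero boundary: the mixed fit must then
  # coincide with ordinary least squares
  df <- simulate_outcomes(n = 600, sd_practice = 0, sd_centre = 0,
                          seed = 10L)
  mixed <- fit_effect_model(df, "qaly", covariates = "age")
  expect_true(mixed$singular)
  ols <- lm(qaly ~ arm + age, data = df)
  expect_equal(mixed$terms$estimate,
               unname(coef(ols)[c("armgp", "armgp_plus_patient")]),
               tolerance = 1e-6)

  gm <- fit_cost_model(df, "cost", covariates = "age")
  glm_fit <- glm(cost ~ arm + age, data = df, family = Gamma(link = "log"))
  expect_equal(gm$terms$estimate,
               unname(coef(glm_fit)[c("armgp", "armgp_plus_patient")]),
               tolerance = 1e-3)
})

test_that("a constant cost outcome yields a null arm ratio", {
  df <- simulate_outcomes(n = 300, seed = 5L)
  df$cost <- 1000
  fit <- fit_cost_model(df, "cost", covariates = character())
  expect_equal(fit$terms$estimate, c(0, 0), tolerance = 1e-6)
  expect_equal(fit$terms$ratio, c(1, 1), tolerance = 1e-6)
})

test_that("zero totals are shifted, not dropped, under the gamma family", {
  df <- simulate_outcomes(n = 400, zero_prob = 0.1, seed = 6L)
  fit <- fit_cost_model(df, "cost", covariates = "age")
  expect_equal(fit$n_zero_shifted, sum(df$cost == 0))
  expect_true(all(is.finite(fit$terms$se)))
})

test_that("the two-part model collapses to the gamma model without zeros", {
  df <- simulate_outcomes(n = 400, seed = 7L)
  zi <- fit_zi_cost_model(df, "cost", covariates = "age")
  gm <- fit_cost_model(df, "cost", covariates = "age")
  expect_equal(zi$terms$estimate, gm$terms$estimate, tolerance = 1e-6)
  expect_equal(zi$family, "zero-inflated-gamma-log")
})

test_that("the two-part marginal mean formula matches Monte Carlo", {
  set.seed(8)
  pi0 <- 0.4; mu <- 500; shape <- 2
  y <- rgamma(1e6, shape, rate = shape / mu) * (runif(1e6) >= pi0)
  expect_equal(mean(y), (1 - pi0) * mu, tolerance = 0.005)
})

test_that("an injected baseline shift is detected, a constant is flagged", {
  tab <- small_trial()$tab
  tab$age <- tab$age + (tab$arm == "gp") * sd(tab$age)
  bal <- baseline_balance(tab)
  expect_lt(bal$p_gp[bal$variable == "age"], 0.001)
  tab2 <- small_trial()$tab
  tab2$insurance_plan <- FALSE
  bal2 <- baseline_balance(tab2)
  expect_true(is.na(bal2$p_gp[bal2$variable == "insurance_plan"]))
  expect_setequal(bal2$model[bal2$variable %in%
                               c("gender", "city_size")],
                  "multinomial")
})

test_that("payer and subgroup covariate sets follow the scenario rules", {
  expect_true("bl_sick_days" %in% model_covariates("societal"))
  expect_false("bl_sick_days" %in% model_covariates("payer"))
  sub <- model_covariates("societal", subgroup = TRUE)
  expect_false(any(c("pregnancy", "breastfeeding", "living_situation",
                     "city_size") %in% sub))
  expect_true("city_binary" %in% sub)
})
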