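test_that("ICERs classify the plane and guard the zero-effect ray", {
  r1 <- icer(100, 0.01)
  expect_equal(r1$icer, 10000)
  expect_equal(r1$quadrant, "trade-off NE")
  expect_equal(icer(-50, 0.02)$quadrant, "intervention dominant")
  r3 <- icer(25, 0)
  expect_true(is.na(r3$icer))
  expect_equal(r3$quadrant, "cost-minimisation")
  # swapping the comparator keeps the ratio, flips dominance
  a <- icer(-50, 0.02); b <- icer(50, -0.02)
  expect_equal(b$quadrant, "intervention dominated")
  expect_equal(icer(300, 0.03)$icer, icer(-300, -0.03)$icer)
})

test_that("net benefit is linear and anchored at lambda = 0", {
  expect_equal(net_benefit(1000, 0.5, 0), -1000)
  expect_equal(net_benefit(1000, 0.5, 10000), 4000)
  expect_equal(net_benefit(200, 0.3, 5000) + net_benefit(200, 0.3, 1000),
               2 * net_benefit(200, 0.3, 3000))
  expect_error(net_benefit(1, 1, -5), "lambda")
})

test_that("the half-p rule maps coefficients and p-values exactly", {
  expect_equal(ce_probability(0.8, 0.10), 0.95)
  expect_equal(ce_probability(-0.8, 0.10), 0.05)
  expect_equal(ce_probability(0, 1), 0.5)
  x <- ce_probability(rnorm(50), runif(50, 1e-6, 1))
  expect_true(all(x > 0 & x < 1))
  expect_error(ce_probability(1, 0), "p_value")
})

test_that("WTP grids default to the published ranges", {
  gq <- wtp_grid("QALY")
  expect_equal(gq$lambda, seq(0, 160000, 10000))
  expect_length(gq$lambda, 17L)
  gd <- wtp_grid("DFD")
  expect_equal(gd$lambda, seq(0, 200, 20))
  expect_length(gd$lambda, 11L)
  expect_error(wtp_grid("QALY", numeric()), "empty")
  expect_error(wtp_grid("QALY", c(0, 0)), "increasing")
})

test_that("at lambda = 0 the NBR equals the negated cost regression", {
  df <- simulate_outcomes(n = 450, seed = 10L)
  curve <- ceac(list(df), wtp_grid("QALY", lambda = 0), cost_col = "cost",
                effect_col = "qaly", covariates = "age")
  df$.negcost <- -df$cost
  ref <- fit_effect_model(df, ".negcost", covariates = "age")
  expect_equal(curve$coefficient, ref$terms$estimate, tolerance = 1e-6)
  expect_equal(curve$probability,
               ce_probability(ref$terms$estimate, ref$terms$p))
})

test_that("as lambda grows the NBR contrast approaches the effect model", {
  df <- simulate_outcomes(n = 450, qaly_shift_gp = 0.05, seed = 11L)
  lam <- 1e8
  curve <- ceac(list(df), wtp_grid("QALY", lambda = lam), cost_col = "cost",
                effect_col = "qaly", covariates = "age")
  eff <- fit_effect_model(df, "qaly", covariates = "age")
  expect_equal(curve$coefficient / lam, eff$terms$estimate,
               tolerance = 1e-3)
})

test_that("scenario bundles respect perspective and effect conventions", {
  st <- small_trial()
  stack <- mice_impute(st$tab_missing, M = 2L, iterations = 2L, seed = 5L)
  fx <- make_fixtures()
  base <- run_scenario(stack, "base_societal", fx, ceac_curves = FALSE)
  payer <- run_scenario(stack, "payer", fx, ceac_curves = FALSE)
  expect_false("cost_indirect" %in% payer$estimates$outcome)
  tabs <- lapply(stack$imputations, derive_outcomes, fixtures = fx)
  expect_true(all(tabs[[1]]$cost_payer <= tabs[[1]]$cost_societal))
  dfd <- run_scenario(stack, "dfd", fx, ceac_curves = FALSE)
  expect_true(all(dfd$icers$delta_effect > -360 &
                    dfd$icers$delta_effect < 360))
  expect_equal(unique(base$icers$comparison),
               c("gp vs none", "gp_plus_patient vs none",
                 "gp_plus_patient vs gp"))
})

test_that("complete-case on a complete dataset equals the base case", {
  st <- small_trial()
  stack <- mice_impute(st$tab, M = 2L, iterations = 2L, seed = 5L)
  fx <- make_fixtures()
  base <- suppressWarnings(
    run_scenario(stack, "base_societal", fx, ceac_curves = FALSE))
  cc <- suppressWarnings(
    run_scenario(stack, "complete_case", fx, tab_missing = st$tab,
                 ceac_curves = FALSE))
  expect_equal(cc$n, base$n)
  expect_equal(cc$estimates$estimate, base$estimates$estimate,
               tolerance = 1e-8)
})

test_that("a constant split variable reproduces the unsplit analysis", {
  st <- small_trial()
  stack <- mice_impute(st$tab, M = 2L, iterations = 2L, seed = 5L)
  for (m in 1:2) stack$imputations[[m]]$depression_history <- TRUE
  fx <- make_fixtures()
  sg <- suppressWarnings(
    run_subgroup(stack, "depression_history", "base_societal", fx,
                 ceac_curves = FALSE))
  expect_length(sg, 1L)
  # oracle: unsplit scenario with the same reduced covariate set
  sc <- scenario_config("base_societal")
  sc$covariates <- setdiff(model_covariates("societal", subgroup = TRUE),
                           "depression_history")
  unstack <- stack
  unstack$imputations <- lapply(stack$imputations, function(tt) {
    tt$city_binary <- tt$city_size == "city"; tt
  })
  ref <- run_scenario(unstack, sc, fx, ceac_curves = FALSE)
  expect_equal(sg[["TRUE"]]$estimates$estimate, ref$estimates$estimate,
               tolerance = 1e-8)
})
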