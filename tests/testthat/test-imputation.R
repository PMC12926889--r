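test_that("diagnostics report zero fractions and patterns on complete data", {
  tab <- small_trial()$tab
  rep <- missingness_diagnostics(tab)
  expect_true(all(rep$fractions == 0))
  expect_equal(nrow(rep$regressions), 0L)
  expect_equal(sum(rep$patterns$count), nrow(tab))
})

test_that("missing fractions are exact counts over rows", {
  tab <- small_trial()$tab_missing
  rep <- missingness_diagnostics(tab)
  expect_equal(rep$fractions[["eq5d_T2"]],
               sum(is.na(tab$eq5d_T2)) / nrow(tab))
  expect_true(all(rep$fractions >= 0 & rep$fractions < 1))
  expect_gt(nrow(rep$regressions), 0L)
})

test_that("a complete input yields M identical copies", {
  tab <- small_trial()$tab
  st <- mice_impute(tab, M = 4L, iterations = 2L, seed = 3L)
  expect_equal(st$M, 4L)
  for (m in 1:4) expect_identical(st$imputations[[m]], tab)
})

test_that("imputation preserves observed cells and respects types", {
  tab <- small_trial()$tab_missing
  st <- mice_impute(tab, M = 3L, iterations = 3L, seed = 3L)
  expect_length(st$imputations, 3L)
  for (m in 1:3) {
    cur <- st$imputations[[m]]
    expect_false(anyNA(cur[imputable_columns(cur)]))
    for (v in imputable_columns(tab)) {
      obs <- !is.na(tab[[v]])
      expect_identical(cur[[v]][obs], tab[[v]][obs])
      # PMM draws donor values, so imputations stay within observed range
      if (is.numeric(tab[[v]]))
        expect_true(all(cur[[v]] >= min(tab[[v]], na.rm = TRUE) &
                          cur[[v]] <= max(tab[[v]], na.rm = TRUE)))
    }
    expect_true(all(cur$phq9_T2 >= 0 & cur$phq9_T2 <= 27))
    expect_true(all(cur$gp_visit_T3 == round(cur$gp_visit_T3) &
                      cur$gp_visit_T3 >= 0))
    expect_type(cur$mini_depression_T1, "logical")
  }
})

test_that("the stack is fully determined by data, M, iterations and seed", {
  tab <- small_trial()$tab_missing
  s1 <- mice_impute(tab, M = 2L, iterations = 2L, seed = 12L)
  s2 <- mice_impute(tab, M = 2L, iterations = 2L, seed = 12L)
  s3 <- mice_impute(tab, M = 2L, iterations = 2L, seed = 13L)
  expect_identical(s1$imputations, s2$imputations)
  expect_false(identical(s1$imputations, s3$imputations))
})

test_that("missing design variables are rejected", {
  tab <- small_trial()$tab_missing
  tab$arm[3] <- NA
  expect_error(mice_impute(tab, M = 2L, seed = 1L), "design variables")
})

test_that("pooling a zero-between-variance stack equals a single fit", {
  tab <- derive_outcomes(small_trial()$tab)
  single <- fit_effect_model(tab, "qaly")
  pooled <- rubin_pool(list(single, single, single))
  expect_equal(pooled$estimate, single$terms$estimate)
  expect_equal(pooled$se, single$terms$se)
  expect_equal(pooled$between, c(0, 0))
  expect_equal(pooled$p, single$terms$p)
})
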