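vs <- default_value_set()

test_that("EQ-5D-5L index anchors and hand-summed states are reproduced", {
  expect_identical(score_eq5d_index("11111", vs), 1.0)
  expect_equal(score_eq5d_index("55555", vs), -0.661)
  # 21121: level-2 decrements for mobility (0.042) and pain (0.051)
  expect_equal(score_eq5d_index("21121", vs), 1 - 0.042 - 0.051)
  expect_equal(score_eq5d_index(c("11111", "55555"), vs), c(1, -0.661))
  expect_true(is.na(score_eq5d_index(NA_character_, vs)))
  expect_error(score_eq5d_index("11161", vs), "1..5")
  expect_error(score_eq5d_index("1111", vs), "5 digits")
})

test_that("the descriptive system enumerates 3125 states with a unique top", {
  states <- enumerate_eq5d_states()
  expect_length(states, 3125L)
  expect_length(unique(states), 3125L)
  idx <- score_eq5d_index(states, vs)
  expect_equal(sum(idx == 1), 1L)
  expect_equal(states[idx == 1], "11111")
  expect_equal(min(idx), -0.661)
})

test_that("PHQ-9 scoring sums items and validates input", {
  expect_equal(score_phq9(rep(0L, 9L)), 0)
  expect_equal(score_phq9(rep(3L, 9L)), 27)
  expect_equal(score_phq9(c(1, 2, 0, 3, 1, 1, 0, 2, 1)), 11)
  expect_error(score_phq9(rep(1, 8)), "9 items")
  expect_error(score_phq9(c(rep(1, 8), 4)), "0..3")
  m <- rbind(rep(1L, 9L), c(rep(2L, 8L), NA))
  expect_equal(score_phq9(m), c(9, NA))
})

test_that("severity bands partition 0-27 and classify the sample mean", {
  labs <- phq9_severity(0:27)
  expect_equal(as.integer(table(labs)[c("none/minimal", "mild", "moderate",
                                        "moderately severe", "severe")]),
               c(5L, 5L, 5L, 5L, 8L))
  expect_equal(phq9_severity(13.5), "moderate")
  expect_equal(phq9_severity(4), "none/minimal")
  expect_equal(phq9_severity(10), "moderate")
  expect_equal(phq9_severity(15), "moderately severe")
  expect_error(phq9_severity(28), "0, 27")
})

test_that("QALY AUC matches hand trapezoids and is linear in utility", {
  expect_equal(qaly_auc(rep(1, 4)), 360 / 365)
  expect_equal(qaly_auc(rep(0, 4)), 0)
  expect_equal(qaly_auc(c(0.5, 0.5, 0.7, 0.7)),
               (30 * 0.5 + 150 * 0.6 + 180 * 0.7) / 365)
  set.seed(1)
  u <- runif(4, -0.5, 1)
  expect_equal(qaly_auc(u + 0.1), qaly_auc(u) + 0.1 * 360 / 365)
  expect_true(is.na(qaly_auc(c(0.5, NA, 0.7, 0.7))))
})

test_that("DFD probability follows the piecewise-linear anchors", {
  expect_equal(dfd_probability(4), 1)
  expect_equal(dfd_probability(15), 0)
  expect_equal(dfd_probability(10), 0.5)
  # continuity at the anchors
  expect_equal(dfd_probability(5), dfd_probability(5 - 1e-9),
               tolerance = 1e-8)
  expect_equal(dfd_probability(15), dfd_probability(15 - 1e-9),
               tolerance = 1e-8)
  x <- seq(0, 27, by = 0.25)
  expect_true(all(diff(dfd_probability(x)) <= 0))
  expect_error(dfd_probability(-1), "0, 27")
})

test_that("DFD AUC handles constant and crossing trajectories exactly", {
  expect_equal(dfd_auc(rep(20, 4)), 0)
  expect_equal(dfd_auc(rep(0, 4)), 360)
  # one 30-day segment from 16 to 14: closed form gives 0.75 days
  expect_equal(dfd_auc(c(16, 14), reference_days = 30), 0.75)
  expect_true(is.na(dfd_auc(c(10, NA, 10, 10))))
})
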