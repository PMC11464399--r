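stratum_cohort <- function(values) {
  cohort_table(data.frame(
    participant_id = sprintf("p%d", seq_along(values)),
    sex = "female", birth_year = 1970, age = 6,
    nonhdl_c = values, stringsAsFactors = FALSE))
}

test_that("z-scoring maps {1,2,3} to {-1,0,1} and normalizes every stratum", {
  z <- zscore_by_age_sex(stratum_cohort(c(1, 2, 3)))
  expect_equal(z$measurements$nonhdl_c, c(-1, 0, 1))
  tab <- simulate_trajectories(200, seed = 6)
  z <- zscore_by_age_sex(tab)
  m <- z$measurements
  for (s in split(m$nonhdl_c, interaction(m$age, m$sex))) {
    expect_lt(abs(mean(s)), 1e-12)
    expect_lt(abs(sd(s) - 1), 1e-12)
  }
})

test_that("z-scoring a z-scored table is the identity and degenerate strata error", {
  tab <- simulate_trajectories(100, seed = 12)
  z1 <- zscore_by_age_sex(tab)
  z2 <- zscore_by_age_sex(z1)
  expect_equal(z2$measurements$nonhdl_c, z1$measurements$nonhdl_c,
               tolerance = 1e-12)
  expect_error(zscore_by_age_sex(stratum_cohort(c(2, 2, 2))),
               "standardization error")
})

test_that("life-stage aggregation is the stated arithmetic", {
  m <- expand.grid(age = c(6, 9, 12, 15, 18, 21, 24),
                   participant_id = c("a", "b"), stringsAsFactors = FALSE)
  m$sex <- "female"; m$birth_year <- 1970
  m$nonhdl_c <- c(0.3, 0.6, 0.9, 1, -1, 0.5, 0.7, rep(0, 7))
  tab <- cohort_table(m)
  attr(tab, "exposure_scale") <- "zscore"
  ex <- aggregate_life_stages(tab)
  a <- ex[ex$participant_id == "a", ]
  expect_equal(a$childhood, 0.6)
  expect_equal(a$adolescence, 0)
  expect_equal(a$young_adulthood, 0.6)
  b <- ex[ex$participant_id == "b", ]
  expect_equal(unlist(b[, 2:4]), c(childhood = 0, adolescence = 0,
                                   young_adulthood = 0))
  expect_identical(attr(ex, "scale"), "zscore")
})

test_that("aggregation names the participant and age that are missing", {
  tab <- simulate_trajectories(5, seed = 3)
  i <- which(tab$measurements$participant_id == "P00002" &
               tab$measurements$age == 15)
  tab$measurements$nonhdl_c[i] <- NA_real_
  expect_error(aggregate_life_stages(tab), "P00002.*15")
})

test_that("life-stage aggregates are invariant to within-stratum affine rescaling", {
  tab <- simulate_trajectories(80, seed = 21)
  ex1 <- aggregate_life_stages(zscore_by_age_sex(tab))
  warped <- tab
  m <- warped$measurements
  # a different affine map per (age, sex) stratum
  key <- interaction(m$age, m$sex)
  for (s in seq_along(levels(key))) {
    ix <- key == levels(key)[s]
    m$nonhdl_c[ix] <- m$nonhdl_c[ix] * (1 + s / 3) - s
  }
  warped$measurements <- m
  ex2 <- aggregate_life_stages(zscore_by_age_sex(warped))
  expect_equal(ex2$childhood, ex1$childhood, tolerance = 1e-10)
  expect_equal(ex2$young_adulthood, ex1$young_adulthood, tolerance = 1e-10)
})

test_that("trapezoidal AUC matches closed forms and is exact on piecewise-linear series", {
  mk <- function(ages, values) {
    cohort_table(data.frame(participant_id = "a", sex = "male",
                            birth_year = 1970, age = ages, bmi = values))
  }
  # constant c over [6, 24] -> 18 c
  expect_equal(covariate_auc(mk(c(6, 9, 12, 15, 18, 21, 24), rep(2.5, 7)),
                             "bmi", 6, 24)$auc_bmi, 18 * 2.5)
  # v(age) = age on {6, 15, 24} -> (24^2 - 6^2) / 2 = 270
  expect_equal(covariate_auc(mk(c(6, 15, 24), c(6, 15, 24)),
                             "bmi", 6, 24)$auc_bmi, 270)
  expect_error(covariate_auc(mk(6, 20), "bmi", 6, 24), "AUC error")
  # random piecewise-linear series: trapezoid equals the exact integral
  set.seed(99)
  for (r in 1:5) {
    ages <- sort(sample(6:24, 6))
    slope <- runif(1, -2, 2); icpt <- runif(1, 60, 80)
    v <- icpt + slope * ages
    exact <- icpt * (max(ages) - min(ages)) +
      slope * (max(ages)^2 - min(ages)^2) / 2
    expect_equal(covariate_auc(mk(ages, v), "bmi", 6, 24)$auc_bmi, exact,
                 tolerance = 1e-12)
  }
})

test_that("the covariate summary uses the stated age windows", {
  tab <- simulate_trajectories(20, seed = 14)
  cs <- build_covariate_summary(tab)
  expect_setequal(names(cs),
                  c("participant_id", "education_years",
                    "ever_smoked_before_24", "family_history_cvd",
                    "auc_bmi", "auc_hdl_c", "auc_sbp", "auc_glucose",
                    "auc_physical_activity"))
  # glucose/activity AUC over 9-24 (values absent before 9 by design)
  manual <- covariate_auc(tab, "glucose", 9, 24)
  expect_equal(cs$auc_glucose, manual$auc_glucose[match(cs$participant_id,
                                                        manual$participant_id)])
  expect_equal(nrow(cs), 20)
})
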