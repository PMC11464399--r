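noise_free_cohort <- function(n = 30, seed = 5) {
  simulate_trajectories(n, trajectory_params(random_cov = matrix(0, 3, 3),
                                             residual_sd = 0),
                        seed = seed, covariates = FALSE)
}

test_that("noise-free cubic data recover the generating coefficients to 1e-6", {
  p <- trajectory_params(random_cov = matrix(0, 3, 3), residual_sd = 0)
  tab <- noise_free_cohort()
  fit <- fit_igc(tab)
  expect_true(fit$converged)
  est <- unname(fit$fixed[c("(Intercept)", "a", "I(a^2)", "I(a^3)")])
  expect_equal(est, p$fixed_coeffs, tolerance = 1e-6)
  expect_equal(unname(fit$fixed[["male"]]), p$sex_offset, tolerance = 1e-6)
})

test_that("interpolation restores a deleted noise-free value and alters nothing observed", {
  p <- trajectory_params(random_cov = matrix(0, 3, 3), residual_sd = 0)
  tab <- noise_free_cohort()
  pid <- tab$measurements$participant_id[1]
  hole <- tab
  i <- which(hole$measurements$participant_id == pid & hole$measurements$age == 12)
  truth <- hole$measurements$nonhdl_c[i]
  hole$measurements$nonhdl_c[i] <- NA_real_
  fit <- fit_igc(hole)
  filled <- interpolate_missing(fit, hole)
  j <- which(filled$measurements$participant_id == pid & filled$measurements$age == 12)
  expect_equal(filled$measurements$nonhdl_c[j], truth, tolerance = 1e-6)
  expect_true(filled$measurements$imputed_by_igc[j])
  # observed subset bit-identical
  obs <- !is.na(hole$measurements$nonhdl_c)
  expect_identical(filled$measurements$nonhdl_c[obs],
                   hole$measurements$nonhdl_c[obs])
  expect_false(any(filled$measurements$imputed_by_igc[obs]))
})

test_that("a fully observed participant passes through unchanged", {
  tab <- simulate_trajectories(40, seed = 9)
  fit <- fit_igc(tab)
  filled <- interpolate_missing(fit, tab)
  expect_identical(filled$measurements$nonhdl_c, tab$measurements$nonhdl_c)
  expect_false(any(filled$measurements$imputed_by_igc))
})

test_that("a participant with no observations gets flagged population-level predictions", {
  tab <- simulate_trajectories(40, seed = 10)
  pid <- "P00003"
  rows <- tab$measurements$participant_id == pid
  tab$measurements$nonhdl_c[rows] <- NA_real_
  fit <- fit_igc(tab)
  filled <- interpolate_missing(fit, tab)
  got <- filled$measurements[filled$measurements$participant_id == pid &
                               filled$measurements$age == 12, ]
  a <- (12 - 15) / 10
  pop <- fit$fixed[["(Intercept)"]] + fit$fixed[["a"]] * a +
    fit$fixed[["I(a^2)"]] * a^2 + fit$fixed[["I(a^3)"]] * a^3 +
    ifelse(got$sex == "male", fit$fixed[["male"]], 0)
  expect_equal(got$nonhdl_c, unname(pop), tolerance = 1e-10)
  expect_true(got$imputed_by_igc)
})

test_that("identifiability preconditions are enforced", {
  tab <- simulate_trajectories(1, seed = 2)
  expect_error(fit_igc(tab), "identifiability")
  few <- simulate_trajectories(10, trajectory_params(wave_ages = c(6, 9, 12)),
                               seed = 2)
  expect_error(fit_igc(few), "4 distinct")
})

test_that("extrapolation beyond the fitted age range requires explicit consent", {
  tab <- simulate_trajectories(30, seed = 11)
  fit <- fit_igc(tab)
  expect_error(interpolate_missing(fit, tab, target_ages = c(6, 30)),
               "extrapolation")
  expect_silent(suppressMessages(
    interpolate_missing(fit, tab, target_ages = c(6, 30),
                        allow_extrapolation = TRUE)))
})

test_that("random-intercept variance is recovered across simulation replicates", {
  # truth: intercept s.d. 0.5 -> variance 0.25
  p <- trajectory_params(random_cov = diag(c(0.25, 0, 0)), residual_sd = 0.3)
  ests <- vapply(1:12, function(r) {
    tab <- simulate_trajectories(250, p, seed = 40 + r, covariates = FALSE)
    fit_igc(tab)$random_cov[1, 1]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.25), 3 * mc_se)
})

test_that("BLUP predictions agree with the direct GLS formula on a small instance", {
  p <- trajectory_params(random_cov = diag(c(0.3, 0.05, 0.02)),
                         residual_sd = 0.25)
  tab <- simulate_trajectories(5, p, seed = 77, covariates = FALSE)
  fit <- fit_igc(tab)
  # oracle: b_i = G Z_i' (Z_i G Z_i' + s2 I)^{-1} (y_i - X_i beta_hat),
  # with the fitted variance components and fixed effects held fixed
  m <- tab$measurements
  G <- fit$random_cov
  s2 <- fit$residual_var
  for (pid in unique(m$participant_id)) {
    rows <- m[m$participant_id == pid, ]
    a <- (rows$age - 15) / 10
    Z <- cbind(1, a, a^2)
    Xb <- fit$fixed[["(Intercept)"]] + fit$fixed[["a"]] * a +
      fit$fixed[["I(a^2)"]] * a^2 + fit$fixed[["I(a^3)"]] * a^3 +
      ifelse(rows$sex == "male", fit$fixed[["male"]], 0)
    V <- Z %*% G %*% t(Z) + s2 * diag(nrow(Z))
    b_oracle <- G %*% t(Z) %*% solve(V, rows$nonhdl_c - Xb)
    expect_equal(as.numeric(fit$ranef[pid, ]), as.numeric(b_oracle),
                 tolerance = 1e-4)
  }
})
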