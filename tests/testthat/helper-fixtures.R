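# Shared fixtures, all built in code.

# A tiny hand-written cohort: 2 participants x 3 waves.
tiny_cohort <- function() {
  m <- data.frame(
    participant_id = rep(c("a", "b"), each = 3),
    sex = rep(c("female", "male"), each = 3),
    birth_year = rep(c(1970, 1972), each = 3),
    age = rep(c(6, 9, 12), 2),
    total_chol = c(4.2, 4.4, 4.6, 4.0, 4.1, 4.3),
    hdl_c = c(1.2, 1.3, 1.3, 1.1, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
  o <- data.frame(
    participant_id = c("a", "b"),
    plaque_present = c(1, 0),
    plaque_area_mm2 = c(8.5, NA),
    education_years = c(14, 12),
    ever_smoked_before_24 = c(0, 1),
    family_history_cvd = c(0, 0),
    stringsAsFactors = FALSE
  )
  cohort_table(m, o)
}

# Point-mass posterior fit at given lifetime effect and weights. Weights
# quoted from printed tables may sum to 0.999/1.001 by rounding; renormalize.
point_mass_fit <- function(beta_life, weights, family = "relative_risk",
                           n_draws = 100) {
  weights <- weights / sum(weights)
  d <- cbind(alpha = rep(0, n_draws), beta_life = beta_life,
             w_childhood = weights[1], w_adolescence = weights[2],
             w_young_adulthood = weights[3])
  brlm_fit_from_draws(d, family = family)
}

# Exposure + outcome pair simulated under known truth, without missingness.
simulated_exposure_outcome <- function(n, seed, beta_life = log(1.22),
                                       weights = c(1, 1, 1) / 3,
                                       prevalence = 0.396) {
  tab <- simulate_trajectories(n, seed = seed)
  z <- zscore_by_age_sex(tab)
  ex <- aggregate_life_stages(z)
  out <- simulate_outcomes(ex, outcome_params(beta_life = beta_life,
                                              weights = weights,
                                              target_prevalence = prevalence),
                           seed = seed + 5000)
  list(exposures = ex, outcomes = out)
}

# Short-chain spec for tests that only need posterior means.
test_spec <- function(family = "relative_risk", seed = 99, chains = 2) {
  brlm_spec(family = family, chains = chains, warmup = 1500, draws = 1000,
            thin = 10, seed = seed)
}
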