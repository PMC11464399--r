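#' Trajectory-generator parameters
#'
#' Parameters of the synthetic non-HDL-C trajectory model: a cubic fixed
#' polynomial in age plus a sex offset, per-participant random (intercept,
#' age-slope, age-squared-slope) effects, and independent residual noise —
#' the same model family the individual growth-curve stage later fits.
#'
#' The default fixed curve rises from about 3.0 mmol/l at age 3 to about
#' 3.9 mmol/l at age 24, with males 0.15 mmol/l below females; the scale is
#' plausible for a young European cohort and is irrelevant to inference after
#' z-scoring. The polynomial is specified in the centered-and-scaled age
#' `a = (age - 15) / 10` for numerical conditioning.
#'
#' @param fixed_coeffs length-4 numeric: intercept, a, a^2, a^3 coefficients
#'   of the fixed curve (mmol/l) in the scaled age `a`.
#' @param sex_offset mmol/l added for males.
#' @param random_cov 3x3 symmetric positive semi-definite covariance of the
#'   per-participant random (intercept, a-slope, a^2-slope) effects.
#' @param residual_sd residual standard deviation (mmol/l), non-negative.
#' @param wave_ages integer measurement-wave ages.
#' @return a list of class `trajectory_params`.
#' @export
trajectory_params <- function(fixed_coeffs = c(3.55, 0.42, 0.35, -0.45),
                              sex_offset = -0.15,
                              random_cov = diag(c(0.36, 0.04, 0.01)),
                              residual_sd = 0.35,
                              wave_ages = c(3, 6, 9, 12, 15, 18, 21, 24)) {
  random_cov <- as.matrix(random_cov)
  if (!isTRUE(all.equal(random_cov, t(random_cov))) ||
      any(eigen(random_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("parameter error: random_cov must be symmetric positive semi-definite")
  }
  if (residual_sd < 0) stop("parameter error: residual_sd must be non-negative")
  structure(list(fixed_coeffs = fixed_coeffs, sex_offset = sex_offset,
                 random_cov = random_cov, residual_sd = residual_sd,
                 wave_ages = as.integer(wave_ages)),
            class = "trajectory_params")
}

#' Outcome-generator parameters
#'
#' Parameters of the synthetic outcome model. Plaque presence is generated
#' from a log-link Bernoulli ("true relative-risk" structure): risk_i =
#' exp(alpha + beta_life * sum_k w_k X_ik + gamma' C_i), so that `beta_life`
#' is a log relative risk recoverable by Poisson regression. Among
#' plaque-positive participants, log plaque area is Gaussian with the same
#' linear-predictor form. The intercept `alpha` is calibrated at generation
#' time so the marginal prevalence matches `target_prevalence` (default
#' 39.6%, the anchoring mid-adulthood plaque prevalence).
#'
#' @param beta_life lifetime effect per 1 s.d. of life-stage exposure, on the
#'   log-RR scale for plaque presence. Default `log(1.22)`.
#' @param weights 3-simplex of life-stage weights (childhood, adolescence,
#'   young adulthood); must be non-negative and sum to 1.
#' @param target_prevalence marginal plaque prevalence in (0, 1).
#' @param gamma named numeric of covariate coefficients (may be empty).
#' @param alpha_area,beta_life_area,sigma_area intercept, lifetime effect and
#'   residual s.d. of the log plaque-area model (area in mm2).
#' @param clip_risk if `TRUE`, risks above 1 are clipped to `1 - 1e-9`
#'   instead of raising a generation error. Off by default because silent
#'   clipping distorts the recoverable relative risk.
#' @return a list of class `outcome_params`.
#' @export
outcome_params <- function(beta_life = log(1.22),
                           weights = c(1, 1, 1) / 3,
                           target_prevalence = 0.396,
                           gamma = numeric(0),
                           alpha_area = log(8),
                           beta_life_area = 0.27,
                           sigma_area = 0.8,
                           clip_risk = FALSE) {
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    stop("parameter error: weights must be a non-negative 3-vector summing to 1")
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("parameter error: target_prevalence must lie in (0, 1)")
  }
  structure(list(beta_life = beta_life, weights = weights,
                 target_prevalence = target_prevalence, gamma = gamma,
                 alpha_area = alpha_area, beta_life_area = beta_life_area,
                 sigma_area = sigma_area, clip_risk = clip_risk),
            class = "outcome_params")
}

.scale_age <- function(age) (age - 15) / 10

.fixed_curve <- function(age, params, sex) {
  a <- .scale_age(age)
  mu <- params$fixed_coeffs[1] + params$fixed_coeffs[2] * a +
    params$fixed_coeffs[3] * a^2 + params$fixed_coeffs[4] * a^3
  mu + ifelse(sex == "male", params$sex_offset, 0)
}

#' Simulate longitudinal non-HDL-C trajectories
#'
#' Generates `n` participants (sexes balanced, birth years uniform over a
#' 16-year span) each measured at every wave age. The non-HDL-C value is the
#' fixed cubic curve plus the sex offset, the participant's random effects
#' evaluated at the scaled age, and independent Gaussian residual noise.
#' Covariate trajectories (BMI, SBP, glucose, physical activity) are
#' participant-level Gaussian curves correlated with the lipid random
#' intercept, giving the imputation stage realistic predictive structure.
#' Total and HDL cholesterol are back-filled consistently with
#' `nonhdl_c = total_chol - hdl_c`.
#'
#' @param n number of participants (>= 1).
#' @param params a [trajectory_params()].
#' @param seed integer seed; identical `(n, params, seed)` give identical
#'   tables.
#' @param birth_year_start first year of the 16-year birth-year span.
#' @param covariates if `TRUE` (default) simulate the covariate columns.
#' @return a `cohort_table` with measurements only (outcomes empty).
#' @export
simulate_trajectories <- function(n, params = trajectory_params(), seed = 1,
                                  birth_year_start = 1962, covariates = TRUE) {
  if (n < 1) stop("parameter error: n must be >= 1")
  stopifnot(inherits(params, "trajectory_params"))
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n))
  sex <- rep(c("female", "male"), length.out = n)
  birth_year <- birth_year_start + sample.int(16, n, replace = TRUE) - 1L
  # participant random effects b_i ~ N(0, random_cov)
  ev <- eigen(params$random_cov, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
  b <- matrix(rnorm(3 * n), n, 3) %*% rt
  ages <- params$wave_ages
  k <- length(ages)
  a <- .scale_age(ages)
  long <- data.frame(
    participant_id = rep(ids, each = k),
    sex = rep(sex, each = k),
    birth_year = rep(birth_year, each = k),
    age = rep(ages, times = n),
    stringsAsFactors = FALSE
  )
  fixed <- .fixed_curve(long$age, params, long$sex)
  # (n x k) participant-by-wave random contribution, flattened participant-major
  ranpart <- as.vector(t(b %*% rbind(rep(1, k), a, a^2)))
  noise <- if (params$residual_sd > 0) rnorm(n * k, 0, params$residual_sd) else 0
  long$nonhdl_c <- fixed + ranpart + noise
  # consistent total/HDL split: HDL around 1.4 mmol/l, weakly age-dependent
  hdl <- pmax(0.6, 1.45 - 0.1 * .scale_age(long$age) + rep(rnorm(n, 0, 0.15), each = k))
  long$hdl_c <- hdl
  long$total_chol <- long$nonhdl_c + hdl
  if (covariates) {
    # participant-level curves correlated with the lipid random intercept b1
    b1 <- rep(b[, 1], each = k)
    agec <- .scale_age(long$age)
    long$bmi <- pmax(12, 17.5 + 4.5 * agec + 1.2 * b1 +
                       rep(rnorm(n, 0, 1.8), each = k) + rnorm(n * k, 0, 0.8))
    long$sbp <- pmax(70, 112 + 8 * agec + 3 * b1 +
                       rep(rnorm(n, 0, 7), each = k) + rnorm(n * k, 0, 4))
    long$glucose <- pmax(2.5, 4.9 + 0.25 * agec + 0.15 * b1 +
                           rep(rnorm(n, 0, 0.3), each = k) + rnorm(n * k, 0, 0.25))
    long$physical_activity <- pmax(0.5, 9 - 0.8 * agec - 0.3 * b1 +
                                     rep(rnorm(n, 0, 1.5), each = k) +
                                     rnorm(n * k, 0, 1))
    # activity index collected from age 9 on
    long$glucose[long$age < 9] <- NA_real_
    long$physical_activity[long$age < 9] <- NA_real_
  }
  cohort_table(long)
}

#' Apply missing-completely-at-random missingness to measurement values
#'
#' Sets each value of the chosen columns independently to missing with the
#' given probability, keeping the participant rows themselves. This emulates
#' ragged wave attendance; the mechanism is MCAR, a stand-in for the unknown
#' attendance mechanism of real cohorts, and is labelled as such in the
#' returned table's `missingness` attribute.
#'
#' @param tab a `cohort_table`.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param variables measurement columns to censor (default `nonhdl_c`).
#' @return the censored table (attribute `missingness` records the mechanism).
#' @export
apply_missingness <- function(tab, rate, seed = 1, variables = "nonhdl_c") {
  if (rate < 0 || rate >= 1) stop("parameter error: rate must lie in [0, 1)")
  if (rate == 0) return(tab)
  set.seed(seed)
  m <- tab$measurements
  for (v in variables) {
    drop <- runif(nrow(m)) < rate
    m[[v]][drop] <- NA_real_
  }
  tab$measurements <- m
  attr(tab, "missingness") <- list(mechanism = "MCAR", rate = rate,
                                   variables = variables)
  tab
}

#' Simulate plaque outcomes from life-stage exposures
#'
#' Draws plaque presence from a log-link Bernoulli model whose linear
#' predictor is `alpha + beta_life * (w1*childhood + w2*adolescence +
#' w3*young_adulthood) + gamma'C`; `alpha` is calibrated so the marginal
#' prevalence equals `target_prevalence`. For plaque-positive participants,
#' log plaque area (mm2) is Gaussian around the analogous linear predictor.
#' Baseline covariates (education years, smoking before 24, family history)
#' are drawn per participant.
#'
#' @param exposures data frame of life-stage exposures as returned by
#'   [aggregate_life_stages()] (columns `participant_id`, `childhood`,
#'   `adolescence`, `young_adulthood`).
#' @param params an [outcome_params()].
#' @param seed integer seed.
#' @param covariates optional data frame of per-participant covariate values
#'   matching `names(params$gamma)`; required when `gamma` is non-empty.
#' @return a data frame of outcome records (one per participant).
#' @export
simulate_outcomes <- function(exposures, params = outcome_params(), seed = 1,
                              covariates = NULL) {
  stopifnot(inherits(params, "outcome_params"))
  set.seed(seed)
  n <- nrow(exposures)
  idx <- as.matrix(exposures[, c("childhood", "adolescence", "young_adulthood")]) %*%
    params$weights
  eta <- params$beta_life * as.vector(idx)
  if (length(params$gamma) > 0) {
    if (is.null(covariates)) {
      stop("parameter error: gamma supplied without covariate values")
    }
    C <- as.matrix(covariates[, names(params$gamma), drop = FALSE])
    eta <- eta + as.vector(C %*% params$gamma)
  }
  # calibrate alpha so mean risk = target prevalence
  alpha <- log(params$target_prevalence / mean(exp(eta)))
  risk <- exp(alpha + eta)
  if (any(risk > 1)) {
    if (params$clip_risk) {
      risk <- pmin(risk, 1 - 1e-9)
    } else {
      i <- which.max(risk)
      stop(sprintf("generation error: risk %.4g > 1 for participant %s (linear predictor %.4g); enable clip_risk or reduce effects",
                   risk[i], dQuote(exposures$participant_id[i]), alpha + eta[i]))
    }
  }
  plaque <- rbinom(n, 1, risk)
  eta_area <- params$alpha_area + params$beta_life_area * as.vector(idx)
  log_area <- eta_area + rnorm(n, 0, params$sigma_area)
  out <- data.frame(
    participant_id = exposures$participant_id,
    plaque_present = plaque,
    plaque_area_mm2 = ifelse(plaque == 1, exp(log_area), NA_real_),
    education_years = pmax(6, round(12 + rnorm(n, 0, 2.5))),
    ever_smoked_before_24 = rbinom(n, 1, 0.35),
    family_history_cvd = rbinom(n, 1, 0.25),
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  out
}
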