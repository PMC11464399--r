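#' Fit the individual growth-curve (IGC) model
#'
#' Fits the linear mixed-effects model used to interpolate missing exposure
#' measurements: a cubic fixed polynomial in age with sex as a main-effect
#' modifier, a per-participant random intercept and a quadratic random age
#' slope, and independent Gaussian residuals. Estimation is by restricted
#' maximum likelihood through [lme4::lmer()]. Age is centered and scaled as
#' `(age - 15) / 10` inside the optimizer to condition the cubic design; the
#' reported fixed coefficients are on this scaled-age basis with the raw-age
#' polynomial also provided.
#'
#' @param tab a `cohort_table` whose `nonhdl_c` column is the response (rows
#'   with missing response are dropped from the fit).
#' @param variable response column, default `"nonhdl_c"`.
#' @param sex_by_age if `TRUE`, add a sex-by-age interaction.
#' @param per_sex if `TRUE`, fit a separate model per sex (each without the
#'   sex term) and return a list of class `igc_model_list`.
#' @return an object of class `igc_model`: fixed effects, estimated random
#'   covariance, residual variance, per-participant predicted random effects
#'   (empirical BLUPs), log-likelihood and convergence flag.
#' @export
fit_igc <- function(tab, variable = "nonhdl_c", sex_by_age = FALSE,
                    per_sex = FALSE) {
  m <- tab$measurements
  obs <- m[!is.na(m[[variable]]), , drop = FALSE]
  if (length(unique(m$participant_id)) < 2 ||
      length(unique(obs$participant_id)) < 2) {
    stop("identifiability error: at least 2 participants with observations are required")
  }
  if (length(unique(obs$age)) < 4) {
    stop("identifiability error: a cubic age polynomial needs >= 4 distinct observed ages")
  }
  if (per_sex) {
    fits <- lapply(split(seq_len(nrow(m)), m$sex), function(ix) {
      sub <- tab
      sub$measurements <- m[ix, , drop = FALSE]
      sub$outcomes <- sub$outcomes[0, , drop = FALSE]
      fit_igc(sub, variable = variable, sex_by_age = FALSE, per_sex = FALSE)
    })
    return(structure(fits, class = "igc_model_list"))
  }
  d <- data.frame(
    y = obs[[variable]],
    a = .scale_age(obs$age),
    male = as.numeric(obs$sex == "male"),
    pid = obs$participant_id,
    stringsAsFactors = FALSE
  )
  two_sexes <- length(unique(d$male)) > 1
  fe <- "y ~ 1 + a + I(a^2) + I(a^3)"
  if (two_sexes) fe <- paste(fe, "+ male")
  if (two_sexes && sex_by_age) fe <- paste(fe, "+ male:a")
  form <- stats::as.formula(paste(fe, "+ (1 + a + I(a^2) | pid)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           optCtrl = list(maxfun = 1e5),
                                           check.conv.singular = "ignore",
                                           check.nobs.vs.nRE = "ignore"))
  ))
  # gradient-based convergence checks raise spurious alarms in the exact-fit
  # (residual variance -> 0) limit; the optimizer code is authoritative there
  exact_fit <- stats::sigma(fit)^2 < 1e-10 * stats::var(d$y)
  conv <- isTRUE(fit@optinfo$conv$opt == 0) &&
    (length(fit@optinfo$conv$lme4$messages) == 0 || exact_fit)
  vc <- lme4::VarCorr(fit)
  rc <- vc$pid[, , drop = FALSE]
  attr(rc, "stddev") <- NULL
  attr(rc, "correlation") <- NULL
  re <- lme4::ranef(fit)$pid  # per-participant BLUPs (intercept, a, a^2)
  fx <- lme4::fixef(fit)
  structure(list(
    fixed = fx,
    fixed_raw = .to_raw_age_poly(fx),
    random_cov = rc,
    residual_var = stats::sigma(fit)^2,
    ranef = re,
    variable = variable,
    sex_by_age = sex_by_age && two_sexes,
    has_sex = two_sexes,
    age_range = range(obs$age),
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv
  ), class = "igc_model")
}

# Convert coefficients in a = (age-15)/10 to the raw-age polynomial basis.
.to_raw_age_poly <- function(fx) {
  p <- c(fx[["(Intercept)"]], fx[["a"]], fx[["I(a^2)"]], fx[["I(a^3)"]])
  # substitute a = (age - 15)/10 into p0 + p1 a + p2 a^2 + p3 a^3
  out <- numeric(4)
  for (j in 0:3) {
    # p_j * ((age - 15)/10)^j expands via binomial theorem
    for (i in 0:j) {
      out[i + 1] <- out[i + 1] +
        p[j + 1] * choose(j, i) * (-15)^(j - i) / 10^j
    }
  }
  names(out) <- c("intercept", "age", "age2", "age3")
  out
}

#' @export
print.igc_model <- function(x, ...) {
  cat("<igc_model>", if (x$converged) "converged" else "NOT converged", "\n")
  cat("  fixed effects (scaled age):\n")
  print(round(x$fixed, 4))
  cat(sprintf("  residual s.d.: %.4f; random s.d.: %s\n",
              sqrt(x$residual_var),
              paste(round(sqrt(diag(x$random_cov)), 4), collapse = ", ")))
  invisible(x)
}

# Participant-level prediction at given ages: fixed curve + predicted
# random effects (zero for participants never seen by the fit).
.igc_predict <- function(model, pid, sex, ages) {
  a <- .scale_age(ages)
  fx <- model$fixed
  mu <- fx[["(Intercept)"]] + fx[["a"]] * a + fx[["I(a^2)"]] * a^2 +
    fx[["I(a^3)"]] * a^3
  if (model$has_sex && sex == "male") {
    mu <- mu + fx[["male"]]
    if (model$sex_by_age) mu <- mu + fx[["male:a"]] * a
  }
  if (pid %in% rownames(model$ranef)) {
    b <- as.numeric(model$ranef[pid, ])
    mu <- mu + b[1] + b[2] * a + b[3] * a^2
  }
  mu
}

#' Interpolate missing exposure values from a fitted IGC model
#'
#' For every (participant, target age) cell: an observed value is kept
#' unchanged, exactly; a missing one — including ages the participant never
#' attended — is filled with that participant's model prediction (fixed curve
#' plus their predicted random effects) and flagged in a new logical column
#' `imputed_by_igc`. Participants with no observations at all receive
#' population-level predictions (fixed curve plus sex term) and are flagged
#' likewise.
#'
#' @param model a converged `igc_model` (or `igc_model_list` from a per-sex
#'   fit).
#' @param tab the `cohort_table` the model was fitted to (or a compatible
#'   one).
#' @param target_ages ages at which values are required; must lie within the
#'   fitted age range unless `allow_extrapolation = TRUE`.
#' @param allow_extrapolation permit target ages outside the fitted range.
#' @return a `cohort_table` with complete `nonhdl_c` (or `model$variable`) at
#'   every target age and the `imputed_by_igc` flag column.
#' @export
interpolate_missing <- function(model, tab,
                                target_ages = c(6, 9, 12, 15, 18, 21, 24),
                                allow_extrapolation = FALSE) {
  if (inherits(model, "igc_model_list")) {
    parts <- lapply(names(model), function(sx) {
      sub <- tab
      keep <- tab$measurements$sex == sx
      sub$measurements <- tab$measurements[keep, , drop = FALSE]
      sub$outcomes <- tab$outcomes[0, , drop = FALSE]
      interpolate_missing(model[[sx]], sub, target_ages, allow_extrapolation)
    })
    meas <- do.call(rbind, lapply(parts, function(p) p$measurements))
    out <- cohort_table(meas, NULL)
    out$outcomes <- tab$outcomes
    validate_cohort(out)
    return(out)
  }
  stopifnot(inherits(model, "igc_model"))
  if (!model$converged) {
    stop("convergence error: refusing to interpolate from a non-converged IGC model")
  }
  if (!allow_extrapolation &&
      (min(target_ages) < model$age_range[1] ||
       max(target_ages) > model$age_range[2])) {
    stop(sprintf("extrapolation error: target ages outside fitted range [%g, %g]; set allow_extrapolation = TRUE to override",
                 model$age_range[1], model$age_range[2]))
  }
  v <- model$variable
  m <- tab$measurements
  m$imputed_by_igc <- FALSE
  per <- unique(m[, c("participant_id", "sex", "birth_year")])
  add <- list()
  for (i in seq_len(nrow(per))) {
    pid <- per$participant_id[i]
    rows <- which(m$participant_id == pid)
    have <- m$age[rows]
    # fill missing values at attended target ages
    need_fill <- rows[m$age[rows] %in% target_ages & is.na(m[[v]][rows])]
    if (length(need_fill) > 0) {
      m[[v]][need_fill] <- .igc_predict(model, pid, per$sex[i], m$age[need_fill])
      m$imputed_by_igc[need_fill] <- TRUE
    }
    # create rows for target ages never attended
    new_ages <- setdiff(target_ages, have)
    if (length(new_ages) > 0) {
      nr <- m[rep(rows[1], length(new_ages)), , drop = FALSE]
      nr[, setdiff(names(nr), c("participant_id", "sex", "birth_year", "age",
                                "imputed_by_igc"))] <- NA_real_
      nr$age <- new_ages
      nr[[v]] <- .igc_predict(model, pid, per$sex[i], new_ages)
      nr$imputed_by_igc <- TRUE
      add[[length(add) + 1]] <- nr
    }
  }
  if (length(add) > 0) m <- rbind(m, do.call(rbind, add))
  m <- m[order(m$participant_id, m$age), , drop = FALSE]
  rownames(m) <- NULL
  tab$measurements <- m
  validate_cohort(tab)
  tab
}
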