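#' Specification of a Bayesian relevant life-course exposure model fit
#'
#' The model regresses an outcome on a total lifetime effect multiplied by a
#' weighted sum of life-stage exposures, with the weights on the 3-simplex:
#' `eta_i = alpha + beta_life * (w1*X_child + w2*X_adol + w3*X_yadult) +
#' gamma'C_i`. For binary outcomes (`family = "relative_risk"`) a Poisson
#' likelihood with log link is used on the 0/1 outcome so that
#' `exp(beta_life)` is a relative risk; for continuous outcomes
#' (`family = "gaussian"`) the outcome is Gaussian around `eta` with residual
#' scale `sigma`.
#'
#' Priors: `beta_life ~ Cauchy(0, 2.5)`; `w ~ Dirichlet(1, 1, 1)`
#' (non-informative over the simplex); `alpha, gamma ~ Normal(0, 10)` (on
#' internally standardized covariates); `sigma ~ half-Cauchy(0, 2.5)`.
#'
#' Sampling uses the package's adaptive random-walk Metropolis sampler with
#' heavy thinning; `draws` is the number of retained draws per chain, taken
#' every `thin`-th post-warmup iteration. Convergence is gated on split-Rhat
#' and bulk effective sample size.
#'
#' @param family `"relative_risk"` or `"gaussian"`; a log-link Bernoulli
#'   sensitivity variant is available as `"bernoulli_log"`.
#' @param chains number of chains (>= 2).
#' @param warmup warmup iterations per chain.
#' @param draws retained draws per chain (>= 500).
#' @param thin post-warmup iterations per retained draw.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param concentration Dirichlet concentration over the stage weights.
#' @param beta_prior_scale Cauchy scale of the lifetime-effect prior.
#' @param nuisance_prior_sd Normal s.d. for intercept and covariate effects.
#' @param rhat_max,ess_min convergence gates.
#' @return a list of class `brlm_spec`.
#' @export
brlm_spec <- function(family = c("relative_risk", "gaussian", "bernoulli_log"),
                      chains = 4, warmup = 2000, draws = 1000, thin = 20,
                      seed = 2024, concentration = c(1, 1, 1),
                      beta_prior_scale = 2.5, nuisance_prior_sd = 10,
                      rhat_max = 1.01, ess_min = 400) {
  family <- match.arg(family)
  if (chains < 2) stop("specification error: at least 2 chains are required")
  if (draws < 500) stop("specification error: at least 500 retained draws per chain are required")
  if (any(concentration <= 0)) stop("specification error: Dirichlet concentration must be strictly positive")
  structure(list(family = family, chains = chains, warmup = warmup,
                 draws = draws, thin = thin, seed = as.integer(seed),
                 concentration = concentration,
                 beta_prior_scale = beta_prior_scale,
                 nuisance_prior_sd = nuisance_prior_sd,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "brlm_spec")
}

.stage_names <- c("childhood", "adolescence", "young_adulthood")

# Split-Rhat (Gelman et al.): each chain halved, potential scale reduction
# across the 2*chains half-sequences.
.split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n <- length(ch)
    h <- n %/% 2
    halves <- c(halves, list(ch[1:h], ch[(h + 1):(2 * h)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.mcmc_diagnostics <- function(chains) {
  pars <- colnames(chains[[1]])
  ml <- coda::as.mcmc.list(lapply(chains, coda::as.mcmc))
  ess <- coda::effectiveSize(ml)
  rhat <- vapply(pars, function(p) {
    .split_rhat(lapply(chains, function(ch) ch[, p]))
  }, numeric(1))
  data.frame(parameter = pars, rhat = unname(rhat), ess = unname(ess[pars]),
             row.names = NULL, stringsAsFactors = FALSE)
}

.new_brlm_fit <- function(draws, chains_list, diagnostics, converged, spec,
                          data_info) {
  structure(list(draws = draws, chains = chains_list,
                 diagnostics = diagnostics, converged = converged,
                 spec = spec, data = data_info),
            class = "brlm_fit")
}

#' Construct a fit object from externally supplied posterior draws
#'
#' Wraps a matrix of posterior draws as a `brlm_fit` so the summary,
#' classification and pooling machinery can operate on draws that did not
#' come from [fit_brlm()] — degenerate point-mass fixtures, draws imported
#' from another sampler, and similar.
#'
#' @param draws matrix with columns `alpha`, `beta_life`, `w_childhood`,
#'   `w_adolescence`, `w_young_adulthood` (plus optional `gamma_*`, `sigma`).
#'   Weight columns must be non-negative and sum to 1 per draw.
#' @param family outcome family the draws refer to.
#' @param scale exposure scale label (`"zscore"` or `"mmol_per_l"`).
#' @param n nominal sample size behind the draws.
#' @return a `brlm_fit` flagged as converged, with empty diagnostics.
#' @export
brlm_fit_from_draws <- function(draws,
                                family = c("relative_risk", "gaussian"),
                                scale = "zscore", n = NA_integer_) {
  family <- match.arg(family)
  draws <- as.matrix(draws)
  wcols <- paste0("w_", .stage_names)
  stopifnot(all(c("beta_life", wcols) %in% colnames(draws)))
  .check_simplex_draws(draws[, wcols, drop = FALSE])
  .new_brlm_fit(draws, NULL,
                data.frame(parameter = character(0), rhat = numeric(0),
                           ess = numeric(0)),
                converged = TRUE,
                spec = brlm_spec(family = family),
                data_info = list(n = n, family = family, scale = scale))
}

.check_simplex_draws <- function(w) {
  if (any(w < -1e-12) || any(abs(rowSums(w) - 1) > 1e-9)) {
    stop("invariant violation: weight draws off the simplex")
  }
  invisible(TRUE)
}

#' Fit the Bayesian relevant life-course exposure model
#'
#' Samples the posterior of the life-course model for one outcome. For
#' `family = "relative_risk"` the outcome is plaque presence (0/1) over all
#' matched participants, with a Poisson likelihood and log link so
#' `exp(beta_life)` is the lifetime relative risk per 1 s.d. (or 1 mmol/l)
#' of exposure. For `family = "gaussian"` the outcome is natural-log plaque
#' area among plaque-positive participants.
#'
#' Covariates are standardized internally (centered, unit s.d.) for sampler
#' conditioning and weak-prior calibration; reported `gamma` draws are
#' rescaled back to per-original-unit effects, and `alpha` refers to
#' covariates held at their sample means.
#'
#' Convergence is assessed by split-Rhat and bulk effective sample size on
#' every parameter; a failing fit is returned with `converged = FALSE` and a
#' warning — downstream summaries refuse it unless explicitly overridden.
#'
#' @param exposures life-stage exposure data frame from
#'   [aggregate_life_stages()].
#' @param outcomes outcome records (`participant_id`, `plaque_present`,
#'   `plaque_area_mm2`, ...).
#' @param covariates optional data frame (`participant_id` + numeric
#'   adjustment columns); must be complete — impute upstream.
#' @param spec a [brlm_spec()].
#' @param sample_prior if `TRUE`, sample the prior only (no likelihood);
#'   used for prior-predictive checks.
#' @return an object of class `brlm_fit`.
#' @export
fit_brlm <- function(exposures, outcomes, covariates = NULL,
                     spec = brlm_spec(), sample_prior = FALSE) {
  stopifnot(inherits(spec, "brlm_spec"))
  d <- merge(exposures,
             outcomes[, intersect(names(outcomes),
                                  c("participant_id", "plaque_present",
                                    "plaque_area_mm2"))],
             by = "participant_id")
  if (spec$family == "gaussian") {
    if (!"plaque_area_mm2" %in% names(d)) {
      stop("specification error: gaussian family requires plaque_area_mm2 in the outcomes")
    }
    d <- d[d$plaque_present == 1 & !is.na(d$plaque_area_mm2), , drop = FALSE]
    d$y <- log(d$plaque_area_mm2)
  } else {
    if (any(!d$plaque_present %in% c(0, 1))) {
      stop("specification error: relative-risk family requires a 0/1 outcome")
    }
    d$y <- d$plaque_present
  }
  cov_names <- character(0)
  cov_center <- numeric(0)
  cov_scale <- numeric(0)
  if (!is.null(covariates) && ncol(covariates) > 1) {
    d <- merge(d, covariates, by = "participant_id")
    cov_names <- setdiff(names(covariates), "participant_id")
  }
  need <- c("y", .stage_names, cov_names)
  cc <- complete.cases(d[, need, drop = FALSE])
  if (!all(cc)) {
    stop(sprintf("specification error: %d incomplete case(s) across exposures/outcome/covariates; impute upstream",
                 sum(!cc)))
  }
  n <- nrow(d)
  if (!sample_prior && n < 50) {
    stop(sprintf("specification error: n = %d is below the minimum of 50", n))
  }
  X <- as.matrix(d[, .stage_names])
  K <- ncol(X)
  if (length(cov_names) > 0) {
    C <- as.matrix(d[, cov_names, drop = FALSE])
    cov_center <- colMeans(C)
    cov_scale <- apply(C, 2, sd)
    if (any(cov_scale == 0)) {
      stop(sprintf("specification error: covariate %s is constant",
                   dQuote(cov_names[which(cov_scale == 0)[1]])))
    }
    C <- sweep(sweep(C, 2, cov_center), 2, cov_scale, "/")
  } else {
    C <- matrix(0, n, 0)
  }
  P <- ncol(C)
  fam_code <- match(spec$family,
                    c("relative_risk", "gaussian", "bernoulli_log")) - 1L
  gaussian <- spec$family == "gaussian"
  dpar <- 2L + (K - 1L) + P + as.integer(gaussian)

  init0 <- numeric(dpar)
  if (!sample_prior) {
    init0[1] <- if (gaussian) mean(d$y) else log(max(mean(d$y), 1 / n))
    if (gaussian) init0[dpar] <- log(max(sd(d$y), 1e-3))
  }
  par_names <- c("alpha", "beta_life", paste0("w_", .stage_names),
                 if (P > 0) paste0("gamma_", cov_names),
                 if (gaussian) "sigma")

  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch)
    init <- init0 + rnorm(dpar, 0, 0.1)
    raw <- .brlm_chain(X, C, d$y, fam_code, spec$concentration,
                       spec$nuisance_prior_sd, spec$beta_prior_scale,
                       spec$warmup, spec$draws * spec$thin, spec$thin,
                       init, sample_prior)
    chains[[ch]] <- .transform_draws(raw, K, P, cov_names, cov_scale,
                                     gaussian, par_names)
  }
  diagnostics <- .mcmc_diagnostics(chains)
  converged <- all(diagnostics$rhat <= spec$rhat_max) &&
    all(diagnostics$ess >= spec$ess_min)
  if (!converged && !sample_prior) {
    bad <- diagnostics[diagnostics$rhat > spec$rhat_max |
                         diagnostics$ess < spec$ess_min, ]
    warning(sprintf("convergence failure: %s (max Rhat %.3f, min ESS %.0f); fit flagged, summaries will refuse it",
                    paste(bad$parameter, collapse = ", "),
                    max(diagnostics$rhat), min(diagnostics$ess)))
  }
  draws <- do.call(rbind, chains)
  .check_simplex_draws(draws[, paste0("w_", .stage_names), drop = FALSE])
  .new_brlm_fit(draws, chains, diagnostics,
                converged = converged || sample_prior, spec = spec,
                data_info = list(
                  n = n, family = spec$family,
                  scale = if (is.null(attr(exposures, "scale"))) "zscore"
                          else attr(exposures, "scale"),
                  covariates = cov_names, sample_prior = sample_prior))
}

# Map raw sampler states to natural-scale named draws.
.transform_draws <- function(raw, K, P, cov_names, cov_scale, gaussian,
                             par_names) {
  n <- nrow(raw)
  z <- cbind(raw[, 3:(K + 1), drop = FALSE], 0)
  ez <- exp(z - apply(z, 1, max))
  w <- ez / rowSums(ez)
  out <- cbind(raw[, 1], raw[, 2], w)
  if (P > 0) {
    g <- raw[, (K + 2):(K + 1 + P), drop = FALSE]
    g <- sweep(g, 2, cov_scale, "/")  # back to per-original-unit effects
    out <- cbind(out, g)
  }
  if (gaussian) out <- cbind(out, exp(raw[, ncol(raw)]))
  colnames(out) <- par_names
  out
}

#' @export
print.brlm_fit <- function(x, ...) {
  cat(sprintf("<brlm_fit> family=%s, n=%s, %d draws, %s\n",
              x$data$family, x$data$n, nrow(x$draws),
              if (x$converged) "converged" else "NOT CONVERGED"))
  if (nrow(x$diagnostics) > 0) {
    cat(sprintf("  max split-Rhat %.3f, min bulk ESS %.0f\n",
                max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  }
  invisible(x)
}

.require_converged <- function(fit, allow_nonconverged) {
  if (!fit$converged && !allow_nonconverged) {
    stop("convergence error: fit did not pass the Rhat/ESS gates; pass allow_nonconverged = TRUE to summarize anyway")
  }
  invisible(TRUE)
}

.effect_summary <- function(v, scale, parameter) {
  data.frame(parameter = parameter, point = mean(v),
             ci_lo = unname(quantile(v, 0.025)),
             ci_hi = unname(quantile(v, 0.975)),
             scale = scale, stringsAsFactors = FALSE)
}

#' Summarize the lifetime effect
#'
#' Posterior mean and central 95% credible interval of the lifetime effect:
#' `exp(beta_life)` draws on the relative-risk scale for the binary-outcome
#' family, `beta_life` draws on the beta scale for the Gaussian family. The
#' effect is per 1 s.d. of life-stage exposure when the exposure scale is
#' `zscore`, per 1 mmol/l otherwise.
#'
#' @param fit a converged `brlm_fit` (or pooled fit).
#' @param allow_nonconverged summarize despite failed convergence gates.
#' @return a one-row data frame: `parameter`, `point`, `ci_lo`, `ci_hi`,
#'   `scale`.
#' @export
summarize_lifetime_effect <- function(fit, allow_nonconverged = FALSE) {
  .require_converged(fit, allow_nonconverged)
  b <- fit$draws[, "beta_life"]
  if (fit$data$family == "gaussian") {
    .effect_summary(b, "beta", "lifetime_effect")
  } else {
    .effect_summary(exp(b), "RR", "lifetime_effect")
  }
}

#' Summarize the life-stage relative weights
#'
#' Posterior mean and 95% credible interval of each stage weight, in percent.
#' The three posterior means sum to 100% (the weights live on the simplex in
#' every draw).
#'
#' @inheritParams summarize_lifetime_effect
#' @return a three-row data frame (childhood, adolescence, young adulthood)
#'   on the `weight_percent` scale.
#' @export
summarize_weights <- function(fit, allow_nonconverged = FALSE) {
  .require_converged(fit, allow_nonconverged)
  do.call(rbind, lapply(.stage_names, function(s) {
    .effect_summary(100 * fit$draws[, paste0("w_", s)], "weight_percent", s)
  }))
}

#' Summarize the life-stage-specific effects
#'
#' The stage-specific effect is the lifetime effect scaled by that stage's
#' relative weight, computed per posterior draw: `beta_life * w_k`, reported
#' as `exp(beta_life * w_k)` (a stage relative risk) for the binary-outcome
#' family. Because the weights sum to one, the stage relative risks multiply
#' to the lifetime relative risk within every draw (additively for the
#' Gaussian family).
#'
#' @inheritParams summarize_lifetime_effect
#' @return a three-row data frame of stage effects.
#' @export
life_stage_effects <- function(fit, allow_nonconverged = FALSE) {
  .require_converged(fit, allow_nonconverged)
  b <- fit$draws[, "beta_life"]
  rr <- fit$data$family != "gaussian"
  do.call(rbind, lapply(.stage_names, function(s) {
    eff <- b * fit$draws[, paste0("w_", s)]
    if (rr) .effect_summary(exp(eff), "RR", s)
    else .effect_summary(eff, "beta", s)
  }))
}
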