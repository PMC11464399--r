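#' Build a validated pipeline configuration
#'
#' Accepts a nested list (or a YAML/JSON file path) describing a full
#' analysis run and fills in defaults. Exactly one input mode is required:
#' `input = "simulate"` with a `simulate` block, or `input = "load"` with a
#' `load$path` pointing at cohort CSV files. The `model` block selects the
#' outcomes (`plaque_presence`, `log_plaque_area`), the adjustment sets
#' (`model1` = sex + year of birth; `model2` = model1 + covariate AUCs +
#' education + smoking + family history), the exposure scale and optional
#' sex stratification. All seeds are explicit — nothing is seeded from the
#' wall clock.
#'
#' @param config a list, or path of a YAML or JSON file.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      config <- yaml::read_yaml(config)
      # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore it
      if (is.list(config$simulate)) {
        names(config$simulate)[names(config$simulate) == "FALSE"] <- "n"
      }
      config
    }
  }
  stopifnot(is.list(config))
  def <- list(
    input = "simulate",
    simulate = list(n = 2000, seed = 11, missing_rate = 0.15,
                    lifetime_rr = 1.22, weights = c(1, 1, 1) / 3,
                    target_prevalence = 0.396, beta_life_area = 0.27,
                    covariate_missing_rate = 0.05,
                    outcome_seed = 12, missing_seed = 13),
    load = list(path = NULL),
    model = list(outcomes = "plaque_presence", adjustment = "model1",
                 exposure_scale = "zscore", stratify_by_sex = FALSE,
                 birth_year_categorical = FALSE),
    brlm = list(chains = 4, warmup = 2000, draws = 1000, thin = 20,
                seed = 2024),
    imputation = list(enabled = TRUE, m = 3, donor_k = 5, seed = 71),
    output_dir = NULL
  )
  cfg <- utils::modifyList(def, config)
  if (!cfg$input %in% c("simulate", "load")) {
    stop("config validation error: input must be \"simulate\" or \"load\"")
  }
  if (cfg$input == "load" && is.null(cfg$load$path)) {
    stop("config validation error: load mode requires load$path")
  }
  if (length(cfg$model$outcomes) == 0 ||
      !all(cfg$model$outcomes %in% c("plaque_presence", "log_plaque_area"))) {
    stop("config validation error: model$outcomes must select plaque_presence and/or log_plaque_area")
  }
  if (!all(cfg$model$adjustment %in% c("model1", "model2"))) {
    stop("config validation error: model$adjustment must be model1 and/or model2")
  }
  if (!cfg$model$exposure_scale %in% c("zscore", "mmol_per_l")) {
    stop("config validation error: exposure_scale must be zscore or mmol_per_l")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Simulate a full synthetic cohort per a pipeline configuration
#'
#' Generates complete exposure trajectories, derives the true life-stage
#' z-score exposures, draws plaque outcomes under the configured lifetime
#' relative risk and weight vector, then censors the exposure measurements
#' at the configured MCAR rate — so the analysis stages see realistic ragged
#' data while the outcomes were generated from the complete truth.
#'
#' @param cfg a [pipeline_config()] (or list coerced to one).
#' @return a `cohort_table` with measurements and outcomes.
#' @export
simulate_cohort <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  s <- cfg$simulate
  tab <- simulate_trajectories(s$n, trajectory_params(), seed = s$seed)
  z <- zscore_by_age_sex(tab)
  expo <- aggregate_life_stages(z)
  op <- outcome_params(beta_life = log(s$lifetime_rr),
                       weights = s$weights,
                       target_prevalence = s$target_prevalence,
                       beta_life_area = s$beta_life_area)
  out <- simulate_outcomes(expo, op, seed = s$outcome_seed)
  # MCAR holes in the baseline adjustment covariates, so the fully-adjusted
  # model sees the attrition / imputation problem real cohorts pose
  cmr <- s$covariate_missing_rate
  if (!is.null(cmr) && cmr > 0) {
    set.seed(s$missing_seed + 1L)
    for (cl in c("education_years", "ever_smoked_before_24",
                 "family_history_cvd")) {
      out[[cl]][runif(nrow(out)) < cmr] <- NA_real_
    }
  }
  tab$outcomes <- out
  validate_cohort(tab)
  if (s$missing_rate > 0) {
    tab <- apply_missingness(tab, s$missing_rate, seed = s$missing_seed)
  }
  tab
}

# Per-participant design covariates for the minimal adjustment set.
.participant_base <- function(tab) {
  per <- unique(tab$measurements[, c("participant_id", "sex", "birth_year")])
  data.frame(participant_id = per$participant_id,
             sex_male = as.numeric(per$sex == "male"),
             birth_year = per$birth_year,
             stringsAsFactors = FALSE)
}

.model_covariates <- function(tab, adjustment, birth_year_categorical = FALSE) {
  base <- .participant_base(tab)
  if (birth_year_categorical) {
    yrs <- sort(unique(base$birth_year))[-1]
    for (y in yrs) base[[paste0("birth_year_", y)]] <-
        as.numeric(base$birth_year == y)
    base$birth_year <- NULL
  }
  if (adjustment == "model1") return(base)
  merge(base, build_covariate_summary(tab), by = "participant_id")
}

#' Run the full life-course analysis pipeline
#'
#' Executes the stages in order: simulate or load the cohort; derive
#' non-HDL-C where needed; fit the individual growth-curve model and
#' interpolate the exposure at ages 6, 9, 12, 15, 18, 21 and 24;
#' standardize to age- and sex-specific z-scores (unless the per-1-mmol/l
#' scale is configured); average into life stages; assemble the adjustment
#' covariates, imputing missing covariates by predictive mean matching for
#' the fully-adjusted model when enabled (fits are then pooled across
#' imputations on the draw scale); fit the Bayesian relevant life-course
#' exposure model per requested outcome and adjustment set (plaque presence
#' over all participants; log plaque area among the plaque-positive); and
#' classify the posterior-mean weight vector against the life-course
#' hypotheses. Identical configuration and seeds give an identical report.
#'
#' @param cfg a [pipeline_config()] or coercible list / file path.
#' @return an `analysis_report`: per outcome-model cell the effect
#'   summaries, weight summaries, stage effects, classification, sample
#'   size and diagnostics, plus configuration provenance. Written to
#'   `output_dir/report.json` (and `table1.md` / `table1.csv`) when
#'   `output_dir` is set.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (cfg$input == "simulate") {
    .log_stage("simulate", "generating synthetic cohort (n = %d)", cfg$simulate$n)
    tab <- simulate_cohort(cfg)
  } else {
    .log_stage("load", "reading cohort from %s", cfg$load$path)
    tab <- read_cohort(cfg$load$path)
    tab <- derive_nonhdl(tab)
  }
  .log_stage("igc", "fitting individual growth-curve model")
  igc <- fit_igc(tab)
  filled <- interpolate_missing(igc, tab)
  if (cfg$model$exposure_scale == "zscore") {
    .log_stage("standardize", "age- and sex-specific z-scores")
    scaled <- zscore_by_age_sex(filled)
  } else {
    .log_stage("standardize", "per-1-mmol/l scale (no z-scoring)")
    scaled <- filled
    attr(scaled, "exposure_scale") <- "mmol_per_l"
  }
  expo <- aggregate_life_stages(scaled)

  grid <- expand.grid(outcome = cfg$model$outcomes,
                      adjustment = cfg$model$adjustment,
                      stringsAsFactors = FALSE)
  strata <- list(all = NULL)
  if (isTRUE(cfg$model$stratify_by_sex)) {
    strata <- list(all = NULL, female = "female", male = "male")
  }
  results <- list()
  for (g in seq_len(nrow(grid))) {
    outc <- grid$outcome[g]
    adj <- grid$adjustment[g]
    family <- if (outc == "plaque_presence") "relative_risk" else "gaussian"
    spec <- brlm_spec(family = family, chains = cfg$brlm$chains,
                      warmup = cfg$brlm$warmup, draws = cfg$brlm$draws,
                      thin = cfg$brlm$thin, seed = cfg$brlm$seed)
    covs <- .model_covariates(filled, adj, cfg$model$birth_year_categorical)
    for (sx in names(strata)) {
      keep_ids <- if (is.null(strata[[sx]])) expo$participant_id else {
        per <- .participant_base(tab)
        per$participant_id[(per$sex_male == 1) == (strata[[sx]] == "male")]
      }
      ex_s <- expo[expo$participant_id %in% keep_ids, , drop = FALSE]
      attr(ex_s, "scale") <- attr(expo, "scale")
      cv_s <- covs[covs$participant_id %in% keep_ids, , drop = FALSE]
      if (!is.null(strata[[sx]])) cv_s$sex_male <- NULL
      cell <- .fit_cell(ex_s, tab$outcomes, cv_s, spec, cfg, adj)
      nm <- paste(outc, adj, sx, sep = ".")
      .log_stage("fit", "%s: n = %d, lifetime %s = %.3f", nm, cell$n,
                 if (family == "relative_risk") "RR" else "beta",
                 cell$lifetime$point)
      results[[nm]] <- c(list(outcome = outc, adjustment = adj, stratum = sx),
                         cell)
    }
  }
  report <- structure(list(
    results = results,
    provenance = list(config = unclass(cfg),
                      package_version = as.character(utils::packageVersion("lifecourse")),
                      exposure_scale = attr(expo, "scale"))
  ), class = "analysis_report")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(.report_json(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_table(report, "markdown"),
               file.path(cfg$output_dir, "table1.md"))
    writeLines(render_table(report, "csv"),
               file.path(cfg$output_dir, "table1.csv"))
  }
  report
}

# Fit one outcome x adjustment cell, imputing + pooling when covariates
# have missing cells and imputation is enabled; complete-case otherwise.
.fit_cell <- function(exposures, outcomes, covariates, spec, cfg, adjustment) {
  num_cols <- setdiff(names(covariates), "participant_id")
  n_miss <- sum(is.na(covariates[num_cols]))
  pooled_m <- 1L
  if (n_miss > 0 && isTRUE(cfg$imputation$enabled)) {
    imp <- impute_pmm(covariates, m = cfg$imputation$m,
                      donor_k = cfg$imputation$donor_k,
                      seed = cfg$imputation$seed)
    fits <- lapply(seq_len(imp$m), function(j) {
      sp <- spec
      sp$seed <- spec$seed + 1000L * j
      fit_brlm(exposures, outcomes, imp$completed_tables[[j]], sp)
    })
    fit <- pool_draws(fits)
    pooled_m <- imp$m
  } else {
    if (n_miss > 0) {
      cc <- complete.cases(covariates[num_cols])
      covariates <- covariates[cc, , drop = FALSE]
      exposures <- exposures[exposures$participant_id %in%
                               covariates$participant_id, , drop = FALSE]
    }
    fit <- fit_brlm(exposures, outcomes, covariates, spec)
  }
  wts <- summarize_weights(fit)
  cls <- classify_lifecourse(wts$point / 100)
  list(
    n = fit$data$n,
    m_imputations = pooled_m,
    lifetime = summarize_lifetime_effect(fit),
    weights = wts,
    stage_effects = life_stage_effects(fit),
    classification = list(selected = cls$selected,
                          distances = as.list(cls$distances),
                          sensitive_flag = cls$sensitive_flag),
    archetype_probabilities = as.list(classify_lifecourse_draws(fit)),
    diagnostics = fit$diagnostics,
    fit = fit
  )
}

.report_json <- function(report) {
  res <- lapply(report$results, function(r) {
    r$fit <- NULL
    r$diagnostics <- as.list(r$diagnostics)
    r$lifetime <- as.list(r$lifetime)
    r$weights <- as.list(r$weights)
    r$stage_effects <- as.list(r$stage_effects)
    r
  })
  list(results = res, provenance = report$provenance)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d outcome x model cell(s)\n",
              length(x$results)))
  cat(render_table(x, "markdown"), sep = "\n")
  invisible(x)
}

.stage_labels <- c(childhood = "Childhood, 6 to 12 years",
                   adolescence = "Adolescence, 15 to 18 years",
                   young_adulthood = "Young adulthood, 21 to 24 years")

#' Render an analysis report as a results table
#'
#' Lays the report out in the conventional shape: one column block per
#' outcome-model cell, rows for the lifetime effect and the three life
#' periods, each showing the effect (RR or beta) with its 95% credible
#' interval and the relative weight in percent with its interval, and a
#' final line naming the selected life-course model. Effects are printed to
#' two decimals, weights to one.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param format `"markdown"` or `"csv"`.
#' @return a character vector of document lines.
#' @export
render_table <- function(report, format = c("markdown", "csv")) {
  format <- match.arg(format)
  if (length(report$results) == 0) stop("render error: empty report")
  fmt_eff <- function(s) sprintf("%.2f (%.2f-%.2f)", s$point, s$ci_lo, s$ci_hi)
  fmt_wt <- function(s) sprintf("%.1f (%.1f-%.1f)", s$point, s$ci_lo, s$ci_hi)
  rows <- c("Lifetime effect", unname(.stage_labels), "Life-course model", "n")
  cols <- lapply(report$results, function(r) {
    eff <- rbind(r$lifetime, r$stage_effects)
    c(paste0(fmt_eff(eff[1, ]), " | -"),
      vapply(2:4, function(i) paste0(fmt_eff(eff[i, ]), " | ",
                                     fmt_wt(r$weights[i - 1, ])),
             character(1)),
      r$classification$selected,
      as.character(r$n))
  })
  headers <- vapply(report$results, function(r) {
    lab <- if (r$outcome == "plaque_presence") "Carotid plaque (RR)"
           else "log plaque area (beta)"
    sprintf("%s, %s%s", lab, r$adjustment,
            if (r$stratum != "all") paste0(", ", r$stratum) else "")
  }, character(1))
  if (format == "markdown") {
    header <- paste0("| ", paste(c("", headers), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(headers) + 1), collapse = "|"), "|")
    body <- vapply(seq_along(rows), function(i) {
      paste0("| ", paste(c(rows[i], vapply(cols, `[`, character(1), i)),
                         collapse = " | "), " |")
    }, character(1))
    c(header, sep, body)
  } else {
    esc <- function(x) ifelse(grepl("[,\"]", x),
                              paste0('"', gsub('"', '""', x), '"'), x)
    header <- paste(c("row", esc(headers)), collapse = ",")
    body <- vapply(seq_along(rows), function(i) {
      paste(c(esc(rows[i]), esc(vapply(cols, `[`, character(1), i))),
            collapse = ",")
    }, character(1))
    c(header, body)
  }
}
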