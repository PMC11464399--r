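#' Age- and sex-specific z-score standardization
#'
#' Standardizes a measurement column within every (age, sex) stratum: the
#' output has sample mean 0 and sample standard deviation 1 (denominator
#' n - 1) in each stratum, which puts exposures measured at different ages
#' and for both sexes on a uniform per-1-s.d. metric. Standardization is
#' computed over all non-missing values present in the table — observed and
#' growth-curve-filled alike.
#'
#' @param tab a `cohort_table`.
#' @param variable measurement column to standardize (default `"nonhdl_c"`).
#' @return the table with `variable` replaced by its within-stratum z-score;
#'   attribute `zscore_strata` records the stratum means and s.d.s used.
#' @export
zscore_by_age_sex <- function(tab, variable = "nonhdl_c") {
  m <- tab$measurements
  v <- m[[variable]]
  key <- interaction(m$age, m$sex, drop = TRUE)
  strata <- list()
  for (s in levels(key)) {
    ix <- which(key == s & !is.na(v))
    if (length(ix) == 0) next
    if (length(unique(v[ix])) < 2) {
      stop(sprintf("standardization error: stratum %s has fewer than 2 distinct %s values",
                   dQuote(s), variable))
    }
    mu <- mean(v[ix]); sdev <- sd(v[ix])
    v[ix] <- (v[ix] - mu) / sdev
    strata[[s]] <- c(mean = mu, sd = sdev, n = length(ix))
  }
  m[[variable]] <- v
  tab$measurements <- m
  attr(tab, "zscore_strata") <- strata
  attr(tab, "exposure_scale") <- "zscore"
  tab
}

#' Average standardized exposures into life-stage summaries
#'
#' Collapses per-age values into the three canonical life stages:
#' childhood is the mean over ages 6, 9 and 12; adolescence over 15 and 18;
#' young adulthood over 21 and 24. Every participant must have a value
#' (observed or growth-curve-filled) at all seven ages.
#'
#' @param tab a `cohort_table` carrying z-scores (from
#'   [zscore_by_age_sex()]) or raw mmol/l values when the per-1-mmol/l
#'   analysis scale is wanted.
#' @param variable measurement column to aggregate.
#' @param stages named list of age sets defining the stages; the default is
#'   the canonical childhood/adolescence/young-adulthood partition.
#' @return a data frame (one row per participant) with columns
#'   `participant_id`, `childhood`, `adolescence`, `young_adulthood` and a
#'   `scale` attribute (`"zscore"` or `"mmol_per_l"`).
#' @export
aggregate_life_stages <- function(tab, variable = "nonhdl_c",
                                  stages = list(childhood = c(6, 9, 12),
                                                adolescence = c(15, 18),
                                                young_adulthood = c(21, 24))) {
  m <- tab$measurements
  need <- sort(unique(unlist(stages)))
  pids <- unique(m$participant_id)
  out <- data.frame(participant_id = pids, stringsAsFactors = FALSE)
  grid <- m[m$age %in% need & !is.na(m[[variable]]), ]
  # at most one value per (participant, age) by table validation
  wide <- tapply(grid[[variable]], list(grid$participant_id, grid$age), mean)
  missing_cells <- which(is.na(wide), arr.ind = TRUE)
  absent <- setdiff(pids, rownames(wide))
  if (nrow(missing_cells) > 0 || length(absent) > 0) {
    if (length(absent) > 0) {
      msg <- sprintf("participant %s at all ages", dQuote(absent[1]))
    } else {
      msg <- paste(sprintf("participant %s at age %s",
                           dQuote(rownames(wide)[missing_cells[, 1]]),
                           colnames(wide)[missing_cells[, 2]])[
                             seq_len(min(5, nrow(missing_cells)))],
                   collapse = "; ")
    }
    stop(sprintf("aggregation error: required ages missing after interpolation (%s)", msg))
  }
  wide <- wide[pids, as.character(need), drop = FALSE]
  for (st in names(stages)) {
    out[[st]] <- rowMeans(wide[, as.character(stages[[st]]), drop = FALSE])
  }
  scale <- attr(tab, "exposure_scale")
  attr(out, "scale") <- if (is.null(scale)) "mmol_per_l" else scale
  out
}

#' Trapezoidal area under a risk-factor trajectory
#'
#' Computes, per participant, the trapezoidal integral of a measurement
#' against age over the grid points available inside `[age_lo, age_hi]`.
#' These raw AUC summaries (not divided by the age span) serve as cumulative
#' covariate adjustments. At least two points inside the window are required
#' per participant.
#'
#' @param tab a `cohort_table`.
#' @param variable measurement column to integrate.
#' @param age_lo,age_hi integration window in years.
#' @return a data frame with columns `participant_id` and
#'   `auc_<variable>`.
#' @export
covariate_auc <- function(tab, variable, age_lo, age_hi) {
  m <- tab$measurements
  keep <- m$age >= age_lo & m$age <= age_hi & !is.na(m[[variable]])
  m <- m[keep, , drop = FALSE]
  pids <- unique(tab$measurements$participant_id)
  res <- vapply(pids, function(pid) {
    ix <- which(m$participant_id == pid)
    if (length(ix) < 2) {
      stop(sprintf("AUC error: participant %s has %d point(s) of %s in [%g, %g]; >= 2 required",
                   dQuote(pid), length(ix), variable, age_lo, age_hi))
    }
    ord <- ix[order(m$age[ix])]
    x <- m$age[ord]; y <- m[[variable]][ord]
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }, numeric(1))
  out <- data.frame(participant_id = pids, auc = unname(res),
                    stringsAsFactors = FALSE)
  names(out)[2] <- paste0("auc_", variable)
  out
}

#' Assemble the full adjustment-covariate summary table
#'
#' Builds the fully-adjusted model's covariate set: AUC of BMI, HDL-C and
#' systolic blood pressure over ages 6-24; AUC of blood glucose and physical
#' activity over ages 9-24 (the window in which the activity index is
#' collected); and the baseline outcome-record covariates (education years,
#' smoking before age 24, family history of cardiovascular disease).
#'
#' @param tab a `cohort_table` whose covariate trajectories are complete
#'   enough for the AUC windows (interpolate first if needed).
#' @return a data frame, one row per participant with an outcome record.
#' @export
build_covariate_summary <- function(tab) {
  out <- data.frame(participant_id = unique(tab$measurements$participant_id),
                    stringsAsFactors = FALSE)
  out <- merge(out,
               tab$outcomes[, c("participant_id", "education_years",
                                "ever_smoked_before_24", "family_history_cvd")],
               by = "participant_id", all.x = TRUE)
  aucs <- list(
    covariate_auc(tab, "bmi", 6, 24),
    covariate_auc(tab, "hdl_c", 6, 24),
    covariate_auc(tab, "sbp", 6, 24),
    covariate_auc(tab, "glucose", 9, 24),
    covariate_auc(tab, "physical_activity", 9, 24)
  )
  for (a in aucs) out <- merge(out, a, by = "participant_id", all.x = TRUE)
  out[order(out$participant_id), , drop = FALSE]
}
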