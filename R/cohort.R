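#' @useDynLib lifecourse, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef predict quantile rnorm rbinom runif rgamma sd var
#'   complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Canonical column orders for the two delimited-text schemas.
.measurement_cols <- c(
  "participant_id", "sex", "birth_year", "age", "total_chol", "hdl_c",
  "nonhdl_c", "bmi", "sbp", "glucose", "physical_activity"
)
.outcome_cols <- c(
  "participant_id", "plaque_present", "plaque_area_mm2", "education_years",
  "ever_smoked_before_24", "family_history_cvd"
)
.numeric_measurement_cols <- setdiff(.measurement_cols, c("participant_id", "sex"))
.positive_measurement_cols <- c(
  "total_chol", "hdl_c", "bmi", "sbp", "glucose", "physical_activity"
)

#' Construct a validated longitudinal cohort table
#'
#' A cohort table bundles long-format repeated measurements (one row per
#' participant-age) with at most one mid-adulthood outcome record per
#' participant. Lipid values are in mmol/l, blood pressure in mmHg, BMI in
#' kg/m2; `sex` is the literal string `"male"` or `"female"`.
#'
#' @param measurements data frame with columns `participant_id`, `sex`,
#'   `birth_year`, `age` and the optional numeric measurement columns
#'   `total_chol`, `hdl_c`, `nonhdl_c`, `bmi`, `sbp`, `glucose`,
#'   `physical_activity`. Missing values are `NA`.
#' @param outcomes optional data frame with columns `participant_id`,
#'   `plaque_present` (0/1), `plaque_area_mm2` (positive, present iff
#'   `plaque_present == 1`), and optional `education_years`,
#'   `ever_smoked_before_24`, `family_history_cvd`.
#' @return An object of class `cohort_table`: a list with elements
#'   `measurements` and `outcomes`.
#' @examples
#' m <- data.frame(participant_id = "p1", sex = "female", birth_year = 1970,
#'                 age = 6, total_chol = 4.4, hdl_c = 1.3)
#' cohort_table(m)
#' @export
cohort_table <- function(measurements, outcomes = NULL) {
  measurements <- .complete_columns(as.data.frame(measurements),
                                    .measurement_cols)
  if (is.null(outcomes)) {
    outcomes <- .complete_columns(
      data.frame(participant_id = character(0)), .outcome_cols)
  } else {
    outcomes <- .complete_columns(as.data.frame(outcomes), .outcome_cols)
  }
  tab <- structure(list(measurements = measurements, outcomes = outcomes),
                   class = "cohort_table")
  validate_cohort(tab)
  tab
}

.complete_columns <- function(df, cols) {
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA_real_, nrow(df))
  extra <- setdiff(names(df), cols)
  df[, c(cols, extra), drop = FALSE]
}

#' Validate a cohort table against its structural invariants
#'
#' Checks the record-level invariants (non-negative integer ages, strictly
#' positive measurement values where present, valid sex codes, at most one row
#' per participant-age, plaque area present exactly when plaque is present)
#' and the cross-table invariants (outcome participants appear in the
#' measurements; sex and birth year constant within participant).
#'
#' @param tab a `cohort_table`.
#' @return `tab`, invisibly, if valid; otherwise an error naming the offending
#'   rows.
#' @export
validate_cohort <- function(tab) {
  m <- tab$measurements
  o <- tab$outcomes
  if (nrow(m) > 0) {
    if (anyNA(m$participant_id) || anyNA(m$sex) || anyNA(m$age) ||
        anyNA(m$birth_year)) {
      stop("cohort schema error: participant_id, sex, birth_year and age are required in every measurement row")
    }
    bad_sex <- !m$sex %in% c("male", "female")
    if (any(bad_sex)) {
      stop(sprintf("cohort schema error: unknown sex code %s in measurement row(s) %s",
                   dQuote(m$sex[which(bad_sex)[1]]),
                   paste(head(which(bad_sex), 5), collapse = ", ")))
    }
    if (any(m$age < 0 | m$age != round(m$age))) {
      bad <- which(m$age < 0 | m$age != round(m$age))
      stop(sprintf("cohort schema error: age must be a non-negative integer (row(s) %s)",
                   paste(head(bad, 5), collapse = ", ")))
    }
    key <- paste(m$participant_id, m$age)
    if (anyDuplicated(key)) {
      stop(sprintf("cohort schema error: duplicate (participant, age) pair %s",
                   dQuote(key[anyDuplicated(key)])))
    }
    for (cl in .positive_measurement_cols) {
      v <- m[[cl]]
      if (any(!is.na(v) & v <= 0)) {
        stop(sprintf("cohort schema error: %s must be strictly positive where present (row %d)",
                     cl, which(!is.na(v) & v <= 0)[1]))
      }
    }
    # nonhdl_c is exempt from the positivity rule: downstream stages store
    # age/sex z-scores in place, which are legitimately negative
    per <- unique(m[, c("participant_id", "sex", "birth_year")])
    if (anyDuplicated(per$participant_id)) {
      pid <- per$participant_id[anyDuplicated(per$participant_id)]
      stop(sprintf("cohort schema error: sex/birth_year not constant within participant %s",
                   dQuote(pid)))
    }
  }
  if (nrow(o) > 0) {
    if (anyDuplicated(o$participant_id)) {
      stop("cohort schema error: more than one outcome record per participant")
    }
    if (!all(o$participant_id %in% m$participant_id)) {
      miss <- setdiff(o$participant_id, m$participant_id)
      stop(sprintf("cohort schema error: outcome participant %s has no measurements",
                   dQuote(miss[1])))
    }
    if (any(!o$plaque_present %in% c(0, 1))) {
      stop("cohort schema error: plaque_present must be 0 or 1")
    }
    has_area <- !is.na(o$plaque_area_mm2)
    if (any(has_area != (o$plaque_present == 1))) {
      bad <- which(has_area != (o$plaque_present == 1))[1]
      stop(sprintf("cohort schema error: plaque_area_mm2 must be present iff plaque_present (participant %s)",
                   dQuote(o$participant_id[bad])))
    }
    if (any(has_area & o$plaque_area_mm2 <= 0)) {
      stop("cohort schema error: plaque_area_mm2 must be strictly positive (log-area finite)")
    }
  }
  invisible(tab)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d measurements on %d participants, %d outcome records\n",
              nrow(x$measurements), length(unique(x$measurements$participant_id)),
              nrow(x$outcomes)))
  if (nrow(x$measurements) > 0) {
    cat("  ages:", paste(sort(unique(x$measurements$age)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' Reads the two-file comma-separated representation written by
#' [write_cohort()]: `measurements.csv` (long format, one row per
#' participant-age) and optionally `outcomes.csv`. Empty fields denote missing
#' values. The result is validated; malformed rows, duplicate
#' (participant, age) pairs and unknown sex codes raise schema errors naming
#' the offending row.
#'
#' @param path directory containing the CSV files, or the path of the
#'   measurements file itself.
#' @param measurements_file,outcomes_file file names used when `path` is a
#'   directory.
#' @return a validated [cohort_table()].
#' @export
read_cohort <- function(path, measurements_file = "measurements.csv",
                        outcomes_file = "outcomes.csv") {
  if (dir.exists(path)) {
    mpath <- file.path(path, measurements_file)
    opath <- file.path(path, outcomes_file)
  } else {
    mpath <- path
    opath <- file.path(dirname(path), outcomes_file)
  }
  if (!file.exists(mpath)) stop(sprintf("cohort I/O error: %s not found", mpath))
  m <- read.csv(mpath, stringsAsFactors = FALSE,
                colClasses = c(participant_id = "character", sex = "character"))
  need <- c("participant_id", "sex", "birth_year", "age")
  if (!all(need %in% names(m))) {
    stop(sprintf("cohort schema error: measurements header must contain %s",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  }
  for (cl in intersect(.numeric_measurement_cols, names(m))) {
    m[[cl]] <- as.numeric(m[[cl]])
  }
  o <- NULL
  if (file.exists(opath)) {
    o <- read.csv(opath, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
    for (cl in intersect(.outcome_cols[-1], names(o))) {
      o[[cl]] <- as.numeric(o[[cl]])
    }
  }
  cohort_table(m, o)
}

#' Write a cohort to delimited text files
#'
#' Writes UTF-8 comma-separated text with a stable column order and empty
#' fields (not the text "NA" or "NaN") for missing values, so that
#' `read_cohort(write_cohort(tab, d))` reproduces `tab` exactly.
#'
#' @param tab a `cohort_table`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  validate_cohort(tab)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop(sprintf("cohort I/O error: cannot create %s", path))
  write.csv(tab$measurements[, .measurement_cols],
            file.path(path, "measurements.csv"), row.names = FALSE, na = "")
  write.csv(tab$outcomes[, .outcome_cols],
            file.path(path, "outcomes.csv"), row.names = FALSE, na = "")
  invisible(path)
}

#' Derive non-HDL cholesterol from total and HDL cholesterol
#'
#' Non-HDL-C is total serum cholesterol minus HDL cholesterol (mmol/l). Rows
#' already carrying a `nonhdl_c` value are left unchanged; rows with both
#' `total_chol` and `hdl_c` present get the difference. HDL exceeding total
#' cholesterol is a validation error; an exactly-zero difference is retained
#' but flagged with a warning as biologically suspicious.
#'
#' @param tab a `cohort_table`.
#' @return the table with `nonhdl_c` filled in. Idempotent.
#' @export
derive_nonhdl <- function(tab) {
  m <- tab$measurements
  todo <- is.na(m$nonhdl_c) & !is.na(m$total_chol) & !is.na(m$hdl_c)
  if (any(todo)) {
    d <- m$total_chol[todo] - m$hdl_c[todo]
    if (any(d < 0)) {
      i <- which(todo)[which(d < 0)[1]]
      stop(sprintf("validation error: hdl_c (%.3g) exceeds total_chol (%.3g) for participant %s at age %d",
                   m$hdl_c[i], m$total_chol[i], dQuote(m$participant_id[i]), m$age[i]))
    }
    if (any(d == 0)) {
      warning(sprintf("%d row(s) with non-HDL-C exactly 0 (total_chol == hdl_c); retained but suspicious",
                      sum(d == 0)))
    }
    m$nonhdl_c[todo] <- d
  }
  tab$measurements <- m
  tab
}
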