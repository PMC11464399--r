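#' Multiple imputation by chained-equation predictive mean matching
#'
#' Fills missing cells of a numeric covariate table with observed donor
#' values, m times. For each target column a linear predictive model on the
#' remaining columns is fitted to the observed rows; per imputation the
#' coefficients are perturbed by refitting under Bayesian-bootstrap row
#' weights (Dirichlet(1,...,1) over the observed rows), which propagates
#' model uncertainty and gives proper between-imputation variability. Each
#' missing cell then receives the observed value of a donor drawn uniformly
#' from the `donor_k` observed rows whose (unperturbed-model) predicted
#' means are nearest the cell's perturbed-model prediction — classical
#' type-1 matching, so no value is ever fabricated. Columns are visited in
#' order of descending missingness and the chained equations are cycled 5
#' times per imputation.
#'
#' @param covariates data frame: `participant_id` plus numeric columns, some
#'   with `NA` cells. At least one column must be fully observed; every
#'   column with missing cells must have at least `donor_k` observed values.
#' @param m number of imputations (default 3).
#' @param donor_k donor-pool size (default 5).
#' @param seed integer seed.
#' @param cycles chained-equation cycles per imputation.
#' @return an object of class `imputation_set`: `completed_tables` (list of
#'   m completed data frames), `m`, `donor_k`, `seed`, `missing_mask`.
#' @export
impute_pmm <- function(covariates, m = 3, donor_k = 5, seed = 1, cycles = 5) {
  stopifnot(is.data.frame(covariates), "participant_id" %in% names(covariates))
  num_cols <- setdiff(names(covariates), "participant_id")
  dat <- as.data.frame(lapply(covariates[num_cols], as.numeric))
  n <- nrow(dat)
  mask <- is.na(dat)
  n_miss <- colSums(mask)
  targets <- num_cols[n_miss > 0]
  if (any(n_miss == n)) {
    stop(sprintf("imputation error: column %s is entirely missing",
                 dQuote(num_cols[which(n_miss == n)[1]])))
  }
  if (length(targets) > 0 && !any(n_miss == 0)) {
    stop("imputation error: at least one fully observed predictor column is required")
  }
  short <- targets[n - n_miss[targets] < donor_k]
  if (length(short) > 0) {
    stop(sprintf("imputation error: column %s has fewer than donor_k = %d observed values",
                 dQuote(short[1]), donor_k))
  }
  targets <- targets[order(-n_miss[targets])]  # descending missingness

  set.seed(seed)
  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    cur <- dat
    # initialize missing cells with random observed draws from their column
    for (j in targets) {
      obs <- which(!mask[, j])
      cur[[j]][mask[, j]] <- sample(cur[[j]][obs], n_miss[j], replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (j in targets) {
        obs <- which(!mask[, j])
        mis <- which(mask[, j])
        preds <- setdiff(num_cols, j)
        Xall <- cbind(1, as.matrix(cur[preds]))
        yobs <- cur[[j]][obs]
        # unperturbed fit on observed rows
        bhat <- .safe_lm(Xall[obs, , drop = FALSE], yobs)
        # Bayesian-bootstrap perturbed fit
        wts <- rgamma(length(obs), 1, 1)
        bstar <- .safe_lm(Xall[obs, , drop = FALSE], yobs, wts / sum(wts))
        yhat_obs <- Xall[obs, , drop = FALSE] %*% bhat
        yhat_mis <- Xall[mis, , drop = FALSE] %*% bstar
        for (i in seq_along(mis)) {
          dd <- abs(yhat_obs - yhat_mis[i])
          pool <- obs[order(dd)[seq_len(donor_k)]]
          cur[[j]][mis[i]] <- cur[[j]][pool[sample.int(donor_k, 1)]]
        }
      }
    }
    out <- covariates
    for (j in targets) out[[j]] <- cur[[j]]  # non-target columns untouched
    completed[[imp]] <- out
  }
  structure(list(completed_tables = completed, m = m, donor_k = donor_k,
                 seed = seed, missing_mask = mask),
            class = "imputation_set")
}

# Weighted least squares with a pseudoinverse fallback for collinear designs.
.safe_lm <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  XtW <- t(X * w)
  A <- XtW %*% X
  b <- XtW %*% y
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-10
    out <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  }
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m=%d, donor_k=%d, %d missing cell(s) over %d column(s)\n",
              x$m, x$donor_k, sum(x$missing_mask),
              sum(colSums(x$missing_mask) > 0)))
  invisible(x)
}

#' Pool posterior draws across imputations
#'
#' Concatenates the posterior draws of per-imputation model fits into one
#' draw set; means and credible intervals are then taken over the pooled
#' draws (not combined by Rubin's rules — pooling happens on the draw scale,
#' so between-imputation variability widens the pooled posterior directly).
#'
#' @param fits list of `brlm_fit` objects fitted to the m completed tables
#'   under an identical model specification; all must have converged.
#' @return a `brlm_pooled` object (inherits `brlm_fit`); all summary,
#'   stage-effect and classification functions operate on it unchanged.
#' @export
pool_draws <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "brlm_fit")))
  bad <- which(!vapply(fits, function(f) f$converged, TRUE))
  if (length(bad) > 0) {
    stop(sprintf("pooling error: non-converged fit(s) at position(s) %s",
                 paste(bad, collapse = ", ")))
  }
  ref <- fits[[1]]
  same <- vapply(fits[-1], function(f) {
    identical(f$spec[setdiff(names(f$spec), "seed")],
              ref$spec[setdiff(names(ref$spec), "seed")]) &&
      identical(colnames(f$draws), colnames(ref$draws)) &&
      identical(f$data$family, ref$data$family)
  }, TRUE)
  if (!all(same)) {
    stop(sprintf("pooling error: model specification mismatch at position(s) %s",
                 paste(which(!same) + 1, collapse = ", ")))
  }
  pooled <- do.call(rbind, lapply(fits, function(f) f$draws))
  out <- .new_brlm_fit(pooled, NULL,
                       do.call(rbind, lapply(fits, function(f) f$diagnostics)),
                       converged = TRUE, spec = ref$spec,
                       data_info = ref$data)
  out$m <- length(fits)
  out$per_imputation_diagnostics <- lapply(fits, function(f) f$diagnostics)
  class(out) <- c("brlm_pooled", class(out))
  out
}
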