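.archetypes <- function() {
  rbind(accumulation = c(1, 1, 1) / 3,
        critical_childhood = c(1, 0, 0),
        critical_adolescence = c(0, 1, 0),
        critical_young_adulthood = c(0, 0, 1))
}

.check_simplex_point <- function(w, tol = 1e-6) {
  w <- as.numeric(w)
  if (length(w) != 3 || any(w < -tol) || abs(sum(w) - 1) > tol) {
    stop("input error: weights must be a non-negative 3-vector summing to 1")
  }
  w
}

#' Classify a fitted weight vector against life-course hypotheses
#'
#' Computes the Euclidean distance from a 3-simplex weight vector to the
#' archetype vectors of the competing life-course hypotheses — accumulation
#' `(1/3, 1/3, 1/3)` (every stage contributes equally) and the three critical
#' models `(1,0,0)`, `(0,1,0)`, `(0,0,1)` (only one stage matters) — and
#' selects the nearest. Ties are broken toward accumulation, then stage
#' order, and flagged.
#'
#' A "sensitive" pattern (unequal but non-degenerate weights) has no point
#' archetype; when the accumulation distance exceeds `sensitive_threshold`
#' yet accumulation is still the nearest archetype, the result carries a
#' descriptive `sensitive_flag` rather than a different selection.
#'
#' @param weights a 3-simplex vector (childhood, adolescence, young
#'   adulthood), e.g. posterior-mean weights.
#' @param sensitive_threshold accumulation-distance threshold for the
#'   descriptive sensitive flag.
#' @return a list of class `lifecourse_classification`: `distances` (named),
#'   `selected`, `weights_used`, `tie`, `sensitive_flag`.
#' @export
classify_lifecourse <- function(weights, sensitive_threshold = 0.25) {
  w <- .check_simplex_point(weights)
  arch <- .archetypes()
  d <- sqrt(rowSums(sweep(arch, 2, w)^2))
  sel <- names(d)[which.min(d)]  # which.min: first minimum, in archetype order
  tie <- sum(abs(d - min(d)) < 1e-12) > 1
  structure(list(
    distances = d,
    selected = sel,
    weights_used = setNames(w, .stage_names),
    tie = tie,
    sensitive_flag = sel == "accumulation" && d[["accumulation"]] > sensitive_threshold
  ), class = "lifecourse_classification")
}

#' @export
print.lifecourse_classification <- function(x, ...) {
  cat(sprintf("<lifecourse_classification> selected: %s%s%s\n", x$selected,
              if (x$tie) " (tie)" else "",
              if (x$sensitive_flag) " [sensitive pattern flagged]" else ""))
  print(round(x$distances, 4))
  invisible(x)
}

#' Classify per posterior draw
#'
#' Applies [classify_lifecourse()] to every posterior weight draw of a fit
#' and reports the posterior probability of each archetype being nearest —
#' an uncertainty-aware companion to the point classification, useful when
#' the weight credible intervals are wide and overlapping.
#'
#' @param fit a `brlm_fit`.
#' @return named numeric of posterior archetype probabilities.
#' @export
classify_lifecourse_draws <- function(fit) {
  arch <- .archetypes()
  w <- fit$draws[, paste0("w_", .stage_names), drop = FALSE]
  d2 <- sapply(seq_len(nrow(arch)), function(k) {
    rowSums(sweep(w, 2, arch[k, ])^2)
  })
  sel <- max.col(-d2, ties.method = "first")
  tab <- tabulate(sel, nbins = nrow(arch)) / nrow(w)
  setNames(tab, rownames(arch))
}

#' Map simplex weights to ternary-plot coordinates
#'
#' Planar coordinates for composition plots: childhood at the origin,
#' adolescence at (1, 0), young adulthood at (1/2, sqrt(3)/2); a weight
#' vector `(w1, w2, w3)` maps to `x = w2 + w3/2`, `y = (sqrt(3)/2) w3`.
#' The map is a bijection from the simplex onto the reference triangle.
#'
#' @param weights a 3-simplex vector, or a matrix with one vector per row.
#' @return a numeric `c(x, y)`, or a two-column matrix for matrix input.
#' @export
ternary_coordinates <- function(weights) {
  if (is.matrix(weights)) {
    return(t(apply(weights, 1, ternary_coordinates)))
  }
  w <- .check_simplex_point(weights)
  c(x = w[2] + w[3] / 2, y = sqrt(3) / 2 * w[3])
}
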