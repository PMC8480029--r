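# Performance indicators for a known-predictor set against the true
# data-generating mechanism: exact recovery (MSF), superset recovery
# (TPR), superset of the five strongest predictors (DMSF), false
# positive/negative counts, and the out-of-sample MSPE.

#' Score a known-predictor set against the truth
#'
#' Computes the per-replication ingredients of the performance
#' indicators: whether the set equals the true predictor set exactly
#' (MSF), contains all true predictors (TPR), contains the five
#' predictors with the largest absolute standardized coefficients (DMSF),
#' and how many of the non-predictors it wrongly includes / true
#' predictors it wrongly excludes.
#'
#' @param known A `known_set` from [combine_evidence()].
#' @param spec The [generator_spec()] defining the truth.
#'
#' @return A one-row tibble with columns `exact_match`,
#'   `superset_of_truth`, `superset_of_top5`, `n_false_positives`,
#'   `n_false_negatives`.
#' @export
score_selection <- function(known, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!setequal(known$variable, spec$variables)) {
    abort("known set and generator disagree on candidate names")
  }
  mask <- setNames(known$known, known$variable)[spec$variables]
  score_mask(mask, compile_spec(spec))
}

score_mask <- function(mask, cs) {
  in_true <- mask[cs$true_idx]
  fp <- sum(mask[cs$none_idx])
  fn <- sum(!in_true)
  tibble(
    exact_match = all(in_true) && fp == 0,
    superset_of_truth = all(in_true),
    superset_of_top5 = all(mask[cs$top5_idx]),
    n_false_positives = fp,
    n_false_negatives = fn
  )
}

#' Mean squared prediction error of a known-predictor set
#'
#' Draws a fresh "current" study, fits OLS with intercept on the known
#' predictors (intercept-only when the set is empty), draws a fresh
#' validation study and returns the mean squared difference between the
#' observed and predicted outcome.
#'
#' @inheritParams score_selection
#' @param n_current Sample size of the current study used for estimation.
#' @param n_validation Sample size of the validation study.
#' @param seed Optional seed for the two draws.
#' @return A single non-negative number (squared outcome units).
#' @export
compute_mspe <- function(known, spec, n_current = 500,
                         n_validation = 500, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  mask <- setNames(known$known, known$variable)[spec$variables]
  if (n_current <= sum(mask) + 2) {
    abort("n_current too small for the known-predictor model")
  }
  if (!is.null(seed)) set.seed(seed)
  cs <- compile_spec(spec)
  Xc <- gen_x(cs, n_current)
  yc <- gen_y(cs, Xc)
  Xv <- gen_x(cs, n_validation)
  yv <- gen_y(cs, Xv)
  mspe_mask(mask, Xc, yc, Xv, yv)
}

# Fit on (Xc, yc) restricted to mask, evaluate squared error on (Xv, yv).
mspe_mask <- function(mask, Xc, yc, Xv, yv) {
  idx <- which(mask)
  Xd <- cbind(1, Xc[, idx, drop = FALSE])
  ch <- tryCatch(chol(crossprod(Xd)), error = function(e) NULL)
  if (is.null(ch)) abort("singular design in the current-study fit")
  b <- chol2inv(ch) %*% crossprod(Xd, yc)
  pred <- as.vector(cbind(1, Xv[, idx, drop = FALSE]) %*% b)
  mean((yv - pred)^2)
}

#' Aggregate replication outcomes into scenario summaries
#'
#' Turns per-replication rows into the six indicators: MSF, TPR and DMSF
#' are the means of the corresponding booleans; FPR is the mean count of
#' false positives divided by the number of non-predictors (11); FNR the
#' mean count of false negatives divided by the number of true predictors
#' (9); MSPE the mean of per-replication MSPEs.  Per-variable inclusion
#' frequencies are computed from the `known_vars` list-column.
#'
#' @param outcomes A tibble of replication outcomes as produced by
#'   [run_replication()] (possibly row-bound over replications), with at
#'   least the columns `rule`, `exact_match`, `superset_of_truth`,
#'   `superset_of_top5`, `n_false_positives`, `n_false_negatives`,
#'   `mspe`, `known_vars`.
#' @param spec The generator the outcomes refer to.
#'
#' @return A tibble with one row per rule: the six indicators, their
#'   Monte Carlo standard errors (`*_se`), `n_replications`, and a nested
#'   `inclusion` list-column of per-variable frequencies.
#' @export
aggregate_outcomes <- function(outcomes, spec) {
  if (nrow(outcomes) == 0) abort("cannot aggregate zero outcomes")
  stopifnot(inherits(spec, "generator_spec"))
  n_none <- length(spec$nonpredictor_set)
  n_true <- length(spec$true_set)
  vars <- spec$variables
  rate_se <- function(p, n) sqrt(p * (1 - p) / n)
  outcomes |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("scenario", "method", "alpha_in", "rule")))) |>
    dplyr::summarise(
      n_replications = dplyr::n(),
      msf = mean(.data$exact_match),
      tpr = mean(.data$superset_of_truth),
      dmsf = mean(.data$superset_of_top5),
      fpr = mean(.data$n_false_positives) / n_none,
      fnr = mean(.data$n_false_negatives) / n_true,
      msf_se = rate_se(msf, n_replications),
      tpr_se = rate_se(tpr, n_replications),
      dmsf_se = rate_se(dmsf, n_replications),
      mspe_se = sd(.data$mspe) / sqrt(n_replications),
      mspe = mean(.data$mspe),
      inclusion = list(inclusion_frequency(.data$known_vars, vars)),
      .groups = "drop"
    )
}

inclusion_frequency <- function(known_vars, vars) {
  counts <- table(factor(unlist(known_vars), levels = vars))
  tibble(variable = vars,
         frequency = as.vector(counts) / length(known_vars))
}
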