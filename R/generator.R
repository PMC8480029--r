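# Data-generating mechanism: a linear outcome model over 20 candidate
# predictors (9 true, 11 pure noise), with covariates drawn by the NORTA /
# Gaussian-copula scheme: correlated standard-normal deviates transformed
# column-wise to realistic marginal distributions.

#' Candidate, true-predictor and non-predictor variable names
#'
#' The simulated candidate set mimics a blood-pressure study: the outcome is
#' the home-vs-clinic difference in diastolic blood pressure and the nine
#' true predictors are age (years), sex (0/1), the first clinic blood
#' pressure reading (`cbp.first`, mmHg), its change at follow-up
#' (`cbp.change`, mmHg), body-mass index, history of hypertension,
#' antihypertensive medication, cardiovascular disease (all 0/1) and pulse
#' pressure (mmHg).  Eleven noise variables `X_none1` ... `X_none11` with
#' zero outcome effect complete the candidate set.
#'
#' @return A character vector of variable names, in the canonical column
#'   order used by every dataset in the package.
#' @export
candidate_variables <- function() {
  c(true_predictors(), paste0("X_none", 1:11))
}

#' @rdname candidate_variables
#' @export
true_predictors <- function() {
  c("age", "sex", "cbp.first", "cbp.change", "bmi",
    "history", "antihyp", "cvd", "pp")
}

#' @rdname candidate_variables
#' @export
nonpredictor_variables <- function() {
  paste0("X_none", 1:11)
}

#' Predictors with the five largest absolute standardized coefficients
#'
#' Used by the descriptive model selection frequency (DMSF): a selected set
#' "captures the important predictors" when it contains all five.
#'
#' @return Character vector of five variable names.
#' @export
top5_predictors <- function() {
  c("sex", "age", "cbp.first", "antihyp", "cbp.change")
}

#' True regression coefficients of the data-generating mechanism
#'
#' The outcome model is
#' `y = 36 - 0.08 age + 3.33 sex - 0.47 cbp.first + 0.31 cbp.change -
#'  0.07 bmi - 0.03 history + 2.37 antihyp - 0.40 cvd - 0.06 pp + e`,
#' with `e ~ N(0, error_sd^2)`.  Non-predictors have coefficient 0.
#'
#' @return A tibble with columns `variable` and `coefficient` covering all
#'   20 candidates.
#' @export
true_coefficients <- function() {
  tibble(
    variable = candidate_variables(),
    coefficient = c(-0.08, 3.33, -0.47, 0.31, -0.07, -0.03, 2.37, -0.40,
                    -0.06, rep(0, 11))
  )
}

#' Standardized coefficients targeted by the calibration
#'
#' Standardized coefficients are defined as `beta * SD(X) / SD(Y)`.  The
#' generator is calibrated so that the nine true predictors reproduce these
#' values, which fixes every predictor's marginal SD given the raw
#' coefficients and the outcome SD.
#'
#' @return A tibble with columns `variable` and `std_coefficient`.
#' @export
target_std_coefficients <- function() {
  tibble(
    variable = c("sex", "cbp.first", "antihyp", "age", "cbp.change",
                 "pp", "bmi", "cvd", "history"),
    std_coefficient = c(0.528, -0.406, 0.315, -0.268, 0.201,
                        -0.161, -0.093, -0.050, -0.004)
  )
}

#' Back out marginal SDs from standardized coefficients
#'
#' Inverts `beta_std = beta * SD(X) / SD(Y)` for each variable, with
#' `SD(Y) = error_sd / sqrt(1 - r_squared)` the outcome SD implied by the
#' error scale and the target coefficient of determination.  For binary
#' variables the Bernoulli success probability `p` solving
#' `sqrt(p (1 - p)) = SD(X)` is also returned (the `p <= 0.5` root unless
#' `p_above_half = TRUE`).
#'
#' @param std_coefs Tibble with columns `variable` and `std_coefficient`.
#' @param coefficients Tibble with columns `variable` and `coefficient`;
#'   must contain a nonzero coefficient for every row of `std_coefs`.
#' @param error_sd SD of the Gaussian error term.
#' @param r_squared Target proportion of outcome variance explained by the
#'   linear predictor, in (0, 1).
#' @param binary Character vector naming the variables that are 0/1
#'   indicators and need an implied threshold probability.
#' @param p_above_half Take the `p > 0.5` root for binary variables.
#'
#' @return A tibble with columns `variable`, `target_sd` and `p` (`NA` for
#'   continuous variables).
#' @export
calibrate_marginal_sds <- function(std_coefs, coefficients,
                                   error_sd = sqrt(2), r_squared = 0.75,
                                   binary = character(),
                                   p_above_half = FALSE) {
  stopifnot(error_sd > 0, r_squared > 0, r_squared < 1)
  beta <- setNames(coefficients$coefficient, coefficients$variable)
  miss <- setdiff(std_coefs$variable, names(beta))
  if (length(miss) > 0) {
    abort(paste0("no coefficient given for: ", paste(miss, collapse = ", ")))
  }
  b <- beta[std_coefs$variable]
  if (any(b == 0)) {
    abort(paste0("cannot calibrate an SD for variables with a zero ",
                 "coefficient: ",
                 paste(std_coefs$variable[b == 0], collapse = ", ")))
  }
  sd_y <- error_sd / sqrt(1 - r_squared)
  target_sd <- unname(abs(std_coefs$std_coefficient) * sd_y / abs(b))
  p <- rep(NA_real_, length(target_sd))
  is_bin <- std_coefs$variable %in% binary
  if (any(is_bin & target_sd > 0.5)) {
    abort(paste0("binary calibration infeasible (implied SD > 0.5) for: ",
                 paste(std_coefs$variable[is_bin & target_sd > 0.5],
                       collapse = ", ")))
  }
  root <- (1 - sqrt(1 - 4 * target_sd[is_bin]^2)) / 2
  p[is_bin] <- if (p_above_half) 1 - root else root
  tibble(variable = std_coefs$variable, target_sd = target_sd, p = p)
}

#' Default latent correlation matrix
#'
#' Correlations of the latent multivariate-normal deviates before the
#' marginal transforms.  The predictor block encodes clinically motivated
#' dependence: a strong history-of-hypertension / sex correlation (0.6), a
#' blood-pressure block (first reading, pulse pressure, follow-up change)
#' and age links to blood pressure, medication and cardiovascular disease.
#' The age / first-reading entry (0.345) is the one value set by
#' calibration rather than clinical judgement: it brings the variance
#' explained by the linear predictor to the target R-squared of 0.75.
#' Several noise variables are deliberately correlated with strong true
#' predictors so that they carry confounded marginal associations with the
#' outcome; others form internal blocks or stay independent.
#'
#' @return A 20 x 20 symmetric positive-definite matrix with unit diagonal
#'   and dimnames equal to [candidate_variables()].
#' @export
default_latent_correlation <- function() {
  nm <- candidate_variables()
  R <- diag(length(nm))
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  # true-predictor block
  set2("age", "cbp.first", 0.345)
  set2("age", "pp", 0.40)
  set2("age", "antihyp", 0.25)
  set2("age", "cvd", 0.25)
  set2("age", "history", 0.20)
  set2("sex", "history", 0.60)
  set2("cbp.first", "pp", 0.50)
  set2("cbp.first", "cbp.change", 0.30)
  set2("cbp.first", "antihyp", 0.20)
  set2("cbp.change", "pp", 0.15)
  set2("bmi", "cbp.first", 0.20)
  set2("bmi", "antihyp", 0.20)
  set2("history", "antihyp", 0.50)
  set2("cvd", "antihyp", 0.30)
  set2("cvd", "history", 0.30)
  # noise variables: some confounded with strong predictors, some in
  # internal blocks, some independent
  set2("X_none1", "age", 0.50)
  set2("X_none1", "X_none2", 0.30)
  set2("X_none2", "cbp.first", 0.45)
  set2("X_none3", "sex", 0.40)
  set2("X_none4", "antihyp", 0.35)
  set2("X_none5", "X_none6", 0.50)
  set2("X_none5", "X_none7", 0.50)
  set2("X_none6", "X_none7", 0.50)
  set2("X_none5", "pp", 0.25)
  set2("X_none8", "bmi", 0.30)
  set2("X_none9", "X_none10", 0.40)
  R
}

#' Default marginal specifications
#'
#' One row per candidate variable: the marginal distribution each latent
#' normal deviate is transformed to.  Kinds are `"continuous"` (affine map
#' `mean + sd * Z`), `"binary"` (indicator `Z >= qnorm(1 - p)`, preserving
#' the sign of latent correlations) and `"lognormal"`
#' (`exp(meanlog + sdlog * Z)`).  True-predictor SDs come from
#' [calibrate_marginal_sds()]; their means are clinically plausible
#' anchors and only shift the outcome through the intercept.  Noise
#' variables mix all three kinds.
#'
#' @inheritParams calibrate_marginal_sds
#' @return A tibble with columns `variable`, `kind`, `mean`, `sd`, `p`,
#'   `meanlog`, `sdlog`.
#' @export
default_marginals <- function(error_sd = sqrt(2), r_squared = 0.75) {
  binary_true <- c("sex", "history", "antihyp", "cvd")
  cal <- calibrate_marginal_sds(target_std_coefficients(),
                                true_coefficients(),
                                error_sd = error_sd, r_squared = r_squared,
                                binary = binary_true)
  cal <- cal[match(true_predictors(), cal$variable), ]
  means <- c(age = 60, sex = NA, cbp.first = 85, cbp.change = 0, bmi = 27,
             history = NA, antihyp = NA, cvd = NA, pp = 50)
  truth <- tibble(
    variable = true_predictors(),
    kind = ifelse(true_predictors() %in% binary_true, "binary",
                  "continuous"),
    mean = unname(means[true_predictors()]),
    sd = ifelse(true_predictors() %in% binary_true, NA_real_,
                cal$target_sd),
    p = cal$p,
    meanlog = NA_real_, sdlog = NA_real_
  )
  noise <- tibble(
    variable = nonpredictor_variables(),
    kind = c("continuous", "continuous", "binary", "continuous",
             "continuous", "continuous", "continuous", "lognormal",
             "binary", "continuous", "lognormal"),
    mean = c(0, 50, NA, 5, 0, 0, 0, NA, NA, 100, NA),
    sd = c(1, 10, NA, 2, 1, 1, 1, NA, NA, 15, NA),
    p = c(NA, NA, 0.3, NA, NA, NA, NA, NA, 0.45, NA, NA),
    meanlog = c(NA, NA, NA, NA, NA, NA, NA, 0, NA, NA, 1),
    sdlog = c(NA, NA, NA, NA, NA, NA, NA, 0.5, NA, NA, 0.3)
  )
  dplyr::bind_rows(truth, noise)
}

#' Construct a generator specification
#'
#' Bundles everything that defines the data-generating mechanism: the
#' outcome model (intercept, coefficients, error SD), the latent
#' correlation matrix and the marginal specifications, plus the variable
#' role sets used by the performance metrics.
#'
#' @param coefficients Tibble with columns `variable`, `coefficient` for
#'   all candidates (zero for non-predictors).
#' @param marginals Tibble as returned by [default_marginals()].
#' @param latent_correlation Symmetric positive-definite matrix with unit
#'   diagonal, dimnames matching the variables.
#' @param intercept Outcome-model intercept.
#' @param error_sd SD of the Gaussian error.
#' @param true_set,top5_set Character vectors of variable roles.
#'
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(coefficients, marginals, latent_correlation,
                           intercept = 36, error_sd = sqrt(2),
                           true_set = true_predictors(),
                           top5_set = top5_predictors()) {
  vars <- marginals$variable
  spec <- structure(
    list(
      variables = vars,
      intercept = intercept,
      coefficients = setNames(coefficients$coefficient,
                              coefficients$variable)[vars],
      error_sd = error_sd,
      marginals = marginals,
      latent_correlation = latent_correlation[vars, vars],
      true_set = true_set,
      nonpredictor_set = setdiff(vars, true_set),
      top5_set = top5_set
    ),
    class = "generator_spec"
  )
  validate_generator_spec(spec)
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("<generator_spec>\n")
  cat("  candidates:     ", length(x$variables), " (",
      length(x$true_set), " true, ", length(x$nonpredictor_set),
      " noise)\n", sep = "")
  cat("  intercept:      ", x$intercept, "\n", sep = "")
  cat("  error_sd:       ", format(x$error_sd, digits = 4), "\n", sep = "")
  cat("  marginal kinds: ",
      paste(names(table(x$marginals$kind)), table(x$marginals$kind),
            sep = ":", collapse = ", "), "\n", sep = "")
  invisible(x)
}

validate_generator_spec <- function(spec) {
  vars <- spec$variables
  if (anyDuplicated(vars)) abort("duplicated variable names")
  if (!setequal(names(spec$coefficients), vars) ||
      anyNA(spec$coefficients)) {
    abort("coefficients must cover exactly the candidate variables")
  }
  if (any(spec$coefficients[spec$nonpredictor_set] != 0)) {
    abort("non-predictor coefficients must be exactly 0")
  }
  if (!all(spec$top5_set %in% spec$true_set)) {
    abort("top5_set must be a subset of true_set")
  }
  if (spec$error_sd < 0) abort("error_sd must be non-negative")
  R <- spec$latent_correlation
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12)) {
    abort("latent_correlation must be symmetric with unit diagonal")
  }
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    abort("latent_correlation is not positive definite")
  }
  m <- spec$marginals
  if (!all(m$kind %in% c("continuous", "binary", "lognormal"))) {
    abort("unknown marginal kind")
  }
  bad <- m$kind == "binary" & !(m$p > 0 & m$p < 1)
  if (any(bad, na.rm = TRUE) || anyNA(m$p[m$kind == "binary"])) {
    abort("binary marginals need p strictly inside (0, 1)")
  }
  if (any(m$sd[m$kind == "continuous"] <= 0, na.rm = TRUE) ||
      anyNA(m$sd[m$kind == "continuous"])) {
    abort("continuous marginals need a positive sd")
  }
  spec
}

#' Default calibrated generator
#'
#' The stock data-generating mechanism: true coefficients of
#' [true_coefficients()], marginal SDs calibrated so that the standardized
#' coefficients match [target_std_coefficients()], the default latent
#' correlation matrix, and Gaussian error with `error_sd = sqrt(2)`,
#' which together give a full-model R-squared of about 0.75.
#'
#' @inheritParams calibrate_marginal_sds
#' @return A `generator_spec`.
#' @export
default_generator <- function(error_sd = sqrt(2), r_squared = 0.75) {
  generator_spec(
    coefficients = true_coefficients(),
    marginals = default_marginals(error_sd = error_sd,
                                  r_squared = r_squared),
    latent_correlation = default_latent_correlation(),
    intercept = 36,
    error_sd = error_sd
  )
}

# Precompute everything the samplers need as plain vectors/matrices.
compile_spec <- function(spec) {
  m <- spec$marginals
  list(
    vars = spec$variables,
    cholR = chol(spec$latent_correlation),
    kind = m$kind,
    mean = m$mean,
    sd = m$sd,
    thr = ifelse(m$kind == "binary", qnorm(1 - m$p), NA_real_),
    meanlog = m$meanlog,
    sdlog = m$sdlog,
    beta = unname(spec$coefficients),
    intercept = spec$intercept,
    error_sd = spec$error_sd,
    true_idx = match(spec$true_set, spec$variables),
    none_idx = match(spec$nonpredictor_set, spec$variables),
    top5_idx = match(spec$top5_set, spec$variables)
  )
}

# Draw an n x p covariate matrix from a compiled spec (uses the current
# RNG state; callers own seeding).
gen_x <- function(cs, n) {
  p <- length(cs$vars)
  Z <- matrix(rnorm(n * p), nrow = n) %*% cs$cholR
  X <- Z
  for (j in seq_len(p)) {
    X[, j] <- switch(cs$kind[j],
      continuous = cs$mean[j] + cs$sd[j] * Z[, j],
      binary = as.numeric(Z[, j] >= cs$thr[j]),
      lognormal = exp(cs$meanlog[j] + cs$sdlog[j] * Z[, j])
    )
  }
  colnames(X) <- cs$vars
  X
}

gen_y <- function(cs, X) {
  mu <- cs$intercept + as.vector(X %*% cs$beta)
  if (cs$error_sd == 0) mu else mu + rnorm(nrow(X), 0, cs$error_sd)
}

#' Sample covariates from a generator specification
#'
#' Draws latent multivariate-normal deviates with the specification's
#' correlation matrix and transforms each column to its marginal
#' distribution.
#'
#' @param spec A [generator_spec()].
#' @param n Number of rows.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the global RNG state is left untouched by the caller's standards
#'   (the seed is set immediately before sampling).
#'
#' @return A tibble with `n` rows and one column per candidate variable.
#' @export
sample_covariates <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  as_tibble(as.data.frame(gen_x(compile_spec(spec), n)))
}

#' Generate outcomes for a covariate table
#'
#' Applies the linear outcome model `intercept + X beta` and adds i.i.d.
#' Gaussian noise with SD `spec$error_sd`.
#'
#' @param X Tibble or matrix containing every candidate column.
#' @inheritParams sample_covariates
#' @return A numeric outcome vector of length `nrow(X)`.
#' @export
generate_outcome <- function(X, spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  miss <- setdiff(spec$variables, colnames(X))
  if (length(miss) > 0) {
    abort(paste0("missing candidate columns: ", paste(miss, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  cs <- compile_spec(spec)
  gen_y(cs, as.matrix(X[, spec$variables, drop = FALSE]))
}

#' Generate a complete study dataset
#'
#' Composition of [sample_covariates()] and [generate_outcome()]: one
#' simulated study with all 20 candidate columns and the outcome `y`.
#'
#' @inheritParams sample_covariates
#' @return A tibble with `n` rows and 21 columns (candidates then `y`).
#' @export
generate_study <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cs <- compile_spec(spec)
  X <- gen_x(cs, n)
  out <- as_tibble(as.data.frame(X))
  out$y <- gen_y(cs, X)
  out
}

#' Read and write study datasets as CSV
#'
#' Column order is fixed: the nine true predictors in outcome-model order,
#' then `X_none1` ... `X_none11`, then the outcome `y`.
#'
#' @param data A study tibble as produced by [generate_study()].
#' @param path File path.
#' @return `write_study_csv()` returns `data` invisibly;
#'   `read_study_csv()` returns the study tibble.
#' @export
write_study_csv <- function(data, path) {
  cols <- c(candidate_variables(), "y")
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("study is missing columns: ", paste(miss, collapse = ", ")))
  }
  readr::write_csv(data[, cols], path)
  invisible(data)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

#' Read and write generator configurations as YAML
#'
#' Serializes a full [generator_spec()] (coefficients, error scale,
#' marginals, latent correlation matrix) so that users can substitute
#' their own correlation structure or error convention.
#'
#' @param spec A `generator_spec`.
#' @param path File path to a YAML document.
#' @return `write_generator_config()` returns `spec` invisibly;
#'   `read_generator_config()` returns a reconstructed `generator_spec`.
#' @export
write_generator_config <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  cfg <- list(
    intercept = spec$intercept,
    error_sd = spec$error_sd,
    true_set = spec$true_set,
    top5_set = spec$top5_set,
    coefficients = as.list(spec$coefficients),
    marginals = lapply(seq_len(nrow(spec$marginals)), function(i) {
      row <- as.list(spec$marginals[i, ])
      row[!vapply(row, is.na, logical(1))]
    }),
    latent_correlation = apply(spec$latent_correlation, 1, as.list,
                               simplify = FALSE)
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(spec)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  marg <- dplyr::bind_rows(lapply(cfg$marginals, function(row) {
    defaults <- list(mean = NA_real_, sd = NA_real_, p = NA_real_,
                     meanlog = NA_real_, sdlog = NA_real_)
    as_tibble(utils::modifyList(defaults, row)[c("variable", "kind",
                                                 names(defaults))])
  }))
  vars <- marg$variable
  R <- do.call(rbind, lapply(cfg$latent_correlation,
                             function(r) unlist(r[vars])))
  dimnames(R) <- list(vars, vars)
  generator_spec(
    coefficients = tibble(variable = names(cfg$coefficients),
                          coefficient = unlist(cfg$coefficients)),
    marginals = marg,
    latent_correlation = R,
    intercept = cfg$intercept,
    error_sd = cfg$error_sd,
    true_set = cfg$true_set,
    top5_set = cfg$top5_set
  )
}

#' Standardized coefficients realized by a generator
#'
#' Monte Carlo diagnostic: draws one large sample, fits the full OLS model
#' on the true predictors and reports `beta_hat * SD(X) / SD(Y)` for each.
#'
#' @inheritParams sample_covariates
#' @param n Sample size of the diagnostic draw.
#' @return A tibble with columns `variable`, `std_coefficient` (realized)
#'   and `target` (from [target_std_coefficients()] where applicable).
#' @export
realized_std_coefficients <- function(spec, n = 100000, seed = NULL) {
  data <- generate_study(spec, n, seed = seed)
  fit <- ols_fit(data[, spec$true_set], data$y)
  est <- fit$coefficients[spec$true_set]
  sds <- vapply(data[, spec$true_set], sd, numeric(1))
  out <- tibble(
    variable = spec$true_set,
    std_coefficient = unname(est * sds / sd(data$y))
  )
  tgt <- target_std_coefficients()
  out$target <- tgt$std_coefficient[match(out$variable, tgt$variable)]
  out
}
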