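# Independent oracles and small fixture builders shared across tests.

# Brute-force greedy backward elimination: at every step refit every
# single-variable deletion with stats::lm and compare stats::AIC values.
# Completely independent of the package's RSS-downdating implementation.
oracle_backward <- function(data, outcome = "y") {
  vars <- setdiff(names(data), outcome)
  active <- vars
  repeat {
    f_cur <- stats::as.formula(paste(
      outcome, "~", if (length(active)) paste(active, collapse = "+") else "1"
    ))
    aic_cur <- stats::AIC(stats::lm(f_cur, data = data))
    if (length(active) == 0) break
    aic_drop <- vapply(active, function(v) {
      rest <- setdiff(active, v)
      f <- stats::as.formula(paste(
        outcome, "~", if (length(rest)) paste(rest, collapse = "+") else "1"
      ))
      stats::AIC(stats::lm(f, data = data))
    }, numeric(1))
    if (min(aic_drop) < aic_cur - 1e-10) {
      active <- setdiff(active, active[which.min(aic_drop)])
    } else {
      break
    }
  }
  active
}

# A small correlated regression dataset with named columns x1..xp.
make_toy_data <- function(n, p, beta, sigma = 1, rho = 0.3, seed = 1) {
  set.seed(seed)
  R <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  X <- matrix(rnorm(n * p), n) %*% chol(R)
  colnames(X) <- paste0("x", seq_len(p))
  y <- as.vector(X %*% beta) + rnorm(n, 0, sigma)
  tibble::as_tibble(as.data.frame(X)) |> dplyr::mutate(y = y)
}

# Default generator with the latent correlation replaced by the identity
# (independent covariates), used for null-calibration checks.
independent_generator <- function(...) {
  spec <- default_generator(...)
  generator_spec(
    coefficients = true_coefficients(),
    marginals = spec$marginals,
    latent_correlation = diag(20) |>
      `dimnames<-`(list(candidate_variables(), candidate_variables())),
    intercept = spec$intercept,
    error_sd = spec$error_sd
  )
}

# Build a prs_selection object directly from a logical vector, for
# evidence-module fixtures.
mask_selection <- function(mask, vars = NULL, method = "univariable") {
  if (is.null(vars)) vars <- paste0("v", seq_along(mask))
  priorsim:::new_selection(
    tibble::tibble(variable = vars, selected = mask),
    method = method, threshold = 0.05, study_n = 100L
  )
}
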