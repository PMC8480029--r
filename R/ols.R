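# Least-squares engine shared by both selection procedures.

#' Fit an ordinary least-squares model
#'
#' A small, fast OLS fit returning exactly the quantities the selection
#' procedures need: coefficients, standard errors, two-sided t-test
#' p-values, the Gaussian AIC and R-squared.
#'
#' The AIC uses the full Gaussian log-likelihood,
#' `AIC = n log(2 pi) + n log(RSS / n) + n + 2 (k + 1)`,
#' where `k` counts the estimated mean parameters (intercept included) and
#' the `+ 1` counts the error variance.  The constant terms are shared by
#' every model fitted to the same dataset, so model comparisons do not
#' depend on them; the convention matches `stats::AIC()` on an `lm` fit.
#'
#' @param x Covariate tibble, data frame or matrix (zero columns allowed).
#' @param y Numeric outcome vector.
#' @param intercept Include an intercept term.
#'
#' @return An object of class `prs_ols` with elements `coefficients`,
#'   `std_errors`, `p_values`, `aic`, `r_squared`, `residual_variance`,
#'   `rss`, `n`, `k`, `terms`.
#' @export
ols_fit <- function(x, y, intercept = TRUE) {
  X <- if (is.null(x) || (!is.null(ncol(x)) && ncol(x) == 0)) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    as.matrix(x)
  }
  if (nrow(X) != length(y)) abort("x and y disagree on the sample size")
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  k <- ncol(X)
  n <- length(y)
  if (n <= k) abort("insufficient data: need more rows than parameters")
  if (k == 0) abort("empty model: no intercept and no covariates")
  qrX <- qr(X)
  if (qrX$rank < k) abort("singular design: columns are linearly dependent")
  coef <- qr.coef(qrX, y)
  res <- y - as.vector(X %*% coef)
  rss <- sum(res^2)
  tss <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coef / se
  structure(
    list(
      coefficients = coef,
      std_errors = setNames(se, names(coef)),
      p_values = setNames(2 * pt(abs(tval), df = n - k,
                                 lower.tail = FALSE), names(coef)),
      aic = gaussian_aic(rss, n, k),
      r_squared = if (tss > 0) 1 - rss / tss else 1,
      residual_variance = sigma2,
      rss = rss,
      n = n,
      k = k,
      terms = colnames(X)
    ),
    class = "prs_ols"
  )
}

# k = number of mean parameters; + 1 inside 2 * (k + 1) counts sigma^2.
gaussian_aic <- function(rss, n, k) {
  n * log(2 * pi) + n * log(rss / n) + n + 2 * (k + 1)
}

#' @export
print.prs_ols <- function(x, ...) {
  cat("<prs_ols> n = ", x$n, ", k = ", x$k,
      ", R^2 = ", format(x$r_squared, digits = 4),
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict from a `prs_ols` fit
#'
#' @param object A fit from [ols_fit()].
#' @param newdata Tibble or matrix containing the model's covariate
#'   columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.prs_ols <- function(object, newdata, ...) {
  terms <- setdiff(object$terms, "(Intercept)")
  X <- as.matrix(as.data.frame(newdata)[, terms, drop = FALSE])
  eta <- if (length(terms) > 0) {
    as.vector(X %*% object$coefficients[terms])
  } else {
    rep(0, nrow(as.data.frame(newdata)))
  }
  if ("(Intercept)" %in% object$terms) {
    eta <- eta + object$coefficients[["(Intercept)"]]
  }
  eta
}

#' Broom-style tidiers for `prs_ols` fits
#'
#' @param x A fit from [ols_fit()].
#' @param ... Unused.
#' @return `tidy()` gives one row per term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`); `glance()` gives a one-row
#'   model summary.
#' @export
tidy.prs_ols <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$coefficients / x$std_errors),
    p.value = unname(x$p_values)
  )
}

#' @rdname tidy.prs_ols
#' @export
glance.prs_ols <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$residual_variance),
    AIC = x$aic,
    nobs = x$n,
    df = x$k
  )
}
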