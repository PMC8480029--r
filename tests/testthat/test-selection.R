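# OLS engine, univariable prescreening and AIC backward elimination.

test_that("ols_fit agrees with stats::lm on every reported quantity", {
  d <- make_toy_data(60, 4, beta = c(1, -0.5, 0, 0.2), seed = 3)
  fit <- ols_fit(d[, 1:4], d$y)
  ref <- lm(y ~ x1 + x2 + x3 + x4, data = d)
  sref <- summary(ref)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit$std_errors),
               unname(sref$coefficients[, "Std. Error"]), tolerance = 1e-10)
  expect_equal(unname(fit$p_values),
               unname(sref$coefficients[, "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(fit$r_squared, sref$r.squared, tolerance = 1e-10)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(glance(fit)$nobs, 60)
})

test_that("ols_fit handles the degenerate closed forms", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  empty <- ols_fit(NULL, y)
  expect_equal(unname(empty$coefficients), mean(y))
  x <- tibble::tibble(x1 = seq_along(y))
  exact <- ols_fit(x, 2 + 3 * x$x1)
  expect_equal(exact$r_squared, 1)
  expect_equal(predict(exact, x), 2 + 3 * x$x1, tolerance = 1e-10)
})

test_that("AIC differences between nested models follow the RSS formula", {
  d <- make_toy_data(30, 3, beta = c(0.8, 0, 0), seed = 8)
  f1 <- ols_fit(d[, c("x1", "x2")], d$y)
  f0 <- ols_fit(d[, "x1", drop = FALSE], d$y)
  expect_equal(f0$aic - f1$aic,
               30 * log(f0$rss / f1$rss) - 2, tolerance = 1e-10)
})

test_that("ols_fit rejects singular and undersized designs", {
  d <- make_toy_data(20, 2, beta = c(1, 1), seed = 2)
  d$x3 <- d$x1 + d$x2
  expect_error(ols_fit(d[, c("x1", "x2", "x3")], d$y), "singular")
  expect_error(ols_fit(d[1:3, 1:2], d$y[1:3]), "insufficient")
})

test_that("univariable p-values match per-variable lm fits", {
  d <- make_toy_data(80, 5, beta = c(0.6, 0, 0.3, 0, 0), seed = 13)
  sel <- univariable_select(d, alpha_in = 0.05)
  for (v in paste0("x", 1:5)) {
    ref <- summary(lm(stats::reformulate(v, "y"), data = d))
    expect_equal(sel$p_value[sel$variable == v],
                 ref$coefficients[v, "Pr(>|t|)"], tolerance = 1e-10)
  }
  expect_equal(sel$selected, sel$p_value <= 0.05)
})

test_that("a candidate identical to the outcome is always selected", {
  d <- tibble::tibble(x1 = rnorm(50), y = NA)
  d$y <- d$x1
  d$x2 <- rnorm(50)
  sel <- univariable_select(d, alpha_in = 0.05)
  expect_true(sel$selected[sel$variable == "x1"])
})

test_that("selection at alpha 0.05 is nested in selection at alpha 0.2", {
  for (seed in 1:15) {
    d <- make_toy_data(60, 6, beta = c(0.5, 0.2, 0.1, 0, 0, 0),
                       seed = seed)
    s05 <- univariable_select(d, 0.05)
    s20 <- univariable_select(d, 0.2)
    expect_true(all(!s05$selected | s20$selected))
  }
})

test_that("constant columns are not selected and trigger a warning", {
  d <- make_toy_data(40, 2, beta = c(1, 0), seed = 4)
  d$flat <- 1
  expect_warning(sel <- univariable_select(d, 0.05), "flat")
  expect_false(sel$selected[sel$variable == "flat"])
  expect_true(is.na(sel$p_value[sel$variable == "flat"]))
})

test_that("backward elimination matches the brute-force stepwise oracle", {
  for (seed in 1:25) {
    p <- sample(4:6, 1)
    beta <- round(rnorm(p, 0, 0.4), 2)
    d <- make_toy_data(40, p, beta = beta, rho = 0.4, seed = seed)
    got <- backward_eliminate(d)
    expect_identical(got$variable[got$selected], oracle_backward(d),
                     label = paste("seed", seed))
  }
})

test_that("backward elimination agrees with MASS::stepAIC", {
  skip_if_not_installed("MASS")
  d <- make_toy_data(50, 6, beta = c(0.7, -0.4, 0.2, 0, 0, 0),
                     rho = 0.35, seed = 99)
  got <- backward_eliminate(d)
  ref <- MASS::stepAIC(lm(y ~ ., data = d), direction = "backward",
                       trace = 0, scope = list(lower = ~1))
  expect_setequal(got$variable[got$selected],
                  setdiff(names(coef(ref)), "(Intercept)"))
})

test_that("the final backward model is a local AIC optimum", {
  for (seed in c(7, 17)) {
    d <- make_toy_data(70, 8,
                       beta = c(0.6, 0.4, -0.3, 0.1, 0, 0, 0, 0),
                       rho = 0.3, seed = seed)
    got <- backward_eliminate(d)
    kept <- got$variable[got$selected]
    full_aic <- ols_fit(d[, setdiff(names(d), "y")], d$y)$aic
    final_aic <- ols_fit(d[, kept, drop = FALSE], d$y)$aic
    expect_lte(final_aic, full_aic + 1e-8)
    for (v in kept) {
      rest <- setdiff(kept, v)
      expect_gte(ols_fit(d[, rest, drop = FALSE], d$y)$aic,
                 final_aic - 1e-8)
    }
  }
})

test_that("a dominant single signal is always retained", {
  set.seed(5)
  d <- tibble::tibble(x1 = rnorm(100))
  d$y <- d$x1 + rnorm(100, 0, 0.01)
  d$x2 <- rnorm(100)
  got <- backward_eliminate(d)
  expect_true(got$selected[got$variable == "x1"])
})

test_that("null inclusion frequencies are calibrated", {
  # univariable: an independent noise candidate is included with
  # probability alpha; backward/AIC: with probability P(chi2_1 > 2)
  set.seed(314)
  n_rep <- 1500
  hits05 <- 0
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(100 * 4), 100)
    colnames(X) <- paste0("x", 1:4)
    y <- rnorm(100)
    hits05 <- hits05 + sum(univariable_screen(X, y, 0.05)$selected)
  }
  expect_lt(abs(hits05 / (n_rep * 4) - 0.05), 0.012)

  n_rep <- 400
  hits_bw <- 0
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(300 * 10), 300)
    colnames(X) <- paste0("x", 1:10)
    y <- rnorm(300)
    hits_bw <- hits_bw + sum(backward_screen(X, y)$selected)
  }
  expect_lt(abs(hits_bw / (n_rep * 10) -
                  pchisq(2, 1, lower.tail = FALSE)), 0.025)
})

test_that("selection results export as a 0/1 audit matrix", {
  d1 <- make_toy_data(50, 4, beta = c(1, 0.5, 0, 0), seed = 1)
  d2 <- make_toy_data(50, 4, beta = c(1, 0.5, 0, 0), seed = 2)
  sels <- list(univariable_select(d1, 0.05), univariable_select(d2, 0.05))
  m <- selections_to_matrix(sels)
  expect_equal(dim(m), c(2, 4))
  expect_true(all(m %in% 0:1))
  expect_equal(m[1, ], setNames(as.integer(sels[[1]]$selected),
                                sels[[1]]$variable))
})
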