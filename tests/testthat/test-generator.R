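# The synthetic-data generator: marginal calibration, copula sampling,
# outcome model.

test_that("marginal SDs invert the standardized-coefficient definition", {
  cal <- calibrate_marginal_sds(target_std_coefficients(),
                                true_coefficients(),
                                error_sd = sqrt(2), r_squared = 0.75,
                                binary = c("sex", "history", "antihyp",
                                           "cvd"))
  sd_y <- sqrt(2) / sqrt(1 - 0.75)
  beta <- setNames(true_coefficients()$coefficient,
                   true_coefficients()$variable)
  # back-substitution oracle: beta * SD(X) / SD(Y) must return the target
  tgt <- setNames(target_std_coefficients()$std_coefficient,
                  target_std_coefficients()$variable)
  for (v in cal$variable) {
    sd_v <- cal$target_sd[cal$variable == v]
    expect_equal(abs(beta[[v]]) * sd_v / sd_y, abs(tgt[[v]]),
                 tolerance = 1e-12)
  }
  expect_equal(cal$target_sd[cal$variable == "sex"],
               0.528 * sd_y / 3.33, tolerance = 1e-12)
  expect_equal(cal$target_sd[cal$variable == "age"], 9.475,
               tolerance = 1e-3)
  # implied Bernoulli probability solves sqrt(p (1 - p)) = SD
  p_sex <- cal$p[cal$variable == "sex"]
  expect_equal(sqrt(p_sex * (1 - p_sex)),
               cal$target_sd[cal$variable == "sex"], tolerance = 1e-12)
  expect_equal(p_sex, 0.279, tolerance = 1e-3)
  expect_true(all(cal$p <= 0.5, na.rm = TRUE))
})

test_that("calibration rejects zero coefficients and infeasible binaries", {
  expect_error(
    calibrate_marginal_sds(
      tibble::tibble(variable = "dead", std_coefficient = 0.1),
      tibble::tibble(variable = "dead", coefficient = 0)
    ),
    "zero coefficient"
  )
  # std coefficient so large the implied binary SD exceeds 0.5
  expect_error(
    calibrate_marginal_sds(
      tibble::tibble(variable = "huge", std_coefficient = 0.6),
      tibble::tibble(variable = "huge", coefficient = 1),
      binary = "huge"
    ),
    "huge"
  )
})

test_that("sampling is deterministic given a seed", {
  spec <- default_generator()
  a <- generate_study(spec, 300, seed = 11)
  b <- generate_study(spec, 300, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_study(spec, 300, seed = 12)))
  # byte-for-byte after serialization
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("identity latent correlation yields independent covariates", {
  spec <- independent_generator()
  X <- sample_covariates(spec, 50000, seed = 5)
  C <- cor(as.matrix(X))
  expect_lt(max(abs(C[upper.tri(C)])), 0.02)
})

test_that("marginals are recovered at scale", {
  spec <- default_generator()
  X <- sample_covariates(spec, 50000, seed = 21)
  m <- spec$marginals
  for (i in seq_len(nrow(m))) {
    v <- m$variable[i]
    if (m$kind[i] == "continuous") {
      expect_lt(abs(sd(X[[v]]) / m$sd[i] - 1), 0.03)
      expect_lt(abs(mean(X[[v]]) - m$mean[i]), 4 * m$sd[i] / sqrt(50000))
    } else if (m$kind[i] == "binary") {
      expect_true(all(X[[v]] %in% c(0, 1)))
      half <- 2.576 * sqrt(m$p[i] * (1 - m$p[i]) / 50000)
      expect_lt(abs(mean(X[[v]]) - m$p[i]), half + 1e-9)
    } else {
      expect_true(all(X[[v]] > 0))
      expect_lt(abs(mean(log(X[[v]])) - m$meanlog[i]), 0.02)
    }
  }
})

test_that("outcome model follows the stated linear mechanism", {
  spec <- default_generator()
  spec$error_sd <- 0
  zeros <- tibble::as_tibble(
    as.data.frame(matrix(0, nrow = 5, ncol = 20,
                         dimnames = list(NULL, candidate_variables())))
  )
  expect_equal(generate_outcome(zeros, spec), rep(36, 5))
  one_sex <- zeros[1, ]
  one_sex$sex <- 1
  expect_equal(generate_outcome(one_sex, spec), 36 + 3.33)
  expect_error(generate_outcome(zeros[, -1], spec), "missing candidate")
})

test_that("error variance matches sigma^2 = 2", {
  spec <- default_generator()
  d <- generate_study(spec, 100000, seed = 31)
  beta <- spec$coefficients
  mu <- spec$intercept +
    as.vector(as.matrix(d[, spec$variables]) %*% beta)
  expect_gt(var(d$y - mu), 1.97)
  expect_lt(var(d$y - mu), 2.03)
})

test_that("full-model OLS recovers the generating coefficients", {
  spec <- default_generator()
  d <- generate_study(spec, 100000, seed = 41)
  fit <- ols_fit(d[, spec$true_set], d$y)
  for (v in spec$true_set) {
    expect_lt(abs(fit$coefficients[[v]] - spec$coefficients[[v]]),
              3 * fit$std_errors[[v]] + 1e-9)
  }
  expect_equal(fit$coefficients[["(Intercept)"]], 36, tolerance = 0.05)
})

test_that("a non-positive-definite latent matrix is rejected", {
  R <- default_latent_correlation()
  R["age", "sex"] <- R["sex", "age"] <- 0.999
  R["age", "cbp.first"] <- R["cbp.first", "age"] <- 0.999
  R["sex", "cbp.first"] <- R["cbp.first", "sex"] <- -0.999
  expect_error(
    generator_spec(true_coefficients(), default_marginals(), R),
    "positive definite"
  )
})

test_that("generator configuration round-trips through YAML", {
  spec <- default_generator()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(spec, path)
  spec2 <- read_generator_config(path)
  expect_equal(spec2$coefficients, spec$coefficients)
  expect_equal(spec2$latent_correlation, spec$latent_correlation)
  expect_equal(spec2$error_sd, spec$error_sd)
  expect_equal(as.data.frame(spec2$marginals), as.data.frame(spec$marginals))
  expect_identical(generate_study(spec2, 50, seed = 3),
                   generate_study(spec, 50, seed = 3))
})

test_that("the packaged example config is the calibrated default", {
  path <- system.file("extdata", "default_generator.yaml",
                      package = "priorsim")
  spec <- read_generator_config(path)
  expect_equal(spec$coefficients, default_generator()$coefficients)
  expect_identical(generate_study(spec, 20, seed = 1),
                   generate_study(default_generator(), 20, seed = 1))
})

test_that("study datasets round-trip through CSV", {
  spec <- default_generator()
  d <- generate_study(spec, 40, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(d, path)
  d2 <- read_study_csv(path)
  expect_equal(names(d2), c(candidate_variables(), "y"))
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})
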