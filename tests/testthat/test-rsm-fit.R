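test_that("zero-noise linear data are interpolated exactly (NO_PH)", {
  d <- expand.grid(ph = c(3, 5, 7), gradient_time_min = c(20, 60))
  d$retention_time_min <- exp(2 + 0.01 * d$gradient_time_min)
  fit <- rsm_fit(d, case = "NO_PH")
  expect_equal(unname(coef(fit)), c(2, 0.01), tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-10)
  expect_equal(fit$residual_df, nrow(d) - 2L)
})

test_that("coefficients match a normal-equations oracle on a fixed design", {
  d <- data.frame(
    ph = c(2.7, 3.5, 5, 6.5, 8, 2.7, 3.5, 5, 6.5, 8),
    gradient_time_min = rep(c(20, 60), each = 5),
    retention_time_min = c(5.2, 6.7, 9.1, 7.4, 4.9,
                           8.3, 11.2, 15.8, 12.1, 7.7))
  fit <- rsm_fit(d, case = "TWO_PLATEAU")
  X <- cbind(1, d$ph, d$gradient_time_min, d$ph^2, d$ph^3,
             d$ph * d$gradient_time_min)
  beta <- oracle_ols(X, log(d$retention_time_min))
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-6)
  # residual sd from first principles
  rss <- sum((log(d$retention_time_min) - X %*% beta)^2)
  expect_equal(fit$residual_sd, sqrt(rss / (10 - 6)), tolerance = 1e-6)
})

test_that("log-scale residuals sum to zero (intercept present)", {
  for (case in c("NO_PH", "ONE_PLATEAU", "TWO_PLATEAU")) {
    d <- random_design(case, seed = 42)
    fit <- rsm_fit(d, case = case)
    expect_lt(abs(sum(residuals(fit))), 1e-10)
  }
})

test_that("NO_PH predictions are invariant to pH", {
  d <- random_design("NO_PH", seed = 7)
  fit <- rsm_fit(d, case = "NO_PH")
  p1 <- predict(fit, data.frame(ph = 3, gradient_time_min = 40),
                warn_extrapolation = FALSE)
  p2 <- predict(fit, data.frame(ph = 7.5, gradient_time_min = 40),
                warn_extrapolation = FALSE)
  expect_identical(p1, p2)
})

test_that("polynomial evaluation matches term-by-term hand evaluation", {
  set.seed(11)
  d <- random_design("TWO_PLATEAU", seed = 11)
  fit <- rsm_fit(d, case = "TWO_PLATEAU")
  b <- coef(fit)
  nd <- data.frame(ph = runif(20, 2.7, 8), gradient_time_min = runif(20, 20, 60))
  manual <- b[1] + b[2] * nd$ph + b[3] * nd$gradient_time_min +
    b[4] * nd$ph^2 + b[5] * nd$ph^3 +
    b[6] * nd$ph * nd$gradient_time_min
  expect_equal(predict(fit, nd, type = "log"), unname(manual),
               tolerance = 1e-12)
})

test_that("degenerate and deficient designs are rejected with context", {
  d <- data.frame(ph = c(3, 3, 3, 5, 5, 5), gradient_time_min = rep(40, 6),
                  retention_time_min = runif(6, 5, 10))
  expect_error(rsm_fit(d, case = "NO_PH"), "2 distinct gradient times")
  d2 <- random_design("ONE_PLATEAU", seed = 3)
  d2$ph <- rep(c(3, 5), 5)
  expect_error(rsm_fit(d2, case = "ONE_PLATEAU"), "3 distinct pH")
  d3 <- random_design("TWO_PLATEAU", seed = 3)
  d3$retention_time_min[4] <- -1
  expect_error(rsm_fit(d3, case = "TWO_PLATEAU"), "non-positive retention")
  # too few observations for the coefficient count
  d4 <- data.frame(ph = c(3, 5, 7), gradient_time_min = c(20, 60, 40),
                   retention_time_min = c(5, 6, 7))
  expect_error(rsm_fit(d4, case = "ONE_PLATEAU"), "more than 5 observations")
})

test_that("calibration and prediction diagnostics follow their definitions", {
  d <- random_design("NO_PH", seed = 5)
  fit <- rsm_fit(d, case = "NO_PH")
  # perfect predictions: zero errors
  perfect <- d
  perfect$retention_time_min <- fitted(fit)
  m <- prediction_metrics(fit, perfect)
  expect_equal(m$rmse, 0, tolerance = 1e-12)
  expect_equal(m$mape, 0, tolerance = 1e-12)
  # single observation, predicted 9.5 vs observed 10
  one <- data.frame(ph = 4, gradient_time_min = 40, retention_time_min = 10)
  fit_const <- fit
  fit_const$coefficients <- c("(Intercept)" = log(9.5), tg = 0)
  m1 <- prediction_metrics(fit_const, one, warn_extrapolation = FALSE)
  expect_equal(m1$per_condition$abs_error_min, -0.5, tolerance = 1e-12)
  expect_equal(m1$per_condition$rel_error_pct, -5, tolerance = 1e-12)
  expect_equal(m1$rmse, 0.5, tolerance = 1e-12)
  expect_equal(m1$mape, 5, tolerance = 1e-12)
  expect_error(prediction_metrics(fit, d[0, ]), "no observations")
})

test_that("extrapolation beyond the training box warns but proceeds", {
  d <- random_design("NO_PH", seed = 9)
  fit <- rsm_fit(d, case = "NO_PH")
  expect_warning(
    p <- predict(fit, data.frame(ph = 5, gradient_time_min = 80)),
    "outside the training")
  expect_true(is.finite(p))
})
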