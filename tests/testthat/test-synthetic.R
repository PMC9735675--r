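mid_acid_truth <- function(noise_sd = 0) {
  # mid-range pKa, broad transition, unit log amplitude, common tG slope
  sigmoid_truth(compound_spec("probe", 5.4, 0.5, 0.5),
                neutral_intercept = 2.9, neutral_slope = 0.011,
                ionized_intercept = 1.9, ionized_slope = 0.011,
                hill_slope = 0.5, acid_or_base = "acid",
                noise_sd = noise_sd)
}

test_that("the sigmoid ground truth has the expected geometry", {
  tr <- mid_acid_truth()
  at <- function(ph, tg) true_log_tr(tr, data.frame(ph = ph,
                                                    gradient_time_min = tg))
  # at pH = pKa the two forms contribute equally
  expect_equal(at(5.4, 40), (2.9 + 1.9) / 2 + 0.011 * 40, tolerance = 1e-12)
  # far above the pKa an acid is fully ionized
  expect_equal(at(20, 40), 1.9 + 0.011 * 40, tolerance = 1e-4)
  # equal neutral and ionized forms: pH has no effect anywhere
  flat <- sigmoid_truth(compound_spec("f", 5, 0.5, 0.5), 2, 0.01, 2, 0.01,
                        acid_or_base = "acid")
  expect_equal(at2 <- true_log_tr(flat, data.frame(
    ph = c(2.7, 5, 8), gradient_time_min = rep(30, 3))),
    rep(2 + 0.3, 3), tolerance = 1e-12)
  # a base mirrors the acid: retention rises with pH
  base <- sigmoid_truth(compound_spec("b", 5, 0.5, 0.5), 3, 0.01, 2, 0.01,
                        acid_or_base = "base")
  lows <- true_log_tr(base, data.frame(ph = c(3, 7), gradient_time_min = 30))
  expect_lt(lows[1], lows[2])
})

test_that("observations reproduce the truth exactly at zero noise", {
  obs <- generate_observations(mid_acid_truth(0), training_design(),
                               seed = 1)
  expect_equal(log(obs$retention_time_min),
               true_log_tr(mid_acid_truth(0), obs), tolerance = 1e-12)
  # determinism and RNG hygiene
  o1 <- generate_observations(mid_acid_truth(0.05), training_design(),
                              seed = 7)
  o2 <- generate_observations(mid_acid_truth(0.05), training_design(),
                              seed = 7)
  expect_identical(o1, o2)
})

test_that("observation noise has the configured log-scale spread", {
  tr <- mid_acid_truth(0.08)
  one_cond <- data.frame(ph = 5, gradient_time_min = 40)
  obs <- generate_observations(tr, one_cond[rep(1, 10000), ], seed = 3)
  expect_lt(abs(sd(log(obs$retention_time_min)) - 0.08) / 0.08, 0.05)
})

test_that("the cubic model recovers a mid-pKa sigmoid truth closely", {
  tr <- mid_acid_truth(0)
  obs <- generate_observations(tr, training_design(), seed = 1)
  fit <- rsm_fit(obs[c("ph", "gradient_time_min", "retention_time_min")],
                 compound = tr$compound)
  expect_identical(fit$case, "TWO_PLATEAU")
  dense <- expand.grid(ph = seq(2.7, 8, by = 0.05),
                       gradient_time_min = c(20, 40, 60))
  err <- predict(fit, dense, type = "log", warn_extrapolation = FALSE) -
    true_log_tr(tr, dense)
  expect_lte(max(abs(err)), 0.02)
})

test_that("a pH-independent truth is recovered exactly by the NO_PH model", {
  flat <- sigmoid_truth(compound_spec("f", numeric(0), 0.5, 0.5),
                        2.2, 0.012, noise_sd = 0)
  obs <- generate_observations(flat, training_design(), seed = 2)
  fit <- rsm_fit(obs[c("ph", "gradient_time_min", "retention_time_min")],
                 compound = flat$compound)
  expect_identical(fit$case, "NO_PH")
  expect_equal(unname(coef(fit)), c(2.2, 0.012), tolerance = 1e-6)
  expect_lt(fit$residual_sd, 1e-8)
})

test_that("prediction error grows with the observation noise", {
  new_cond <- data.frame(ph = c(3, 6), gradient_time_min = c(40, 40))
  rmse_at <- function(noise_sd, seed) {
    tr <- mid_acid_truth(noise_sd)
    obs <- generate_observations(tr, training_design(), seed = seed)
    fit <- rsm_fit(obs[c("ph", "gradient_time_min", "retention_time_min")],
                   compound = tr$compound)
    truth_new <- new_cond
    truth_new$retention_time_min <- exp(true_log_tr(mid_acid_truth(0),
                                                    new_cond))
    prediction_metrics(fit, truth_new, warn_extrapolation = FALSE)$rmse
  }
  rmse <- sapply(c(0.01, 0.03, 0.1), function(s)
    mean(sapply(1:3, function(seed) rmse_at(s, seed))))
  expect_true(all(diff(rmse) > 0))
})

test_that("mixtures concatenate compounds with matching metadata", {
  mix <- demo_mixture(seed = 11)
  expect_setequal(unique(mix$retention$compound), mix$metadata$name)
  expect_equal(nrow(mix$retention), 7 * 10)
  expect_true(all(mix$retention$retention_time_min > 0))
  # metadata round-trips into specs that span all three model cases
  specs <- as_compound_specs(mix$metadata)
  cases <- vapply(specs, select_equation, character(1))
  expect_setequal(unique(cases), c("NO_PH", "ONE_PLATEAU", "TWO_PLATEAU"))
  expect_identical(demo_mixture(seed = 11), mix)
  # duplicate names are rejected
  tr <- demo_truths()
  expect_error(generate_mixture(tr[c(1, 1)], training_design()),
               "duplicate|at least 2")
})
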