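# The square-root-scale calibration fit and its derived equations.

test_that("noise-free data is interpolated exactly and R^2 is 1", {
  cohort <- generate_cohort(10, 10, seed = 2)
  truth <- truth_parameters(residual_sd_sqrt_met = 0)
  obs <- simulate_observations(cohort, truth, seed = 2)
  # zero-noise fixture: silence summary.lm's perfect-fit warning
  fit <- suppressWarnings(fit_calibration(obs))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  eqs <- stratum_equations(fit)
  for (s in stratum_levels()) {
    b <- truth$betas[truth$betas$stratum == s, ]
    expect_equal(eqs[[s]]$b0, b$b0, tolerance = 1e-8)
    expect_equal(eqs[[s]]$b1, b$b1, tolerance = 1e-8)
  }
})

test_that("coefficients match an independent normal-equations solve", {
  set.seed(42)
  obs <- random_obs_fixture(45)
  fit <- fit_calibration(obs)
  expect_equal(unname(fit$beta), unname(ols_oracle(obs)),
               tolerance = 1e-10)
})

test_that("a hand-computable single-stratum fixture matches the oracle", {
  obs <- tibble::tibble(
    stratum = rep("GT3X_hip", 10),
    activity = c(0, 100, 400, 900, 1600, 2500, 3600, 4900, 6400, 8100),
    met = c(1.2, 1.7, 2.4, 3.3, 4.4, 5.7, 7.2, 8.9, 10.8, 12.9)
  )
  fit <- fit_calibration(obs)
  expect_equal(length(fit$beta), 2)
  expect_equal(unname(fit$beta), unname(ols_oracle(obs)),
               tolerance = 1e-10)
  expect_equal(fit$n_obs, 10)
  expect_equal(length(fit$residuals), fit$n_obs)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  # covariance symmetric positive semi-definite
  expect_equal(fit$cov, t(fit$cov))
  expect_true(all(eigen(fit$cov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("degenerate designs are rejected with informative errors", {
  obs <- tibble::tibble(stratum = rep("GT3X_hip", 12),
                        activity = rep(100, 12), met = runif(12, 2, 3))
  expect_error(fit_calibration(obs), "rank-deficient")
  expect_error(fit_calibration(random_obs_fixture(9)[1:9, ]),
               "at least 10")
  bad <- random_obs_fixture(20)
  bad$met[3] <- 0
  expect_error(fit_calibration(bad), "positive")
})

test_that("stratum equations collapse the dummy coding correctly", {
  set.seed(9)
  obs <- random_obs_fixture(80)
  fit <- fit_calibration(obs)
  # reference stratum: (beta0, beta1) unchanged
  ref <- stratum_equation(fit, "GT3X", "hip")
  expect_equal(ref$b0, unname(fit$beta["(Intercept)"]))
  expect_equal(ref$b1, unname(fit$beta["sqrt_act"]))
  # explicit a' Sigma a linear-algebra oracle for a non-reference stratum
  eq <- stratum_equation(fit, "ACTT", "wrist")
  nm <- names(fit$beta)
  a0 <- as.numeric(nm %in% c("(Intercept)", "stratumACTT_wrist"))
  a1 <- as.numeric(nm %in% c("sqrt_act", "sqrt_act:stratumACTT_wrist"))
  expect_equal(eq$b0, sum(a0 * fit$beta))
  expect_equal(eq$cov2[1, 1], as.numeric(t(a0) %*% fit$cov %*% a0))
  expect_equal(eq$cov2[2, 2], as.numeric(t(a1) %*% fit$cov %*% a1))
  expect_equal(eq$cov2[1, 2], as.numeric(t(a0) %*% fit$cov %*% a1))
  expect_error(stratum_equation(fit, "GT3X", "ankle"))
})

test_that("dummy-coded fit equals separate per-stratum fits", {
  # the model is saturated in stratum, so merging offsets and refitting each
  # stratum alone gives identical (b0, b1)
  set.seed(12)
  obs <- random_obs_fixture(100)
  eqs <- stratum_equations(fit_calibration(obs))
  for (s in stratum_levels()) {
    sub <- obs[obs$stratum == s, ]
    single <- lm(sqrt(met) ~ sqrt(activity), data = sub)
    expect_equal(eqs[[s]]$b0, unname(coef(single)[1]), tolerance = 1e-9)
    expect_equal(eqs[[s]]$b1, unname(coef(single)[2]), tolerance = 1e-9)
  }
})

test_that("predict_met is the squared calibration line", {
  eq <- make_stratum_equation(1.062, 0.0199)
  expect_equal(predict_met(eq, 0), 1.062^2)
  act <- seq(0, 10000, length = 50)
  expect_true(all(diff(predict_met(eq, act)) > 0))
  expect_error(predict_met(eq, -5), "non-negative")
  neg <- make_stratum_equation(-0.5, 0.001)
  expect_error(predict_met(neg, 100), "out of domain")
})

test_that("published reference coefficients reproduce their own cut-points", {
  ref <- reference_calibration()
  row <- ref[ref$stratum == "GT3X_hip", ]
  expect_equal(row$b0, 1.062)
  expect_equal(row$b1, 0.0199)
  eq <- make_stratum_equation(row$b0, row$b1, "GT3X", "hip")
  expect_equal(invert_cutpoint(eq, 3), row$cp3, tolerance = 0.02)
})

test_that("speed correlations match the textbook formula", {
  obs <- tibble::tibble(
    participant = paste0("P", 1:5), condition = letters[1:5],
    speed = c(0, 3, 5, 7, 9),
    stratum = "GT3X_hip",
    activity = c(2, 15, 40, 80, 140),
    met = c(1, 2.4, 3.9, 7.1, 10.2)
  )
  out <- pearson_speed_correlations(obs)
  r_manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(out$r[out$target == "met"], r_manual(obs$speed, obs$met))
  expect_equal(out$r[out$target == "activity_GT3X_hip"],
               r_manual(obs$speed, obs$activity))
  # perfectly (anti-)linear sets
  lin <- obs; lin$met <- 2 * lin$speed + 1
  expect_equal(pearson_speed_correlations(lin)$r[1], 1)
  anti <- obs; anti$met <- 20 - 2 * anti$speed
  expect_equal(pearson_speed_correlations(anti)$r[1], -1)
})

test_that("two-cell ANOVA equals the squared two-sample t statistic", {
  set.seed(4)
  obs <- tibble::tibble(
    condition = rep(c("rest", "walk3"), each = 8),
    stratum = "GT3X_hip",
    activity = c(rnorm(8, 100, 10), rnorm(8, 400, 10))^2 / 100
  )
  res <- anova_counts(obs)
  tt <- t.test(sqrt(obs$activity) ~ obs$condition, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$df_between, 1)
  expect_true(res$eta_squared >= 0 && res$eta_squared <= 1)
})

test_that("Bland-Altman bias and limits behave under known offsets", {
  set.seed(6)
  obs <- random_obs_fixture(60)
  eqs <- stratum_equations(fit_calibration(obs))
  # predictions identical to measurements: zero bias, zero-width limits
  perfect <- obs
  for (s in stratum_levels()) {
    i <- perfect$stratum == s
    perfect$met[i] <- predict_met(eqs[[s]], perfect$activity[i])
  }
  ba0 <- bland_altman(eqs, perfect)
  expect_equal(ba0$bias, rep(0, 4), tolerance = 1e-12)
  expect_equal(ba0$loa_high - ba0$loa_low, rep(0, 4), tolerance = 1e-12)
  # constant -0.5 MET shift in the measurements: bias +0.5
  shifted <- perfect
  shifted$met <- shifted$met - 0.5
  ba <- bland_altman(eqs, shifted)
  expect_equal(ba$bias, rep(0.5, 4), tolerance = 1e-12)
})

test_that("well-specified synthetic data shows negligible MET bias", {
  cohort <- generate_cohort(34, 22, seed = 8)
  obs <- simulate_observations(cohort, truth_parameters(), seed = 8)
  fit <- fit_calibration(obs)
  ba <- bland_altman(stratum_equations(fit), obs)
  expect_true(all(abs(ba$bias) < 0.1))
})

test_that("residual diagnostics report sane statistics and flag
           heteroscedasticity", {
  cohort <- generate_cohort(17, 11, seed = 10)
  obs <- simulate_observations(cohort, truth_parameters(), seed = 10)
  fit <- fit_calibration(obs)
  d <- residual_diagnostics(fit)
  expect_equal(d$n, fit$n_obs)
  expect_equal(nrow(d$qq), fit$n_obs)
  expect_true(d$shapiro_w > 0 && d$shapiro_w <= 1)
  # inject variance increasing strongly with the linear predictor
  set.seed(10)
  het <- obs
  scaled <- sqrt(het$activity) / max(sqrt(het$activity))
  het$met <- pmax(0.05, sqrt(het$met) +
                    rnorm(nrow(het), 0, 0.01 + 0.4 * scaled))^2
  d_het <- residual_diagnostics(fit_calibration(het))
  expect_lt(d_het$bp_p, 0.05)
})
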