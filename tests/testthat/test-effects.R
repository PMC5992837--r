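test_that("counterfactual equals the with-policy prediction when the policy is null", {
  X <- its_design()
  b <- default_cost_beta()
  b[c("sps", "time_after_sps")] <- 0
  cfg <- sim_config(beta = list(cost_total = b), noise_sd = 0, seed = 1)
  y <- sim_series(cfg, "cost_total")
  f <- suppressWarnings(its_fit(y, X, method = "ols", dw_nsim = 0))
  cf <- counterfactual(f)
  expect_equal(cf$counterfactual, cf$fitted, tolerance = 1e-8)
  eff <- policy_effect(f)
  expect_equal(eff$cumulative_percent, c(0, 0), tolerance = 1e-8)
  expect_equal(eff$endpoint_percent, c(0, 0), tolerance = 1e-8)
})

test_that("counterfactual and with-policy predictions coincide pre-policy", {
  X <- its_design()
  y <- sim_series(sim_config(seed = 3), "cost_total")
  f <- its_fit(y, X, dw_nsim = 0)
  cf <- counterfactual(f)
  pre <- X$sps == 0
  expect_equal(cf$counterfactual[pre], cf$fitted[pre])
  expect_false(isTRUE(all.equal(cf$counterfactual[!pre], cf$fitted[!pre])))
})

test_that("noise-free counterfactual equals the closed-form trend extension", {
  X <- its_design()
  b <- c(20, 0.3, -1, -0.1, -4, 0.25, -2)
  cfg <- sim_config(beta = list(cost_total = b), noise_sd = 0, seed = 5)
  y <- sim_series(cfg, "cost_total")
  f <- suppressWarnings(its_fit(y, X, method = "ols", dw_nsim = 0))
  t <- X$time
  # by hand: trend without the SPS terms
  hand <- b[1] + b[2] * t + b[3] * X$opip + b[4] * X$time_after_opip +
    b[7] * X$feb
  expect_equal(counterfactual(f)$counterfactual, hand, tolerance = 1e-7)
})

test_that("a pure level shift on a flat trend gives exactly that percent", {
  X <- its_design()
  b <- c(100, 0, 0, 0, -10, 0, 0)
  cfg <- sim_config(beta = list(cost_total = b), noise_sd = 0, seed = 7)
  y <- sim_series(cfg, "cost_total")
  f <- suppressWarnings(its_fit(y, X, method = "ols", dw_nsim = 0))
  eff <- policy_effect(f, horizons = c(12, 15))
  expect_equal(eff$cumulative_percent, c(-10, -10), tolerance = 1e-8)
  expect_equal(eff$endpoint_percent, c(-10, -10), tolerance = 1e-8)
  expect_equal(eff$monthly_average_percent, c(-10, -10), tolerance = 1e-8)
})

test_that("noise-free effects match an independent symbolic evaluation", {
  X <- its_design()
  b <- c(50, 0.8, 3, -0.2, -6, 0.5, -1.5)
  cfg <- sim_config(beta = list(cost_total = b), noise_sd = 0, seed = 9)
  y <- sim_series(cfg, "cost_total")
  f <- suppressWarnings(its_fit(y, X, method = "ols", dw_nsim = 0))
  eff <- policy_effect(f, horizons = c(12, 15))

  # independent evaluation straight from the formulas on the true beta
  t <- X$time
  yhat <- b[1] + b[2] * t + b[3] * X$opip + b[4] * X$time_after_opip +
    b[5] * X$sps + b[6] * X$time_after_sps + b[7] * X$feb
  ycf <- b[1] + b[2] * t + b[3] * X$opip + b[4] * X$time_after_opip +
    b[7] * X$feb
  post <- which(X$sps == 1)
  cum <- 100 * (sum(yhat[post[1:12]]) - sum(ycf[post[1:12]])) /
    sum(ycf[post[1:12]])
  ep15 <- 100 * (yhat[post[15]] - ycf[post[15]]) / ycf[post[15]]
  ma15 <- mean(100 * (yhat[post[1:15]] - ycf[post[1:15]]) / ycf[post[1:15]])
  expect_equal(eff$cumulative_percent[2], cum, tolerance = 1e-7)
  expect_equal(eff$endpoint_percent[2], ep15, tolerance = 1e-7)
  expect_equal(eff$monthly_average_percent[2], ma15, tolerance = 1e-7)

  # effects from the fit equal effects from the true coefficients
  f$coefficients[] <- b
  eff_true <- policy_effect(f, horizons = c(12, 15))
  expect_equal(eff$cumulative_percent, eff_true$cumulative_percent,
               tolerance = 1e-7)
})

test_that("effect horizons beyond the window and non-positive denominators error", {
  X <- its_design()
  y <- sim_series(sim_config(seed = 11), "cost_total")
  f <- its_fit(y, X, dw_nsim = 0)
  expect_error(policy_effect(f, horizons = 16), "does not cover")
  f2 <- f
  f2$coefficients[] <- c(-5, 0, 0, 0, 1, 0, 0)
  expect_error(policy_effect(f2), "not positive")
})

test_that("forecast band matches the textbook OLS mean-prediction interval", {
  X <- its_design()
  M <- design_matrix(X)
  y <- sim_series(sim_config(seed = 13), "cost_total")$value
  f <- its_fit(y, X, method = "ols", dw_nsim = 0)
  band <- forecast_band(f, level = 0.95)
  # independent route: se^2 = s2 * x' (X'X)^-1 x at the counterfactual rows
  Mcf <- M
  Mcf[, c("sps", "time_after_sps")] <- 0
  s2 <- sum(residuals(f)^2) / (54 - 7)
  XtXi <- solve(t(M) %*% M)
  se_hand <- sqrt(s2 * rowSums((Mcf %*% XtXi) * Mcf))
  expect_equal(band$se, se_hand, tolerance = 1e-8)
  expect_equal(band$upper - band$counterfactual,
               stats::qnorm(0.975) * se_hand, tolerance = 1e-8)
})

test_that("band width collapses as level drops and grows with level", {
  X <- its_design()
  y <- sim_series(sim_config(seed = 15), "cost_total")
  f <- its_fit(y, X, dw_nsim = 0)
  tiny <- forecast_band(f, level = 1e-9)
  expect_equal(tiny$upper, tiny$counterfactual, tolerance = 1e-6)
  w90 <- forecast_band(f, level = 0.90)
  w99 <- forecast_band(f, level = 0.99)
  expect_true(all(w99$upper - w99$lower >= w90$upper - w90$lower))
  expect_error(forecast_band(f, level = 1.2), "inside")
})

test_that("annual growth reproduces the published per-1000 transitions", {
  g <- annual_growth(published_rates())
  pick <- function(cat, to) g[g$category == cat & g$to == to, ]
  neph <- pick("nephropathy", "period2")
  expect_equal(neph$change, 0.2)
  expect_equal(neph$growth_percent, 43)
  ret <- pick("retinopathy", "period4")
  expect_equal(ret$change, 0)
  expect_equal(ret$growth_percent, 0)
  cvd <- pick("cardiovascular", "period4")
  expect_equal(cvd$change, -0.14)
  expect_equal(cvd$growth_percent, -5)
})

test_that("the full published growth column is reproduced (15 transitions)", {
  g <- annual_growth(published_rates())
  expect_equal(nrow(g), 15)
  expected <- list(
    retinopathy = list(change = c(0.02, 0.01, 0), pct = c(7, 3, 0)),
    cataract = list(change = c(0.10, 0.11, 0.04), pct = c(5, 5, 2)),
    nephropathy = list(change = c(0.20, 0.07, 0.01), pct = c(43, 10, 1)),
    cardiovascular = list(change = c(0.35, 0.06, -0.14), pct = c(14, 2, -5)),
    foot_lesions = list(change = c(0.13, 0.09, 0.06), pct = c(33, 17, 10)))
  for (cat in names(expected)) {
    gc <- g[g$category == cat, ]
    expect_equal(gc$change, expected[[cat]]$change, info = cat)
    expect_equal(gc$growth_percent, expected[[cat]]$pct, info = cat)
  }
})

test_that("growth rejects degenerate inputs and accepts matrix form", {
  expect_error(annual_growth(data.frame(category = "x", period = "p1",
                                        rate = 1)), "at least 2")
  expect_error(annual_growth(data.frame(category = "x", period = c("p1", "p2"),
                                        rate = c(0, 1))), "zero earlier rate")
  m <- default_complication_rates()
  g <- annual_growth(m)
  expect_equal(nrow(g), 15)
  expect_equal(g[g$category == "nephropathy" & g$to == "period2",
                 "growth_percent"], 43)
})

test_that("procedure_rates recovers configured rates from simulated events", {
  cfg <- sim_config(cohort_size = 4e6, seed = 17)
  proc <- sim_procedures(cfg)
  r <- procedure_rates(proc, 4e6)
  truth <- default_complication_rates()
  for (cat in rownames(truth)) {
    est <- r$rate[r$category == cat]
    expect_equal(est, truth[cat, 1:4], tolerance = 0.05, ignore_attr = TRUE)
  }
})
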