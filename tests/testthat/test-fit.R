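test_that("OLS interpolates noise-free data and matches the normal equations", {
  X <- its_design()
  cfg0 <- sim_config(noise_sd = 0, seed = 1)
  y0 <- sim_series(cfg0, "cost_total")
  f0 <- suppressWarnings(its_fit(y0, X, method = "ols", dw_nsim = 0))
  expect_lt(max(abs(coef(f0) - attr(y0, "beta")) / abs(attr(y0, "beta"))), 1e-8)

  # 10-point instance against a direct normal-equations solve
  sch <- intervention_schedule(n_months = 10, opip_start = "2009-04",
                               sps_start = "2009-08")
  d10 <- its_design(sch)
  M <- design_matrix(d10)
  set.seed(101)
  y <- drop(M %*% c(5, 1, 2, -0.5, 3, 0.2, -1)) + rnorm(10)
  f <- its_fit(y, d10, method = "ols", dw_nsim = 0)
  beta_ne <- unname(drop(solve(t(M) %*% M, t(M) %*% y)))
  expect_equal(unname(coef(f)), beta_ne, tolerance = 1e-10)
})

test_that("adding a constant shifts only the intercept", {
  X <- its_design()
  cfg <- sim_config(seed = 2)
  y <- sim_series(cfg, "cost_total")$value
  f1 <- its_fit(y, X, method = "ols", dw_nsim = 0)
  f2 <- its_fit(y + 100, X, method = "ols", dw_nsim = 0)
  expect_equal(coef(f2)[["intercept"]], coef(f1)[["intercept"]] + 100)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-10)
})

test_that("singular designs and missing values are rejected", {
  X <- its_design()
  X2 <- X
  X2$feb <- X2$sps  # duplicate column
  y <- sim_series(sim_config(seed = 3), "cost_total")$value
  expect_error(its_fit(y, X2), "singular")
  y[5] <- NA
  expect_error(its_fit(y, X), "missing")
  expect_error(its_fit(1:10, X), "different lengths")
})

test_that("AR(1) ML log-likelihood matches the dense-covariance oracle", {
  X <- its_design()
  M <- design_matrix(X)
  cfg <- sim_config(seed = 19, ar1_rho = 0.5)
  y <- sim_series(cfg, "cost_total")$value
  f <- its_fit(y, X, method = "ar1", dw_nsim = 0)
  ll_dense <- dense_ar1_loglik(y, M, coef(f), f$rho, f$sigma2)
  expect_equal(f$loglik, ll_dense, tolerance = 1e-6)
  # and at off-optimum parameters, the likelihood function itself agrees
  b <- coef(f) * 0.9
  expect_equal(ar1_loglik(y, M, b, 0.3, 2),
               dense_ar1_loglik(y, M, b, 0.3, 2), tolerance = 1e-8)
})

test_that("AR(1) fit at rho = 0 reduces to OLS", {
  X <- its_design()
  cfg <- sim_config(seed = 29, ar1_rho = 0)
  y <- sim_series(cfg, "cost_total")$value
  f_ols <- its_fit(y, X, method = "ols", dw_nsim = 0)
  f_ar1 <- its_fit(y, X, method = "ar1", dw_nsim = 0)
  expect_lt(abs(f_ar1$rho), 0.3)
  expect_true(all(abs(coef(f_ar1) - coef(f_ols)) < 2 * f_ols$se))
})

test_that("profile-likelihood beta is continuous in rho near zero", {
  X <- its_design()
  M <- design_matrix(X)
  y <- sim_series(sim_config(seed = 31), "cost_total")$value
  b_ols <- unname(coef(its_fit(y, X, method = "ols", dw_nsim = 0)))
  dev <- vapply(c(0.2, 0.1, 0.05, 0.01),
                function(r) max(abs(ar1_profile(y, M, r)$beta - b_ols)),
                numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 1e-2)
})

test_that("AR(1) ML recovers rho in moderate samples", {
  sch <- intervention_schedule(n_months = 200, opip_start = "2014-01",
                               sps_start = "2020-01")
  d <- its_design(sch)
  M <- design_matrix(d)
  beta <- c(10, 0.05, 1, 0.02, -2, -0.05, -0.5)
  set.seed(split_seed(7L, "rho-recovery"))
  rhos <- replicate(120, {
    y <- drop(M %*% beta) + ar1_noise(200, 0.5, 1)
    its_fit(y, d, method = "ar1", dw_nsim = 0)$rho
  })
  mc_se <- stats::sd(rhos) / sqrt(length(rhos))
  # ML rho-hat carries a known O((1 + 3 rho)/n) downward finite-sample bias,
  # inflated by detrending; ~0.025 at n = 200 with 7 regressors
  expect_lt(abs(mean(rhos) - 0.5), 0.04 + 3 * mc_se)
})

test_that("AR(1) fit agrees with an independent GLS cross-check", {
  skip_if_not_installed("nlme")
  X <- its_design()
  cfg <- sim_config(seed = 37, ar1_rho = 0.4)
  y <- sim_series(cfg, "cost_total")$value
  f <- its_fit(y, X, method = "ar1", dw_nsim = 0)
  d <- cbind(y = y, as.data.frame(X))
  g <- nlme::gls(y ~ time + opip + time_after_opip + sps + time_after_sps + feb,
                 data = d, correlation = nlme::corAR1(form = ~ time),
                 method = "ML")
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-4)
  expect_equal(f$rho, as.numeric(coef(g$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
})

test_that("Durbin-Watson statistic matches hand arithmetic", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)  # 12 / 4
  expect_equal(durbin_watson(c(1, 2, 3, 4)), 3 / 30)
  expect_error(durbin_watson(c(0, 0, 0, 0)), "all zero")
  expect_error(durbin_watson(c(1, 2)), "at least 3")
  skip_if_not_installed("lmtest")
  # cross-check on regression residuals against lmtest
  X <- its_design()
  y <- sim_series(sim_config(seed = 41), "cost_total")$value
  f <- its_fit(y, X, method = "ols", dw_nsim = 0)
  d <- cbind(y = y, as.data.frame(X))
  lt <- lmtest::dwtest(y ~ time + opip + time_after_opip + sps +
                         time_after_sps + feb, data = d)
  expect_equal(durbin_watson(residuals(f)), unname(lt$statistic),
               tolerance = 1e-10)
})

test_that("DW null simulation centres near 2 and the p-value is scale-free", {
  X <- its_design()
  M <- design_matrix(X)
  set.seed(split_seed(5L, "dw-mean"))
  # raw white noise: E[DW] = 2 (n - 1) / n, within 0.05 of 2 at n = 54
  dws <- replicate(2000, durbin_watson(rnorm(54)))
  expect_lt(abs(mean(dws) - 2), 0.05)
  y <- sim_series(sim_config(seed = 43), "cost_total")$value
  f <- its_fit(y, X, method = "ols", dw_nsim = 0)
  p1 <- dw_pvalue(durbin_watson(residuals(f)), X, n_sim = 500, seed = 9)
  p2 <- dw_pvalue(durbin_watson(residuals(f) * 1000), X, n_sim = 500, seed = 9)
  expect_identical(p1, p2)
})

test_that("model selection prefers the true error structure and breaks ties to OLS", {
  X <- its_design()
  M <- design_matrix(X)
  beta <- default_cost_beta()
  set.seed(split_seed(3L, "selection-small"))
  pick <- function(rho) {
    replicate(60, {
      y <- drop(M %*% beta) + ar1_noise(54, rho, 0.8)
      its_fit(y, X, method = "auto", dw_nsim = 0)$method
    })
  }
  expect_gt(mean(pick(0.7) == "AR1"), 0.9)
  expect_gt(mean(pick(0) == "OLS"), 0.5)

  # constructed tie: select_model must return the OLS fit
  y <- drop(M %*% beta) + rnorm(54)
  f_ols <- its_fit(y, X, method = "ols", dw_nsim = 0)
  f_ar1 <- its_fit(y, X, method = "ar1", dw_nsim = 0)
  f_ar1$aic <- f_ols$aic
  expect_equal(select_model(f_ols, f_ar1)$method, "OLS")
  expect_error(select_model(f_ols, its_fit(y + 1, X, method = "ar1",
                                           dw_nsim = 0)), "identical data")
  expect_error(select_model(f_ar1, f_ols), "in that order")
})

test_that("AIC counts all free parameters", {
  X <- its_design()
  y <- sim_series(sim_config(seed = 47), "cost_total")$value
  f_ols <- its_fit(y, X, method = "ols", dw_nsim = 0)
  f_ar1 <- its_fit(y, X, method = "ar1", dw_nsim = 0)
  expect_equal(f_ols$aic, 2 * 8 - 2 * f_ols$loglik)
  expect_equal(f_ar1$aic, 2 * 9 - 2 * f_ar1$loglik)
  expect_equal(AIC(f_ols), f_ols$aic)
  expect_equal(attr(logLik(f_ar1), "df"), 9)
})

test_that("white-noise check passes i.i.d. residuals and fails AR(1) ones", {
  set.seed(split_seed(1L, "wn"))
  e_iid <- rnorm(54)
  wn <- white_noise_check(e_iid, max_lag = 10)
  expect_true(wn$pass)

  e_ar <- ar1_noise(54, 0.8, 1)
  wn2 <- white_noise_check(e_ar, max_lag = 10)
  expect_false(wn2$pass)
  expect_gt(wn2$acf[1], wn2$bound)

  e_alt <- rep(c(1, -1), 27)
  wn3 <- white_noise_check(e_alt, max_lag = 5)
  expect_false(wn3$pass)
  expect_lt(wn3$acf[1], -0.9)
  expect_error(white_noise_check(rnorm(10), max_lag = 5), "below n / 2")
})

test_that("segment slopes reproduce the published slope combinations", {
  s_const <- segment_slopes(coef_row("cost_total", "constant"))
  expect_equal(round(s_const$slopes[["post_sps"]], 2), 0.49)
  expect_equal(round(s_const$slopes[["post_opip"]], 2), 0.28)

  s_pat <- segment_slopes(coef_row("n_patients", "reduced"))
  expect_equal(s_pat$slopes[["post_opip"]], 5441)
  expect_equal(s_pat$slopes[["post_sps"]], -2082)

  expect_equal(segment_slopes(rep(0, 7))$slopes,
               c(baseline = 0, post_opip = 0, post_sps = 0))
  expect_error(segment_slopes(1:5), "7 coefficients")
})

test_that("fit methods expose the standard modelling interface", {
  X <- its_design()
  y <- sim_series(sim_config(seed = 53), "cost_total")
  f <- its_fit(y, X, dw_nsim = 100)
  expect_s3_class(f, "its_fit")
  expect_length(coef(f), 7)
  expect_equal(dim(vcov(f)), c(7, 7))
  expect_equal(fitted(f) + residuals(f), y$value)
  expect_equal(predict(f), fitted(f))
  ci <- confint(f)
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(54, 3))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
  expect_output(print(f), "segmented regression")
  expect_output(print(summary(f)), "segment slopes")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_invisible(plot(f))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
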