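# Segmented-regression estimation: OLS and exact stationary AR(1) maximum
# likelihood, serial-correlation diagnostics, and AIC-based model selection.
#
# The AR(1) model is y = X beta + eps, eps_t = rho eps_{t-1} + u_t with
# u_t ~ N(0, sigma2) i.i.d. and eps_1 drawn from the stationary law. Its exact
# Gaussian log-likelihood, via the Prais-Winsten transform
#   y*_1 = sqrt(1 - rho^2) y_1,  y*_t = y_t - rho y_{t-1}  (same for X),
# is  -n/2 log(2 pi sigma2) + 1/2 log(1 - rho^2) - S(beta, rho) / (2 sigma2)
# with S the transformed residual sum of squares. rho is estimated by
# profiling this likelihood over a bracketed 1-D search; standard errors come
# from the observed information (numerical Hessian) at the optimum.

pw_transform <- function(z, rho) {
  z <- as.matrix(z)
  n <- nrow(z)
  rbind(sqrt(1 - rho^2) * z[1, , drop = FALSE],
        z[-1, , drop = FALSE] - rho * z[-n, , drop = FALSE])
}

# Exact stationary AR(1) log-likelihood at given parameters.
ar1_loglik <- function(y, X, beta, rho, sigma2) {
  n <- length(y)
  r <- pw_transform(y - drop(X %*% beta), rho)
  S <- sum(r^2)
  -n / 2 * log(2 * pi * sigma2) + 0.5 * log(1 - rho^2) - S / (2 * sigma2)
}

# Profiled (over beta, sigma2) log-likelihood and GLS estimates at fixed rho.
ar1_profile <- function(y, X, rho) {
  ys <- pw_transform(y, rho)
  Xs <- pw_transform(X, rho)
  fit <- stats::lm.fit(Xs, ys)
  S <- sum(fit$residuals^2)
  n <- length(y)
  list(beta = fit$coefficients, sigma2 = S / n,
       loglik = -n / 2 * (log(2 * pi * S / n) + 1) + 0.5 * log(1 - rho^2))
}

check_design_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dep <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design matrix is singular; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
}

fit_response <- function(y) {
  if (is.data.frame(y)) {
    if (!"value" %in% names(y)) stop("series data frame must have a 'value' column")
    y <- y$value
  }
  y <- as.numeric(y)
  if (anyNA(y)) stop("missing monthly values are not allowed in the fit window")
  y
}

sig_marker <- function(p) {
  ifelse(p < 0.001, "§", ifelse(p < 0.01, "†",
    ifelse(p < 0.05, "*", ifelse(p < 0.1, "#", ""))))
}

#' Fit the two-interruption segmented regression
#'
#' Estimates the segmented model
#' `y_t = b0 + b1 time + b2 OPIP + b3 time_after_OPIP + b4 SPS +
#' b5 time_after_SPS + b6 Feb + e_t` by ordinary least squares and/or by
#' exact maximum likelihood under stationary AR(1) errors. With
#' `method = "auto"` both fits are computed and the one with the smaller AIC
#' is returned (ties go to OLS, the model with fewer parameters); the
#' rejected fit is kept in the `alternative` field. AIC counts all free
#' parameters: the 7 coefficients plus the innovation variance (plus the
#' AR(1) coefficient when present), so k = 8 for OLS and 9 for AR(1).
#'
#' The AR(1) coefficient uses the convention that positive `rho` means
#' positive serial correlation. OLS p-values are the classical t-tests; AR(1)
#' p-values are two-sided normal tests on the observed-information standard
#' errors. If the likelihood search ends within 0.001 of the `|rho| < 1`
#' boundary the fit is flagged (`boundary = TRUE`) with a warning.
#'
#' @param y Numeric vector of monthly outcomes, or a data frame with a
#'   `value` column ([sim_series()], one series of [aggregate_monthly()]).
#'   Missing values are an error: the covariates are calendar-defined.
#' @param design An [its_design()] data frame (or any data frame with the six
#'   regressor columns) with as many rows as `y`.
#' @param method `"auto"` (AIC selection), `"ols"`, or `"ar1"`.
#' @param dw_nsim,dw_seed Monte-Carlo size and seed for the Durbin-Watson
#'   p-value of the OLS residuals; `dw_nsim = 0` skips it.
#' @return An object of class `"its_fit"`: coefficients, standard errors and
#'   p-values for b0..b6, `rho` (AR(1) only) with its SE, innovation variance
#'   `sigma2`, `loglik`, `aic`, Durbin-Watson statistic `dw` (with `dw_p`
#'   when simulated), `method`, the full coefficient covariance `vcov`, the
#'   design and response, and (for `method = "auto"`) the non-selected fit.
#' @examples
#' cfg <- sim_config(seed = 42)
#' y <- sim_series(cfg, "cost_total")
#' f <- its_fit(y, its_design())
#' coef(f)
#' @export
its_fit <- function(y, design, method = c("auto", "ols", "ar1"),
                    dw_nsim = 1000L, dw_seed = 1L) {
  method <- match.arg(method)
  y <- fit_response(y)
  X <- design_matrix(design)
  if (nrow(X) != length(y)) stop("y and design have different lengths")
  check_design_rank(X)
  if (method == "ar1" && length(y) < 10L) stop("AR(1) ML requires n >= 10")

  if (method == "ols") return(fit_ols_(y, X, design, dw_nsim, dw_seed))
  if (method == "ar1") return(fit_ar1_(y, X, design, dw_nsim, dw_seed))

  f_ols <- fit_ols_(y, X, design, dw_nsim, dw_seed)
  f_ar1 <- fit_ar1_(y, X, design, dw_nsim = 0L, dw_seed)
  select_model(f_ols, f_ar1)
}

fit_ols_ <- function(y, X, design, dw_nsim, dw_seed) {
  n <- length(y)
  p <- ncol(X)
  lmfit <- stats::lm(y ~ X - 1)
  beta <- stats::coef(lmfit)
  names(beta) <- colnames(X)
  sm <- summary(lmfit)
  se <- sm$coefficients[, 2]
  pval <- sm$coefficients[, 4]
  names(se) <- names(pval) <- colnames(X)
  res <- unname(stats::residuals(lmfit))
  rss <- sum(res^2)
  sigma2 <- rss / n  # ML variance
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- p + 1L
  vc <- stats::vcov(lmfit)
  dimnames(vc) <- list(colnames(X), colnames(X))
  dw <- durbin_watson(res)
  dw_p <- if (dw_nsim > 0) dw_pvalue(dw, X, n_sim = dw_nsim, seed = dw_seed) else NA_real_
  structure(list(coefficients = beta, se = se, pvalues = pval,
                 rho = NULL, rho_se = NULL, sigma2 = sigma2,
                 loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 dw = dw, dw_p = dw_p, method = "OLS",
                 vcov = vc, residuals = res, fitted = drop(X %*% beta),
                 y = y, design = design, n = n, boundary = FALSE),
            class = "its_fit")
}

fit_ar1_ <- function(y, X, design, dw_nsim, dw_seed) {
  n <- length(y)
  p <- ncol(X)
  bound <- 0.999
  opt <- stats::optimize(function(r) ar1_profile(y, X, r)$loglik,
                         c(-bound, bound), maximum = TRUE, tol = 1e-8)
  rho <- opt$maximum
  prof <- ar1_profile(y, X, rho)
  boundary <- abs(rho) > bound - 1e-3
  if (boundary) warning("AR(1) estimate at the |rho| < 1 boundary; fit flagged")

  # observed information at the optimum, in (beta, rho, sigma2) coordinates
  par <- c(prof$beta, rho, prof$sigma2)
  nll <- function(th) {
    r <- th[p + 1L]; s2 <- th[p + 2L]
    if (abs(r) >= 1 || s2 <= 0) return(1e10)
    -ar1_loglik(y, X, th[seq_len(p)], r, s2)
  }
  H <- stats::optimHess(par, nll)
  vc_full <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; standard errors unavailable")
    matrix(NA_real_, p + 2L, p + 2L)
  })
  nm <- c(colnames(X), "rho", "sigma2")
  dimnames(vc_full) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc_full)[seq_len(p)], 0))
  rho_se <- sqrt(max(vc_full["rho", "rho"], 0))
  beta <- prof$beta
  names(beta) <- names(se) <- colnames(X)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  res <- y - drop(X %*% beta)
  k <- p + 2L
  dw <- durbin_watson(res)
  dw_p <- if (dw_nsim > 0) dw_pvalue(dw, X, n_sim = dw_nsim, seed = dw_seed) else NA_real_
  structure(list(coefficients = beta, se = se, pvalues = pval,
                 rho = rho, rho_se = rho_se, sigma2 = prof$sigma2,
                 loglik = prof$loglik, k = k, aic = 2 * k - 2 * prof$loglik,
                 dw = dw, dw_p = dw_p, method = "AR1",
                 vcov = vc_full[seq_len(p), seq_len(p)],
                 vcov_full = vc_full,
                 residuals = res, fitted = drop(X %*% beta),
                 y = y, design = design, n = n, boundary = boundary),
            class = "its_fit")
}

#' Choose between the OLS and AR(1) fits by AIC
#'
#' Returns the fit with the smaller AIC; ties go to OLS, the model with fewer
#' parameters. Both fits must be on the same response and design. The
#' rejected fit is attached as `alternative`, and the OLS Durbin-Watson
#' p-value (when computed) is carried on the selected fit as `dw_p_ols`.
#'
#' @param ols,ar1 `"its_fit"` objects with methods `"OLS"` and `"AR1"`.
#' @return The selected `"its_fit"`.
#' @export
select_model <- function(ols, ar1) {
  stopifnot(inherits(ols, "its_fit"), inherits(ar1, "its_fit"))
  if (ols$method != "OLS" || ar1$method != "AR1") {
    stop("select_model expects an OLS fit and an AR1 fit, in that order")
  }
  if (ols$n != ar1$n || !isTRUE(all.equal(ols$y, ar1$y))) {
    stop("the two fits are not on identical data")
  }
  sel <- if (ar1$aic < ols$aic) ar1 else ols
  alt <- if (ar1$aic < ols$aic) ols else ar1
  sel$alternative <- alt[setdiff(names(alt), "alternative")]
  sel$dw_p_ols <- ols$dw_p
  sel
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)`; near 2 under no serial
#' correlation, below 2 under positive autocorrelation.
#'
#' @param residuals Numeric vector of at least 3 residuals, not all zero.
#' @return The statistic (in `[0, 4]`).
#' @examples
#' durbin_watson(c(1, -1, 1, -1))  # 3
#' @export
durbin_watson <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 3L) stop("need at least 3 residuals")
  denom <- sum(residuals^2)
  if (denom == 0) stop("Durbin-Watson undefined: residuals are all zero")
  sum(diff(residuals)^2) / denom
}

#' Monte-Carlo Durbin-Watson p-value
#'
#' Tail probability `P(DW <= observed)` under i.i.d. Gaussian errors
#' projected through the same design (one-sided, against positive
#' autocorrelation). The null distribution depends on the design only, so
#' the p-value is invariant to residual scaling.
#'
#' @param dw Observed statistic.
#' @param X Design (an [its_design()] data frame or numeric model matrix).
#' @param n_sim Number of null replicates.
#' @param seed Integer seed for the null simulation.
#' @return Monte-Carlo p-value in `[0, 1]`.
#' @export
dw_pvalue <- function(dw, X, n_sim = 2000L, seed = 1L) {
  if (is.data.frame(X)) X <- design_matrix(X)
  qx <- qr(X)
  set.seed(split_seed(seed, "dw-null"))
  sims <- replicate(n_sim, {
    e <- qr.resid(qx, stats::rnorm(nrow(X)))
    sum(diff(e)^2) / sum(e^2)
  })
  mean(sims <= dw)
}

#' Residual white-noise check
#'
#' Sample autocorrelations and partial autocorrelations of the residuals up
#' to `max_lag`; the check passes when every ACF and PACF value within those
#' lags lies inside the `+/- 1.96 / sqrt(n)` white-noise band.
#'
#' @param residuals Numeric residual vector.
#' @param max_lag Largest lag to examine; must be below `n / 2`.
#' @return A list with `pass` (logical), `acf`, `pacf` (per-lag values,
#'   lags 1..max_lag) and `bound`.
#' @export
white_noise_check <- function(residuals, max_lag = 12L) {
  n <- length(residuals)
  if (max_lag >= n / 2) stop("max_lag must be below n / 2")
  a <- stats::acf(residuals, lag.max = max_lag, plot = FALSE)$acf[-1]
  p <- stats::pacf(residuals, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  bound <- 1.96 / sqrt(n)
  list(pass = all(abs(c(a, p)) <= bound),
       acf = as.numeric(a), pacf = as.numeric(p), bound = bound)
}

#' Segment slopes and level changes implied by the coefficients
#'
#' The three trend segments of the two-interruption model: baseline slope
#' `b1`, post-OPIP slope `b1 + b3`, post-SPS slope `b1 + b3 + b5`; and the
#' baseline level `b0` with the OPIP and SPS level changes `b2`, `b4`.
#'
#' @param fit An `"its_fit"`, or a numeric 7-vector of coefficients in model
#'   order (b0..b6).
#' @return A list with numeric vectors `slopes` (baseline, post_opip,
#'   post_sps) and `levels` (baseline, opip_change, sps_change).
#' @examples
#' segment_slopes(c(6.240, 0.229, -2.264, 0.049, 0.384, 0.211, -0.856))
#' @export
segment_slopes <- function(fit) {
  b <- if (inherits(fit, "its_fit")) fit$coefficients else as.numeric(fit)
  if (length(b) != 7L) stop("expected 7 coefficients (b0..b6)")
  list(slopes = c(baseline = b[[2]],
                  post_opip = b[[2]] + b[[4]],
                  post_sps = b[[2]] + b[[4]] + b[[6]]),
       levels = c(baseline = b[[1]],
                  opip_change = b[[3]],
                  sps_change = b[[5]]))
}

# ---- S3 methods -----------------------------------------------------------

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
logLik.its_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
residuals.its_fit <- function(object, ...) object$residuals

#' @export
fitted.its_fit <- function(object, ...) object$fitted

#' @export
confint.its_fit <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  if (missing(parm)) parm <- names(b)
  q <- stats::qt((1 + level) / 2, df = object$n - length(b))
  ci <- cbind(b - q * object$se, b + q * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                               trim = TRUE), "%")
  ci[parm, , drop = FALSE]
}

#' Predict from a segmented-regression fit
#'
#' @param object An `"its_fit"`.
#' @param newdata Optional design data frame; defaults to the fitted design.
#' @param counterfactual If `TRUE`, the second-interruption columns (`sps`,
#'   `time_after_sps`) are forced to zero: the prediction "if the policy were
#'   not in existence".
#' @param ... Unused.
#' @return Numeric vector of predicted means.
#' @export
predict.its_fit <- function(object, newdata = NULL, counterfactual = FALSE, ...) {
  d <- if (is.null(newdata)) object$design else newdata
  X <- design_matrix(d)
  if (counterfactual) X[, c("sps", "time_after_sps")] <- 0
  drop(X %*% object$coefficients)
}

#' Simulate new series from a fitted model
#'
#' Draws response vectors from the fitted Gaussian model: OLS fits give
#' i.i.d. errors with the ML variance, AR(1) fits give stationary AR(1)
#' errors at the fitted `(rho, sigma2)`.
#'
#' @param object An `"its_fit"`.
#' @param nsim Number of simulated series.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of length `n`.
#' @export
simulate.its_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  sd <- sqrt(object$sigma2)
  rho <- if (is.null(object$rho)) 0 else object$rho
  out <- replicate(nsim, mu + ar1_noise(object$n, rho, sd))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
print.its_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-interruption segmented regression (%s), n = %d\n",
              x$method, x$n))
  print(round(x$coefficients, digits))
  if (!is.null(x$rho)) cat(sprintf("AR(1) rho = %.3f\n", x$rho))
  cat(sprintf("logLik = %.3f, AIC = %.2f, DW = %.3f\n", x$loglik, x$aic, x$dw))
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients,
                    se = object$se,
                    p = object$pvalues,
                    sig = sig_marker(object$pvalues))
  structure(list(table = tab, fit = object), class = "summary.its_fit")
}

#' @export
print.summary.its_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat(sprintf("Two-interruption segmented regression, method = %s\n", f$method))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  print(tab)
  cat("signif: # p<0.1, * p<0.05, † p<0.01, § p<0.001\n")
  if (!is.null(f$rho)) {
    cat(sprintf("AR(1) rho = %.3f (se %.3f)\n", f$rho, f$rho_se))
  }
  cat(sprintf("sigma2 = %.4g, logLik = %.3f, AIC = %.2f, DW = %.3f",
              f$sigma2, f$loglik, f$aic, f$dw))
  if (!is.null(f$dw_p) && !is.na(f$dw_p)) cat(sprintf(" (MC p = %.3f)", f$dw_p))
  cat("\n")
  ss <- segment_slopes(f)
  cat(sprintf("segment slopes: baseline %.4g, post-OPIP %.4g, post-SPS %.4g\n",
              ss$slopes[1], ss$slopes[2], ss$slopes[3]))
  invisible(x)
}

#' Plot observed, fitted and counterfactual series
#'
#' Observed points, the with-policy fitted trend, the counterfactual trend
#' after the second interruption, and its confidence band.
#'
#' @param x An `"its_fit"`.
#' @param level Band coverage for the counterfactual mean.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.its_fit <- function(x, level = 0.95, ...) {
  t <- seq_len(x$n)
  band <- forecast_band(x, level = level)
  ylim <- range(x$y, band$lower, band$upper, na.rm = TRUE)
  graphics::plot(t, x$y, pch = 1, xlab = "month", ylab = "outcome",
                 ylim = ylim, ...)
  graphics::polygon(c(t, rev(t)), c(band$lower, rev(band$upper)),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::lines(t, x$fitted, lty = 1)
  graphics::lines(t, band$counterfactual, lty = 2)
  sch <- attr(x$design, "schedule")
  if (!is.null(sch)) graphics::abline(v = c(sch$opip_month, sch$sps_month), lty = 3)
  invisible(x)
}
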