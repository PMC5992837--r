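# Counterfactual forecasts, percent policy effects, and complication growth.

#' Counterfactual and with-policy predicted series
#'
#' The with-policy prediction uses the full design row; the counterfactual
#' zeroes the second-interruption columns (`sps`, `time_after_sps`),
#' extending the pre-policy trend "if the policy were not in existence". The
#' two coincide on every pre-policy month by construction.
#'
#' @param fit An `"its_fit"` on the two-interruption design.
#' @param design Optional design data frame; defaults to the fitted one.
#' @return Data frame with columns `time`, `observed` (when available),
#'   `fitted`, `counterfactual`.
#' @export
counterfactual <- function(fit, design = NULL) {
  d <- if (is.null(design)) fit$design else design
  out <- data.frame(time = d$time,
                    fitted = predict(fit, d),
                    counterfactual = predict(fit, d, counterfactual = TRUE))
  if (is.null(design) || nrow(d) == length(fit$y)) out$observed <- fit$y
  out[, intersect(c("time", "observed", "fitted", "counterfactual"), names(out))]
}

#' Confidence band for the counterfactual mean
#'
#' Pointwise `level` band for the counterfactual mean trend,
#' `x_cf' beta_hat +/- z * se(x_cf' beta_hat)`, with the standard error from
#' the fit's coefficient covariance (the AR(1) covariance for AR(1) fits).
#' The band covers the mean of the counterfactual trend, not a new
#' observation.
#'
#' @param fit An `"its_fit"`.
#' @param design Optional design; defaults to the fitted one.
#' @param level Coverage in (0, 1).
#' @return Data frame with `time`, `counterfactual`, `se`, `lower`, `upper`.
#' @export
forecast_band <- function(fit, design = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie strictly inside (0, 1)")
  d <- if (is.null(design)) fit$design else design
  Xcf <- design_matrix(d)
  Xcf[, c("sps", "time_after_sps")] <- 0
  V <- fit$vcov
  se <- sqrt(pmax(rowSums((Xcf %*% V) * Xcf), 0))
  z <- stats::qnorm((1 + level) / 2)
  cf <- drop(Xcf %*% fit$coefficients)
  data.frame(time = d$time, counterfactual = cf, se = se,
             lower = cf - z * se, upper = cf + z * se)
}

#' Percent policy effect at stated horizons
#'
#' Compares the with-policy model prediction against the counterfactual over
#' the post-policy months (month 1 = the policy start month):
#' \itemize{
#'   \item `cumulative_percent`: `100 (sum yhat - sum yhat_cf) / sum yhat_cf`
#'     over post months 1..12 (the "in a year" figure);
#'   \item `endpoint_percent`: the same ratio at the single horizon month;
#'   \item `monthly_average_percent`: the arithmetic mean over post months
#'     1..horizon of the per-month percent differences.
#' }
#' Absolute differences are reported alongside, with a `level` confidence
#' interval on the cumulative absolute difference (and its percent scale,
#' holding the counterfactual denominator fixed) from the coefficient
#' covariance.
#'
#' @param fit An `"its_fit"` on the two-interruption design.
#' @param design Optional design; defaults to the fitted one.
#' @param horizons Integer months after the policy at which endpoint effects
#'   are evaluated.
#' @param level Interval coverage.
#' @return An object of class `"its_effect"`: a data frame with one row per
#'   horizon and columns `horizon_months`, `cumulative_percent`,
#'   `endpoint_percent`, `monthly_average_percent`, `cumulative_abs`,
#'   `endpoint_abs`, `lower_percent`, `upper_percent`.
#' @export
policy_effect <- function(fit, design = NULL, horizons = c(12L, 15L),
                          level = 0.95) {
  d <- if (is.null(design)) fit$design else design
  post <- which(d$sps == 1)
  if (length(post) == 0L) stop("design has no post-policy months")
  if (max(horizons) > length(post)) {
    stop("post-policy window (", length(post), " months) does not cover horizon ",
         max(horizons))
  }
  X <- design_matrix(d)
  Xcf <- X
  Xcf[, c("sps", "time_after_sps")] <- 0
  b <- fit$coefficients
  yhat <- drop(X %*% b)
  ycf <- drop(Xcf %*% b)
  z <- stats::qnorm((1 + level) / 2)
  V <- fit$vcov

  cum_idx <- post[seq_len(min(12L, length(post)))]
  if (any(ycf[post[seq_len(max(horizons))]] <= 0) || any(ycf[cum_idx] <= 0)) {
    stop("counterfactual prediction is not positive at a required month; ",
         "percent effect undefined")
  }
  a_cum <- colSums(X[cum_idx, , drop = FALSE] - Xcf[cum_idx, , drop = FALSE])
  se_cum <- sqrt(drop(a_cum %*% V %*% a_cum))
  cum_abs <- sum(yhat[cum_idx]) - sum(ycf[cum_idx])
  cum_pct <- 100 * cum_abs / sum(ycf[cum_idx])

  rows <- lapply(as.integer(horizons), function(h) {
    hm <- post[h]
    mon_idx <- post[seq_len(h)]
    data.frame(
      horizon_months = h,
      cumulative_percent = cum_pct,
      endpoint_percent = 100 * (yhat[hm] - ycf[hm]) / ycf[hm],
      monthly_average_percent = mean(100 * (yhat[mon_idx] - ycf[mon_idx]) / ycf[mon_idx]),
      cumulative_abs = cum_abs,
      endpoint_abs = yhat[hm] - ycf[hm],
      lower_percent = 100 * (cum_abs - z * se_cum) / sum(ycf[cum_idx]),
      upper_percent = 100 * (cum_abs + z * se_cum) / sum(ycf[cum_idx]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("its_effect", "data.frame")
  out
}

# Round half away from zero to `digits` decimals.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Annual growth of complication-procedure rates
#'
#' Per-category period-over-period change in monthly episodes per 1000
#' patients: the absolute change rounded to 2 decimals and the percent
#' growth `100 (later - earlier) / earlier` rounded half away from zero to
#' an integer.
#'
#' @param rates Data frame with columns `category`, `period`, `rate`
#'   (episodes per 1000 patients per month); periods are taken in their
#'   order of appearance. A matrix (categories x periods) is also accepted.
#' @return Data frame of class `"its_growth"` with columns `category`,
#'   `from`, `to`, `rate_from`, `rate_to`, `change`, `growth_percent`.
#' @examples
#' r <- data.frame(category = "nephropathy", period = c("p1", "p2"),
#'                 rate = c(0.47, 0.67))
#' annual_growth(r)  # change +0.2, growth 43%
#' @export
annual_growth <- function(rates) {
  if (is.matrix(rates)) {
    rates <- data.frame(category = rep(rownames(rates), ncol(rates)),
                        period = rep(colnames(rates), each = nrow(rates)),
                        rate = as.vector(rates), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("category", "period", "rate") %in% names(rates)))
  out <- do.call(rbind, lapply(unique(rates$category), function(cat) {
    r <- rates[rates$category == cat, , drop = FALSE]
    if (nrow(r) < 2L) stop("category '", cat, "' needs at least 2 periods")
    i <- seq_len(nrow(r) - 1L)
    if (any(r$rate[i] == 0)) {
      stop("growth undefined for category '", cat, "': zero earlier rate")
    }
    data.frame(category = cat,
               from = r$period[i], to = r$period[i + 1L],
               rate_from = r$rate[i], rate_to = r$rate[i + 1L],
               change = round_half_away(r$rate[i + 1L] - r$rate[i], 2),
               growth_percent = round_half_away(
                 100 * (r$rate[i + 1L] - r$rate[i]) / r$rate[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("its_growth", "data.frame")
  out
}

#' Summarise observed procedure events into per-1000 period rates
#'
#' Averages monthly event counts over consecutive 12-month periods and scales
#' to episodes per 1000 cohort patients, the input format of
#' [annual_growth()].
#'
#' @param procedures Data frame from [sim_procedures()] (columns `year`,
#'   `month`, `category`, `events`), in window order within category.
#' @param cohort_size Cohort denominator.
#' @return Data frame with `category`, `period`, `rate`.
#' @export
procedure_rates <- function(procedures, cohort_size) {
  out <- do.call(rbind, lapply(unique(procedures$category), function(cat) {
    ev <- procedures$events[procedures$category == cat]
    n_p <- length(ev) %/% 12L
    if (n_p < 1L) stop("need at least 12 months per category")
    per <- (seq_len(n_p * 12L) - 1L) %/% 12L + 1L
    rate <- tapply(ev[seq_len(n_p * 12L)], per, mean) / cohort_size * 1000
    data.frame(category = cat, period = paste0("period", seq_len(n_p)),
               rate = as.numeric(rate), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
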