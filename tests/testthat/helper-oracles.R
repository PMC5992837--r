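# Independent oracles and shared fixtures for the test suite.

# Exact Gaussian log-density of y - X beta under stationary AR(1) errors,
# computed through the dense Toeplitz covariance (independent of the
# Prais-Winsten route used by the implementation).
dense_ar1_loglik <- function(y, X, beta, rho, sigma2) {
  n <- length(y)
  R <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  Sigma <- sigma2 / (1 - rho^2) * R
  r <- y - drop(as.matrix(X) %*% beta)
  ch <- chol(Sigma)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * drop(crossprod(backsolve(ch, r, transpose = TRUE)))
}

published_coefs <- function() {
  utils::read.csv(system.file("extdata", "published_coefficients.csv",
                              package = "itsar"), stringsAsFactors = FALSE)
}

published_rates <- function() {
  utils::read.csv(system.file("extdata", "published_complication_rates.csv",
                              package = "itsar"), stringsAsFactors = FALSE)
}

coef_row <- function(outcome, group) {
  tab <- published_coefs()
  r <- tab[tab$outcome == outcome & tab$group == group, ]
  as.numeric(r[, paste0("b", 0:6)])
}

# Six-record cohort fixture crossing age, diagnosis and setting filters.
fixture_claims <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    age = c(19, 20, 65, 45, 70, 33),
    service_date = c("2010-03-01", "2010-06-15", "2011-01-10",
                     "2012-02-29", "2010-09-09", "2011-11-30"),
    setting = c("outpatient", "outpatient", "outpatient",
                "inpatient", "outpatient", "outpatient"),
    institution_type = c("clinic", "clinic", "general_hospital",
                         "teaching_hospital", "clinic", "clinic"),
    insurance = c("NHI", "NHI", "MedAid", "NHI", "NHI", "NHI"),
    diagnosis_code = c("E11", "E14", "E11", "E11", "E10", "E149"),
    drug_code = NA_character_, quantity = 0, cost = 10000, copayment = 3000,
    stringsAsFactors = FALSE)
}

# Small claims table with known per-month aggregates: 10 drug records over
# 2 months and both price groups, for the hand-computed aggregation oracle.
fixture_agg <- function() {
  reg <- data.frame(
    code = c("R1", "R2", "C1"),
    group = c("reduced", "reduced", "constant"),
    unit_price_pre = c(100, 200, 300), unit_price_post = c(70, 140, 300),
    who_ddd_units = c(2, NA, 1), standard_daily_dose_units = c(NA, 4, NA),
    market_entry_month = 1L, stringsAsFactors = FALSE)
  claims <- data.frame(
    patient_id = c("A", "A", "B", "B", "C", "A", "B", "C", "C", "A"),
    age = 50,
    service_date = c("2009-01-05", "2009-01-20", "2009-01-07", "2009-01-07",
                     "2009-01-28", "2009-02-02", "2009-02-14", "2009-02-14",
                     "2009-02-20", "2009-02-25"),
    setting = "outpatient", institution_type = "clinic", insurance = "NHI",
    diagnosis_code = "E11",
    drug_code = c("R1", "C1", "R1", "R2", "C1", "R2", "C1", "R1", "R2", "C1"),
    quantity = c(10, 3, 20, 8, 5, 12, 7, 30, 4, 9),
    cost = c(1000, 900, 2000, 1600, 1500, 1680, 2100, 2100, 800, 2700),
    copayment = 0, stringsAsFactors = FALSE)
  list(registry = reg, claims = claims,
       schedule = intervention_schedule(origin = "2009-01", n_months = 2,
                                        opip_start = "2009-01",
                                        sps_start = "2009-02"))
}
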