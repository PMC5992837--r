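# Synthetic claims and monthly-series generator with known ground truth.
#
# The generator emulates the statistical structure of national insurance
# antidiabetic claims: monthly outcome series following the two-interruption
# segmented model with stationary AR(1) noise, patient-level prescription
# claims whose monthly aggregates hit configured targets, and Poisson monthly
# complication-procedure events.

# Deterministic substream seeds: one user seed governs all randomness; each
# named stream gets seed' = (seed * 1009 + hash(stream)) mod (2^31 - 1).
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 99991L
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# Published segmented-regression coefficients for monthly overall antidiabetic
# cost (billion KRW), used as the default ground truth for aggregate series.
default_cost_beta <- function() {
  c(intercept = 29.982, time = 0.295, opip = -0.984, time_after_opip = -0.136,
    sps = -4.384, time_after_sps = 0.192, feb = -2.643)
}

#' Configure the synthetic-data generator
#'
#' Collects every knob of the synthetic claims study in one validated object:
#' the intervention schedule, the true coefficients of the monthly outcome
#' series, the AR(1) noise process, and the composition of the patient pool.
#' Defaults encode the study conditions of the Korean antidiabetics window:
#' 54 months from January 2009 with interruptions at months 22 (OPIP) and 40
#' (SPS), true coefficients equal to the published overall-cost row
#' (billion KRW), AR(1) coefficient 0.282, and an NHI/MedAid split of 92/8.
#'
#' @param schedule An [intervention_schedule()].
#' @param beta Named list of true 7-coefficient vectors
#'   (intercept, time, opip, time_after_opip, sps, time_after_sps, feb), one
#'   per outcome the aggregate generator can produce. Unnamed defaults cover
#'   `cost_reduced`, `cost_constant`, `patients_reduced`, `patients_constant`
#'   at a 2000-patient desk scale, plus `cost_total` at the published
#'   billion-KRW scale.
#' @param ar1_rho AR(1) coefficient of the noise process, in (-1, 1).
#' @param noise_sd Innovation standard deviation(s); a single value or a named
#'   vector per outcome. Zero gives deterministic series.
#' @param n_patients Size of the diabetic cohort pool for claims generation.
#' @param medaid_fraction Proportion of patients on Medical Aid (rest NHI).
#' @param age_mean,age_sd Normal age distribution of the adult pool, truncated
#'   at 20 years.
#' @param under20_fraction Fraction (of `n_patients`) of extra under-20
#'   contamination patients, emitted so that cohort filters are exercised.
#' @param nondiabetic_fraction Fraction of extra patients whose claims carry
#'   non-diabetic diagnosis codes.
#' @param diagnosis_mix Named proportions over `E11`, `E14`, `other` for
#'   per-claim diagnosis codes; `E11 + E14` must be positive.
#' @param complication_rates Named vector or per-period matrix of monthly
#'   complication-procedure episodes per 1000 patients (rows = categories).
#' @param cohort_size Cohort denominator for complication events; defaults to
#'   the four-million-patient scale of the study cohort (the complication
#'   module is an aggregate Poisson draw, so full scale costs nothing).
#' @param seed Integer master seed; all substreams are derived from it.
#' @return A validated list of class `"its_sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' y <- sim_series(cfg, "cost_total")
#' length(y$value)  # 54
#' @export
sim_config <- function(schedule = intervention_schedule(),
                       beta = NULL,
                       ar1_rho = 0.282,
                       noise_sd = 0.8,
                       n_patients = 2000L,
                       medaid_fraction = 0.08,
                       age_mean = 61, age_sd = 13,
                       under20_fraction = 0.02,
                       nondiabetic_fraction = 0.02,
                       diagnosis_mix = c(E11 = 0.85, E14 = 0.10, other = 0.05),
                       complication_rates = default_complication_rates(),
                       cohort_size = NULL,
                       seed = 1L) {
  if (!inherits(schedule, "its_schedule")) stop("schedule must be an 'its_schedule'")
  if (!is.numeric(ar1_rho) || length(ar1_rho) != 1L || abs(ar1_rho) >= 1) {
    stop("ar1_rho must lie strictly inside (-1, 1)")
  }
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (is.null(beta)) beta <- default_sim_beta(n_patients)
  beta <- lapply(beta, function(b) {
    b <- as.numeric(b)
    if (length(b) != 7L) stop("each beta vector must have 7 coefficients")
    names(b) <- c("intercept", its_terms())
    b
  })
  if (is.null(names(beta)) || any(names(beta) == "")) stop("beta must be a named list")
  dm <- diagnosis_mix[c("E11", "E14", "other")]
  dm[is.na(dm)] <- 0
  if (any(dm < 0) || sum(dm) <= 0) stop("diagnosis_mix proportions must be non-negative")
  dm <- dm / sum(dm)
  if (dm[["E11"]] + dm[["E14"]] <= 0) stop("diagnosis_mix must give positive mass to E11 or E14")
  if (medaid_fraction < 0 || medaid_fraction > 1) stop("medaid_fraction must be in [0, 1]")
  if (under20_fraction < 0 || under20_fraction > 1) stop("under20_fraction must be in [0, 1]")
  cr <- complication_rates
  if (is.null(dim(cr))) cr <- matrix(cr, ncol = 1, dimnames = list(names(cr), "period1"))
  if (any(cr < 0)) stop("complication rates must be non-negative")
  if (is.null(cohort_size)) cohort_size <- 4e6
  structure(list(schedule = schedule, beta = beta, ar1_rho = ar1_rho,
                 noise_sd = noise_sd, n_patients = as.integer(n_patients),
                 medaid_fraction = medaid_fraction, age_mean = age_mean,
                 age_sd = age_sd, under20_fraction = under20_fraction,
                 nondiabetic_fraction = nondiabetic_fraction,
                 diagnosis_mix = dm, complication_rates = cr,
                 cohort_size = cohort_size, seed = as.integer(seed)),
            class = "its_sim_config")
}

# Desk-scale default ground truth: cost in thousand KRW per patient-month
# scaled to the pool, patient counts growing linearly with a policy slope
# break, February dips. The SPS level/slope signs mirror the published
# pattern: reduced-price spending drops, constant-price spending accelerates.
default_sim_beta <- function(n_patients) {
  f <- n_patients / 2000
  list(
    cost_total = default_cost_beta(),
    cost_reduced = c(9000, 25, 120, -18, -1800, -9, -900) * f,
    cost_constant = c(3200, 85, -210, 15, 140, 80, -320) * f,
    patients_reduced = c(560, 2.4, -3, 0.25, 3.6, -3.7, -32) * f,
    patients_constant = c(140, 3.4, -20, 0.6, 4, 2.5, -13) * f
  )
}

#' Default complication-procedure rate table
#'
#' Monthly episodes per 1000 cohort patients for the five diabetes
#' complication categories over four annual periods, at the published
#' magnitudes.
#'
#' @return A 5 x 4 numeric matrix (categories x periods).
#' @export
default_complication_rates <- function() {
  m <- rbind(
    retinopathy    = c(0.27, 0.29, 0.30, 0.30),
    cataract       = c(1.98, 2.08, 2.19, 2.23),
    nephropathy    = c(0.47, 0.67, 0.74, 0.75),
    cardiovascular = c(2.49, 2.84, 2.90, 2.76),
    foot_lesions   = c(0.40, 0.53, 0.62, 0.68)
  )
  colnames(m) <- paste0("period", 1:4)
  m
}

# Stationary AR(1) noise of length n: eps_t = rho eps_{t-1} + u_t,
# eps_1 ~ N(0, sd^2 / (1 - rho^2)).
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  u <- stats::rnorm(n, 0, sd)
  eps <- numeric(n)
  eps[1] <- stats::rnorm(1, 0, sd / sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) eps[t] <- rho * eps[t - 1] + u[t]
  eps
}

outcome_noise_sd <- function(config, outcome) {
  s <- config$noise_sd
  if (length(s) > 1L && !is.null(names(s)) && outcome %in% names(s)) s <- s[[outcome]]
  s[[1]]
}

#' Simulate one monthly outcome series from the segmented model
#'
#' Draws `y_t = x_t' beta + eps_t` over the configured window, where `x_t` is
#' the two-interruption design row and `eps_t` is stationary AR(1) noise.
#' Deterministic given the config seed: the stream is keyed by the outcome
#' name, so different outcomes get independent noise and repeated calls
#' reproduce each other.
#'
#' @param config A [sim_config()].
#' @param outcome Name of a coefficient vector in `config$beta`.
#' @return A data frame (class `"its_series"`) with columns `year`, `month`,
#'   `value`, and attributes `outcome` and `beta` (the ground truth).
#' @export
sim_series <- function(config, outcome) {
  stopifnot(inherits(config, "its_sim_config"))
  if (!outcome %in% names(config$beta)) {
    stop("no true coefficients configured for outcome '", outcome, "'")
  }
  beta <- config$beta[[outcome]]
  d <- its_design(config$schedule)
  X <- design_matrix(d)
  sd <- outcome_noise_sd(config, outcome)
  set.seed(split_seed(config$seed, paste0("series:", outcome)))
  y <- drop(X %*% beta) + ar1_noise(nrow(X), config$ar1_rho, sd)
  out <- data.frame(year = d$year, month = d$month, value = y)
  attr(out, "outcome") <- outcome
  attr(out, "beta") <- beta
  class(out) <- c("its_series", "data.frame")
  out
}

#' Build a synthetic drug registry
#'
#' A registry row per active-ingredient code with its pricing group, pre/post
#' unit prices, and dosing information. `reduced` codes get a price cut at the
#' SPS month (post price < pre price); `constant` codes keep their price. One
#' in four entries lacks a WHO DDD and carries a standard adult daily dose
#' instead, exercising the fallback DDD rule.
#'
#' @param n_reduced,n_constant Number of ingredient codes per group. The
#'   defaults (32 reduced of 97 total) mirror the published classification.
#' @param seed Integer seed for price and dose draws.
#' @return A data frame with columns `code`, `group`, `unit_price_pre`,
#'   `unit_price_post`, `who_ddd_units`, `standard_daily_dose_units`,
#'   `market_entry_month`.
#' @export
sim_registry <- function(n_reduced = 32L, n_constant = 65L, seed = 1L) {
  set.seed(split_seed(seed, "registry"))
  n <- n_reduced + n_constant
  code <- sprintf("A10-%03d", seq_len(n))
  group <- c(rep("reduced", n_reduced), rep("constant", n_constant))
  pre <- round(stats::runif(n, 100, 1500), 0)
  post <- ifelse(group == "reduced", round(pre * stats::runif(n, 0.53, 0.86)), pre)
  ddd <- round(stats::runif(n, 0.5, 4), 1)
  fallback <- seq_len(n) %% 4L == 0L
  data.frame(
    code = code, group = group,
    unit_price_pre = pre, unit_price_post = post,
    who_ddd_units = ifelse(fallback, NA_real_, ddd),
    standard_daily_dose_units = ifelse(fallback, ddd, NA_real_),
    market_entry_month = 1L,
    stringsAsFactors = FALSE
  )
}

included_institutions <- function() {
  c("clinic", "nursing_home", "teaching_hospital", "general_hospital", "other_hospital")
}

# Deterministic target series for the claims generator: realized monthly
# patient counts (integer, clamped to the pool) and cost totals per group.
claims_targets <- function(config) {
  pr <- sim_series(config, "patients_reduced")$value
  pc <- sim_series(config, "patients_constant")$value
  cr <- sim_series(config, "cost_reduced")$value
  cc <- sim_series(config, "cost_constant")$value
  clamp_n <- function(v) {
    v <- as.integer(round(v))
    if (any(v > config$n_patients)) {
      stop("target patient count (", max(v), ") exceeds the configured ",
           "pool size n_patients (", config$n_patients, ")")
    }
    pmax(1L, v)
  }
  list(patients = list(reduced = clamp_n(pr), constant = clamp_n(pc)),
       cost = list(reduced = pmax(cr, 1), constant = pmax(cc, 1)))
}

#' Generate patient-level synthetic claims
#'
#' Emits one row per healthcare event: an enrollment visit per cohort patient
#' (diagnosis-only, no drug) inside the index window, drug prescription claims
#' whose monthly aggregates match the configured targets, and contamination
#' records (under-20 patients, non-diabetic codes, a few inpatient events)
#' that cohort filters must remove. Per month and drug group, the number of
#' distinct prescribed patients equals the target count exactly; record costs
#' are whole KRW, so monthly cost totals match the target up to one KRW per
#' record. Costs honour `cost = quantity x unit price` at the era-appropriate
#' price, with quantity and DDD derived from the registry.
#'
#' @param config A [sim_config()].
#' @param registry A drug registry as returned by [sim_registry()].
#' @return A data frame of claims with columns `patient_id`, `age`,
#'   `service_date`, `setting`, `institution_type`, `insurance`,
#'   `diagnosis_code`, `drug_code`, `quantity`, `cost`, `copayment`. The
#'   realized monthly targets are attached as attribute `"targets"`.
#' @export
sim_claims <- function(config, registry = sim_registry(seed = config$seed)) {
  stopifnot(inherits(config, "its_sim_config"))
  if (nrow(registry) == 0L) stop("registry must be non-empty")
  sch <- config$schedule
  n_m <- sch$n_months
  months <- ym_seq(sch$origin, n_m)
  tg <- claims_targets(config)  # errors if targets exceed the patient pool

  # patient pool attributes (fixed over the window)
  set.seed(split_seed(config$seed, "patients"))
  np <- config$n_patients
  ids <- sprintf("P%05d", seq_len(np))
  age <- pmax(20, round(stats::rnorm(np, config$age_mean, config$age_sd)))
  insurance <- ifelse(stats::runif(np) < config$medaid_fraction, "MedAid", "NHI")
  inst <- sample(included_institutions(), np, replace = TRUE,
                 prob = c(0.45, 0.1, 0.15, 0.2, 0.1))
  dm <- config$diagnosis_mix
  dx_first <- sample(c("E11", "E14"), np, replace = TRUE,
                     prob = dm[c("E11", "E14")] / sum(dm[c("E11", "E14")]))

  # index window = calendar years 2..4 of the window when long enough,
  # mirroring a reference period strictly inside the data window
  idx_lo <- min(13L, n_m)
  idx_hi <- max(idx_lo, min(48L, n_m))
  enrol_month <- sample(idx_lo:idx_hi, np, replace = TRUE)

  rows <- vector("list", 2L * n_m + 3L)
  k <- 0L
  add <- function(df) { k <<- k + 1L; rows[[k]] <<- df }

  add(data.frame(
    patient_id = ids, age = age,
    service_date = sprintf("%s-15", months[enrol_month]),
    setting = "outpatient", institution_type = inst, insurance = insurance,
    diagnosis_code = dx_first, drug_code = NA_character_,
    quantity = 0, cost = 12000, copayment = 3600,
    stringsAsFactors = FALSE))

  draw_dx <- function(n) {
    sample(c("E11", "E14", "other"), n, replace = TRUE, prob = dm)
  }
  for (g in c("reduced", "constant")) {
    reg_g <- registry[registry$group == g, , drop = FALSE]
    if (nrow(reg_g) == 0L) stop("registry has no '", g, "' entries")
    set.seed(split_seed(config$seed, paste0("claims:", g)))
    for (t in seq_len(n_m)) {
      n_t <- tg$patients[[g]][t]
      cost_t <- tg$cost[[g]][t]
      who <- sample.int(np, n_t)
      # ~20% of treated patients file two prescriptions that month
      extra <- who[stats::runif(n_t) < 0.2]
      pid <- c(who, extra)
      n_rec <- length(pid)
      w <- stats::runif(n_rec, 0.5, 1.5)
      share <- cost_t * w / sum(w)
      ri <- sample.int(nrow(reg_g), n_rec, replace = TRUE)
      post <- t >= sch$sps_month
      price <- if (post) reg_g$unit_price_post[ri] else reg_g$unit_price_pre[ri]
      qty <- share / price
      dxg <- draw_dx(n_rec)
      day <- sample(1:28, n_rec, replace = TRUE)
      cost <- round(share)
      add(data.frame(
        patient_id = ids[pid], age = age[pid],
        service_date = sprintf("%s-%02d", months[t], day),
        setting = "outpatient", institution_type = inst[pid],
        insurance = insurance[pid], diagnosis_code = dxg,
        drug_code = reg_g$code[ri], quantity = qty,
        cost = cost, copayment = round(0.3 * cost),
        stringsAsFactors = FALSE))
    }
  }

  # contamination: under-20 patients and non-diabetic diagnoses, plus a few
  # inpatient events; all must be dropped by the cohort filters
  set.seed(split_seed(config$seed, "contamination"))
  n_u20 <- round(config$under20_fraction * np)
  if (n_u20 > 0) {
    m <- sample(idx_lo:idx_hi, n_u20, replace = TRUE)
    ri <- sample.int(nrow(registry), n_u20, replace = TRUE)
    add(data.frame(
      patient_id = sprintf("U%05d", seq_len(n_u20)),
      age = sample(5:19, n_u20, replace = TRUE),
      service_date = sprintf("%s-10", months[m]),
      setting = "outpatient",
      institution_type = sample(included_institutions(), n_u20, replace = TRUE),
      insurance = "NHI", diagnosis_code = "E10",
      drug_code = registry$code[ri], quantity = 30,
      cost = round(30 * registry$unit_price_pre[ri]),
      copayment = round(9 * registry$unit_price_pre[ri]),
      stringsAsFactors = FALSE))
  }
  n_nd <- round(config$nondiabetic_fraction * np)
  if (n_nd > 0) {
    m <- sample(idx_lo:idx_hi, n_nd, replace = TRUE)
    inpat <- seq_len(n_nd) %% 3L == 0L
    add(data.frame(
      patient_id = sprintf("N%05d", seq_len(n_nd)),
      age = pmax(20, round(stats::rnorm(n_nd, config$age_mean, config$age_sd))),
      service_date = sprintf("%s-20", months[m]),
      setting = ifelse(inpat, "inpatient", "outpatient"),
      institution_type = sample(included_institutions(), n_nd, replace = TRUE),
      insurance = "NHI",
      diagnosis_code = ifelse(inpat, "E11", "I10"),
      drug_code = NA_character_, quantity = 0,
      cost = 15000, copayment = 4500,
      stringsAsFactors = FALSE))
  }

  claims <- do.call(rbind, rows[seq_len(k)])
  rownames(claims) <- NULL
  claims <- claims[order(claims$service_date, claims$patient_id), ]
  rownames(claims) <- NULL
  attr(claims, "targets") <- tg
  claims
}

#' Simulate monthly complication-procedure events
#'
#' Monthly counts per complication category drawn as Poisson with mean
#' `rate / 1000 x cohort_size`, where the rate for a month is the configured
#' per-1000 rate of the annual period the month falls in (periods are
#' consecutive 12-month bins from the window origin; the last period absorbs
#' the remainder).
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `year`, `month`, `category`, `events`.
#' @export
sim_procedures <- function(config) {
  stopifnot(inherits(config, "its_sim_config"))
  rates <- config$complication_rates
  if (nrow(rates) == 0L) stop("complication_rates must cover at least one category")
  sch <- config$schedule
  n_m <- sch$n_months
  period <- pmin(ncol(rates), (seq_len(n_m) - 1L) %/% 12L + 1L)
  p <- ym_parse(ym_seq(sch$origin, n_m))
  set.seed(split_seed(config$seed, "procedures"))
  out <- lapply(rownames(rates), function(cat) {
    lam <- rates[cat, period] / 1000 * config$cohort_size
    data.frame(year = p$year, month = p$month, category = cat,
               events = stats::rpois(n_m, lam), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
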