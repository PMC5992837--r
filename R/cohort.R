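# Cohort selection and monthly aggregation of claims into outcome series.

claims_columns <- function() {
  c("patient_id", "age", "service_date", "setting", "institution_type",
    "insurance", "diagnosis_code", "drug_code", "quantity", "cost", "copayment")
}

# Parse service dates to year-month strings; malformed dates become NA.
claim_ym <- function(service_date) {
  d <- as.Date(service_date, format = "%Y-%m-%d")
  ifelse(is.na(d), NA_character_, format(d, "%Y-%m"))
}

#' Select the adult diabetic outpatient cohort
#'
#' A patient enters the cohort if, inside the index window, they have at least
#' one outpatient claim at an included institution whose diagnosis code falls
#' in the given ICD-10 categories (3-character prefix match) while aged at
#' least `min_age`. Records with malformed service dates are rejected with a
#' message stating the count.
#'
#' @param claims A claims data frame (see [sim_claims()] for columns).
#' @param index_window Character vector of two year-months `c(from, to)`
#'   bounding the reference period, inclusive.
#' @param min_age Minimum age in years at the qualifying claim.
#' @param diagnosis_codes ICD-10 category prefixes that qualify.
#' @return Character vector of cohort patient ids (sorted, distinct).
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 1)
#' cl <- sim_claims(cfg)
#' length(select_cohort(cl))
#' @export
select_cohort <- function(claims, index_window = c("2010-01", "2012-12"),
                          min_age = 20, diagnosis_codes = c("E11", "E14")) {
  if (nrow(claims) == 0L) return(character(0))
  ym <- claim_ym(claims$service_date)
  n_bad <- sum(is.na(ym))
  if (n_bad > 0) message("select_cohort: rejected ", n_bad, " record(s) with malformed dates")
  ok <- !is.na(ym)
  v <- ym_num(ym[ok])
  in_window <- v >= ym_num(index_window[1]) & v <= ym_num(index_window[2])
  cl <- claims[ok, , drop = FALSE][in_window, , drop = FALSE]
  cat3 <- substr(cl$diagnosis_code, 1L, 3L)
  qual <- cl$setting == "outpatient" &
    cl$institution_type %in% included_institutions() &
    cat3 %in% diagnosis_codes &
    cl$age >= min_age
  sort(unique(cl$patient_id[qual]))
}

#' Convert a dispensed quantity to defined daily doses
#'
#' Quantity divided by the WHO DDD in units when available; items without a
#' WHO DDD (e.g. fixed-dose combinations) fall back to the standard adult
#' daily dosage from the official label.
#'
#' @param entry One drug registry row (list or single-row data frame) with
#'   `who_ddd_units` and/or `standard_daily_dose_units`.
#' @param quantity Dispensed quantity in units, non-negative.
#' @return Numeric DDDs.
#' @examples
#' compute_ddd(list(who_ddd_units = NA, standard_daily_dose_units = 2), 60)  # 30
#' @export
compute_ddd <- function(entry, quantity) {
  if (any(quantity < 0)) stop("quantity must be non-negative")
  ddd <- entry$who_ddd_units
  sdd <- entry$standard_daily_dose_units
  denom <- if (!is.null(ddd) && length(ddd) && !is.na(ddd)) ddd
           else if (!is.null(sdd) && length(sdd) && !is.na(sdd)) sdd
           else stop("drug '", entry$code, "' has neither a WHO DDD nor a standard daily dose")
  quantity / denom
}

# Vectorized DDD over claims rows, via registry lookup. Errors if a drug code
# is missing from the registry or has no dose information.
ddd_for_claims <- function(claims, registry) {
  i <- match(claims$drug_code, registry$code)
  if (anyNA(i)) {
    stop("drug code(s) absent from registry: ",
         paste(unique(claims$drug_code[is.na(i)]), collapse = ", "))
  }
  denom <- ifelse(is.na(registry$who_ddd_units[i]),
                  registry$standard_daily_dose_units[i],
                  registry$who_ddd_units[i])
  if (anyNA(denom)) {
    stop("no dose information for drug code(s): ",
         paste(unique(claims$drug_code[is.na(denom)]), collapse = ", "))
  }
  claims$quantity / denom
}

#' Aggregate claims into monthly outcome series
#'
#' For each calendar month of the window and each drug-price group, sums the
#' antidiabetic drug costs and DDDs of cohort patients and counts distinct
#' treated patients, then derives per-patient outcomes. `overall` aggregates
#' the union of both groups: totals add across groups and the patient count
#' is the distinct count over all antidiabetic claims, so a patient on drugs
#' from both groups counts once overall but in each group's own count.
#' Months with no treated patients get missing per-patient values.
#'
#' @param claims Claims data frame.
#' @param cohort Character vector of cohort patient ids ([select_cohort()]).
#' @param registry Drug registry covering every drug code present.
#' @param schedule An [intervention_schedule()] fixing the window.
#' @return A data frame of class `"its_series_set"` with columns `year`,
#'   `month`, `group` (`overall`/`reduced`/`constant`), `outcome`
#'   (`cost_total`, `ddd_total`, `n_patients`, `cost_per_patient`,
#'   `ddd_per_patient`) and `value`.
#' @export
aggregate_monthly <- function(claims, cohort, registry,
                              schedule = intervention_schedule()) {
  months <- ym_seq(schedule$origin, schedule$n_months)
  drug <- claims[!is.na(claims$drug_code) & claims$patient_id %in% cohort, , drop = FALSE]
  ym <- claim_ym(drug$service_date)
  keep <- !is.na(ym) & ym %in% months
  drug <- drug[keep, , drop = FALSE]
  ym <- ym[keep]
  gi <- match(drug$drug_code, registry$code)
  if (anyNA(gi)) {
    stop("drug code(s) absent from registry: ",
         paste(unique(drug$drug_code[is.na(gi)]), collapse = ", "))
  }
  grp <- registry$group[gi]
  ddd <- ddd_for_claims(drug, registry)

  mf <- factor(ym, levels = months)
  agg_one <- function(sel, gname) {
    cost <- tapply(drug$cost[sel], mf[sel], sum)
    dddv <- tapply(ddd[sel], mf[sel], sum)
    npat <- tapply(drug$patient_id[sel], mf[sel], function(p) length(unique(p)))
    cost[is.na(cost)] <- 0; dddv[is.na(dddv)] <- 0; npat[is.na(npat)] <- 0
    pp_cost <- ifelse(npat > 0, cost / npat, NA_real_)
    pp_ddd <- ifelse(npat > 0, dddv / npat, NA_real_)
    p <- ym_parse(months)
    data.frame(
      year = rep(p$year, 5L), month = rep(p$month, 5L),
      group = gname,
      outcome = rep(c("cost_total", "ddd_total", "n_patients",
                      "cost_per_patient", "ddd_per_patient"),
                    each = length(months)),
      value = c(as.numeric(cost), as.numeric(dddv), as.numeric(npat),
                pp_cost, pp_ddd),
      stringsAsFactors = FALSE)
  }
  out <- rbind(agg_one(rep(TRUE, nrow(drug)), "overall"),
               agg_one(grp == "reduced", "reduced"),
               agg_one(grp == "constant", "constant"))
  rownames(out) <- NULL
  attr(out, "schedule") <- schedule
  class(out) <- c("its_series_set", "data.frame")
  out
}

#' Extract one monthly series from a series set
#'
#' @param set An `"its_series_set"` from [aggregate_monthly()].
#' @param outcome,group Outcome and group identifiers.
#' @return Numeric vector of monthly values in window order.
#' @export
series_values <- function(set, outcome, group = "overall") {
  s <- set[set$outcome == outcome & set$group == group, , drop = FALSE]
  if (nrow(s) == 0L) stop("no series for outcome '", outcome, "', group '", group, "'")
  s$value[order(s$year, s$month)]
}

#' Period-wise descriptive summary of monthly series
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' monthly values within each period. Single-month periods report a missing
#' SD.
#'
#' @param set An `"its_series_set"`.
#' @param periods Named list of integer vectors of month indices (1-based
#'   within the window).
#' @return Data frame with columns `outcome`, `group`, `period`, `mean`, `sd`.
#' @export
descriptive_summary <- function(set, periods) {
  sch <- attr(set, "schedule")
  n_m <- if (!is.null(sch)) sch$n_months else max(table(paste(set$outcome, set$group)))
  idx <- unlist(periods)
  if (any(idx < 1L | idx > n_m)) stop("period month indices outside the window")
  if (anyDuplicated(idx)) stop("periods must not overlap")
  combos <- unique(set[, c("outcome", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    v <- series_values(set, combos$outcome[i], combos$group[i])
    do.call(rbind, lapply(names(periods), function(pn) {
      x <- v[periods[[pn]]]
      data.frame(outcome = combos$outcome[i], group = combos$group[i],
                 period = pn, mean = mean(x),
                 sd = if (length(x) < 2L) NA_real_ else stats::sd(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# ---- delimited-file interfaces -------------------------------------------

#' Read and write the package's delimited files
#'
#' All tabular files are comma-separated UTF-8 with a header row; dates are
#' ISO-8601. `write_series()` stores one monthly series as
#' `(year, month, value)`.
#'
#' @param claims,registry,set Objects to write.
#' @param path File path.
#' @param outcome,group Series selector for `write_series()`.
#' @return The read data frame, or `path` invisibly for writers.
#' @name claims_io
NULL

#' @rdname claims_io
#' @export
write_claims <- function(claims, path) {
  utils::write.csv(claims[, claims_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname claims_io
#' @export
read_claims <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1L))
  cc <- c(patient_id = "character", service_date = "character",
          diagnosis_code = "character", drug_code = "character")
  cl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = cc[names(cc) %in% hdr])
  miss <- setdiff(claims_columns(), names(cl))
  if (length(miss)) stop("claims file missing column(s): ", paste(miss, collapse = ", "))
  cl$drug_code[cl$drug_code == ""] <- NA_character_
  cl
}

#' @rdname claims_io
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname claims_io
#' @export
read_registry <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(code = "character", group = "character"))
  need <- c("code", "group", "unit_price_pre", "unit_price_post",
            "who_ddd_units", "standard_daily_dose_units")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("registry file missing column(s): ", paste(miss, collapse = ", "))
  r
}

#' @rdname claims_io
#' @export
write_series <- function(set, outcome, group, path) {
  s <- set[set$outcome == outcome & set$group == group,
           c("year", "month", "value")]
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname claims_io
#' @export
read_series <- function(path) {
  s <- utils::read.csv(path)
  miss <- setdiff(c("year", "month", "value"), names(s))
  if (length(miss)) stop("series file missing column(s): ", paste(miss, collapse = ", "))
  s
}
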