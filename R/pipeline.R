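# Configuration-driven end-to-end runner: simulate -> aggregate -> fit ->
# effects -> reports. All stage outputs are comma-separated UTF-8 text; the
# run manifest is JSON.

#' Validate claims and registry files
#'
#' Schema check of the delimited inputs: required columns, date parsing,
#' enum values, and record-level invariants (non-negative quantities and
#' costs, copayment not exceeding cost).
#'
#' @param claims_path,registry_path File paths; `NULL` entries are skipped.
#' @return A list with per-file `errors` (character vectors) and `rows`
#'   counts; `ok` is `TRUE` when no errors were found.
#' @export
validate_claims <- function(claims_path = NULL, registry_path = NULL) {
  errs <- list()
  rows <- list()
  if (!is.null(claims_path)) {
    if (!file.exists(claims_path)) stop("unreadable claims file: ", claims_path)
    e <- character(0)
    cl <- tryCatch(read_claims(claims_path), error = function(err) err)
    if (inherits(cl, "error")) {
      e <- conditionMessage(cl)
      rows$claims <- NA_integer_
    } else {
      rows$claims <- nrow(cl)
      if (anyNA(as.Date(cl$service_date, format = "%Y-%m-%d"))) {
        e <- c(e, "claims: unparseable service_date value(s)")
      }
      bad_set <- !cl$setting %in% c("outpatient", "inpatient")
      if (any(bad_set)) e <- c(e, sprintf("claims: %d invalid setting value(s)", sum(bad_set)))
      if (any(cl$quantity < 0, na.rm = TRUE)) e <- c(e, "claims: negative quantity")
      if (any(cl$cost < 0, na.rm = TRUE)) e <- c(e, "claims: negative cost")
      over <- cl$copayment > cl$cost
      if (any(over, na.rm = TRUE)) {
        e <- c(e, sprintf("claims: copayment exceeds cost in %d record(s)", sum(over, na.rm = TRUE)))
      }
    }
    errs$claims <- e
  }
  if (!is.null(registry_path)) {
    if (!file.exists(registry_path)) stop("unreadable registry file: ", registry_path)
    e <- character(0)
    rg <- tryCatch(read_registry(registry_path), error = function(err) err)
    if (inherits(rg, "error")) {
      e <- conditionMessage(rg)
      rows$registry <- NA_integer_
    } else {
      rows$registry <- nrow(rg)
      bad_grp <- !rg$group %in% c("reduced", "constant")
      if (any(bad_grp)) e <- c(e, sprintf("registry: %d invalid group value(s)", sum(bad_grp)))
      if (any(rg$unit_price_pre <= 0 | rg$unit_price_post <= 0, na.rm = TRUE)) {
        e <- c(e, "registry: non-positive unit price")
      }
      red <- rg$group == "reduced"
      if (any(rg$unit_price_post[red] >= rg$unit_price_pre[red], na.rm = TRUE)) {
        e <- c(e, "registry: reduced-price entry without a price cut")
      }
      no_dose <- is.na(rg$who_ddd_units) & is.na(rg$standard_daily_dose_units)
      if (any(no_dose)) {
        e <- c(e, sprintf("registry: no dose information for %s",
                          paste(rg$code[no_dose], collapse = ", ")))
      }
    }
    errs$registry <- e
  }
  list(ok = all(lengths(errs) == 0L), errors = errs, rows = rows)
}

pipeline_outcomes <- function() {
  expand.grid(outcome = c("cost_total", "ddd_total", "n_patients",
                          "cost_per_patient", "ddd_per_patient"),
              group = c("overall", "reduced", "constant"),
              stringsAsFactors = FALSE)
}

#' Run the full policy-evaluation pipeline
#'
#' Simulates (or reads) claims, selects the cohort, aggregates the monthly
#' outcome series, fits the segmented regression for every outcome x group
#' combination with AIC model selection, computes counterfactual policy
#' effects and the complication growth table, and writes all reports to the
#' output directory: `claims.csv`, `registry.csv`, `design_matrix.csv`,
#' `descriptive_summary.csv`, `coefficients.csv` (with significance
#' markers), `effects.csv`, `growth.csv`, and `manifest.json`. Deterministic
#' given the seed.
#'
#' @param config A list (or path to a YAML file) with optional entries
#'   `schedule` (origin, n_months, opip_start, sps_start), `sim` (arguments
#'   for [sim_config()]), `claims`/`registry` (paths to existing input files
#'   instead of simulation), `horizons`, `band_level`, `max_lag`, `seed`.
#' @param out_dir Output directory, created if needed.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the cohort, series set, fits, effects,
#'   growth table and manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  sch <- do.call(intervention_schedule, config$schedule %||% list())
  horizons <- config$horizons %||% c(12L, 15L)
  band_level <- config$band_level %||% 0.95
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # data source: exactly one of simulated claims or user files
  sim_args <- config$sim %||% list()
  use_files <- !is.null(config$claims)
  if (use_files && length(sim_args)) {
    stop("configure either claims/registry input files or synthetic ",
         "generation, not both")
  }
  say("stage: data")
  if (use_files) {
    claims <- stage("read", read_claims(config$claims))
    registry <- stage("read", read_registry(config$registry))
    scfg <- NULL
  } else {
    scfg <- stage("simulate", do.call(sim_config, c(list(schedule = sch, seed = seed),
                                                    sim_args)))
    registry <- sim_registry(seed = seed)
    claims <- sim_claims(scfg, registry)
    write_claims(claims, file.path(out_dir, "claims.csv"))
    write_registry(registry, file.path(out_dir, "registry.csv"))
  }

  say("stage: aggregate")
  window <- ym_seq(sch$origin, sch$n_months)
  idx_lo <- min(13L, sch$n_months)
  idx_hi <- max(idx_lo, min(48L, sch$n_months))
  cohort <- stage("cohort", select_cohort(claims, c(window[idx_lo], window[idx_hi])))
  set <- stage("aggregate", aggregate_monthly(claims, cohort, registry, sch))
  design <- its_design(sch)
  write_design(design, file.path(out_dir, "design_matrix.csv"))

  periods <- split(seq_len(sch$n_months), (seq_len(sch$n_months) - 1L) %/% 12L + 1L)
  names(periods) <- paste0("period", seq_along(periods))
  desc <- descriptive_summary(set, periods)
  utils::write.csv(desc, file.path(out_dir, "descriptive_summary.csv"),
                   row.names = FALSE)

  say("stage: fit")
  combos <- pipeline_outcomes()
  fits <- list()
  coef_rows <- list()
  eff_rows <- list()
  for (i in seq_len(nrow(combos))) {
    oc <- combos$outcome[i]; gr <- combos$group[i]
    y <- series_values(set, oc, gr)
    if (anyNA(y)) next  # per-patient series with empty months are not fit
    f <- stage(paste0("fit:", oc, ":", gr),
               its_fit(y, design, method = "auto", dw_seed = seed))
    key <- paste(oc, gr, sep = ".")
    fits[[key]] <- f
    b <- f$coefficients
    coef_rows[[key]] <- data.frame(
      outcome = oc, group = gr, method = f$method,
      t(matrix(sprintf("%.6g%s", b, sig_marker(f$pvalues)),
               dimnames = list(paste0("b", 0:6), NULL))),
      ar1 = if (is.null(f$rho)) "" else sprintf("%.3f", f$rho),
      dw = sprintf("%.3f", f$dw), stringsAsFactors = FALSE)
    eff <- stage(paste0("effects:", oc, ":", gr),
                 tryCatch(policy_effect(f, horizons = horizons, level = band_level),
                          error = function(e) NULL))
    if (!is.null(eff)) {
      eff_rows[[key]] <- cbind(outcome = oc, group = gr, as.data.frame(eff))
    }
  }
  utils::write.csv(do.call(rbind, coef_rows), file.path(out_dir, "coefficients.csv"),
                   row.names = FALSE)
  effects <- do.call(rbind, eff_rows)
  utils::write.csv(effects, file.path(out_dir, "effects.csv"), row.names = FALSE)

  say("stage: growth")
  growth <- NULL
  if (!use_files && !is.null(scfg)) {
    proc <- sim_procedures(scfg)
    rates <- procedure_rates(proc, scfg$cohort_size)
    growth <- annual_growth(rates)
    utils::write.csv(growth, file.path(out_dir, "growth.csv"), row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("itsar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = config_hash(config),
    schedule = unclass(sch)[c("origin", "n_months", "opip_start", "sps_start")],
    n_claims = nrow(claims), n_cohort = length(cohort),
    outcomes_fit = names(fits))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, series = set, fits = fits,
                 effects = effects, growth = growth, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of the canonicalized config (order-independent at top level).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %% 1e9
}
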