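# Segmented-regression design for a two-interruption monthly series.

#' Month arithmetic helpers
#'
#' Calendar year-months are represented as `"YYYY-MM"` strings throughout the
#' package. `ym_index()` converts a year-month to its 1-based position in the
#' study window; `ym_add()` shifts a year-month by a number of months;
#' `ym_seq()` enumerates the window.
#'
#' @param ym,origin Year-month strings `"YYYY-MM"`.
#' @param k Integer number of months to add.
#' @param n Window length in months.
#' @return `ym_index()` an integer; `ym_add()` a year-month string;
#'   `ym_seq()` a character vector of length `n`.
#' @keywords internal
#' @noRd
ym_parse <- function(ym) {
  m <- regmatches(ym, regexec("^([0-9]{4})-([0-9]{2})$", ym))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed year-month (expected 'YYYY-MM'): ",
         paste(ym[bad], collapse = ", "), call. = FALSE)
  }
  list(year = as.integer(vapply(m, `[`, "", 2L)),
       month = as.integer(vapply(m, `[`, "", 3L)))
}

ym_num <- function(ym) {
  p <- ym_parse(ym)
  if (any(p$month < 1L | p$month > 12L)) stop("month out of 1..12: ", ym, call. = FALSE)
  p$year * 12L + (p$month - 1L)
}

ym_add <- function(ym, k) {
  v <- ym_num(ym) + as.integer(k)
  sprintf("%04d-%02d", v %/% 12L, v %% 12L + 1L)
}

ym_index <- function(ym, origin) ym_num(ym) - ym_num(origin) + 1L

ym_seq <- function(origin, n) ym_add(origin, seq_len(n) - 1L)

#' Define the intervention schedule for a two-interruption study window
#'
#' Fixes the monthly study window and the calendar months at which the two
#' policies take effect: the prescriber-incentive programme (OPIP, first
#' interruption) and the single-price-system price cut (SPS, second
#' interruption). The defaults encode the Korean antidiabetics study window:
#' 54 months from January 2009, OPIP starting October 2010 (month 22) and the
#' SPS starting April 2012 (month 40).
#'
#' @param origin First month of the window, `"YYYY-MM"`.
#' @param n_months Number of monthly observations in the window.
#' @param opip_start Calendar month in which the first policy starts.
#' @param sps_start Calendar month in which the second policy starts; must be
#'   strictly after `opip_start`.
#' @return An object of class `"its_schedule"`: a list with the four inputs
#'   plus the 1-based month indices `opip_month` and `sps_month`.
#' @examples
#' sch <- intervention_schedule()
#' sch$sps_month  # 40
#' @export
intervention_schedule <- function(origin = "2009-01", n_months = 54L,
                                  opip_start = "2010-10", sps_start = "2012-04") {
  n_months <- as.integer(n_months)
  if (is.na(n_months) || n_months < 1L) stop("n_months must be a positive integer")
  opip <- ym_index(opip_start, origin)
  sps <- ym_index(sps_start, origin)
  if (sps <= opip) stop("sps_start must be strictly after opip_start")
  if (opip < 1L || sps > n_months) {
    stop("interruptions must fall inside the study window [", origin, ", ",
         ym_add(origin, n_months - 1L), "]")
  }
  structure(list(origin = origin, n_months = n_months,
                 opip_start = opip_start, sps_start = sps_start,
                 opip_month = opip, sps_month = sps),
            class = "its_schedule")
}

#' @export
print.its_schedule <- function(x, ...) {
  cat("Interrupted time-series schedule\n")
  cat(sprintf("  window : %s .. %s (%d months)\n", x$origin,
              ym_add(x$origin, x$n_months - 1L), x$n_months))
  cat(sprintf("  OPIP   : %s (month %d)\n", x$opip_start, x$opip_month))
  cat(sprintf("  SPS    : %s (month %d)\n", x$sps_start, x$sps_month))
  invisible(x)
}

#' Build the segmented-regression design matrix
#'
#' One row per calendar month of the window, with the covariates of the
#' two-interruption segmented model: a 1-based month counter `time`, a level
#' indicator and elapsed-time counter for each interruption, and a February
#' indicator absorbing the short-month dip in utilization. The policy start
#' month itself is coded as post-policy: the indicator is 1 and the counter is
#' 1 in that month (so the counter equals `time - start + 1` after the start
#' and 0 before).
#'
#' @param schedule An [intervention_schedule()].
#' @return A data frame of class `"its_design"` with columns `year`, `month`,
#'   `time`, `opip`, `time_after_opip`, `sps`, `time_after_sps`, `feb`; the
#'   schedule is attached as attribute `"schedule"`.
#' @examples
#' X <- its_design(intervention_schedule())
#' X[X$time == 40, ]  # April 2012: opip counter 19, sps counter 1
#' @export
its_design <- function(schedule = intervention_schedule()) {
  if (!inherits(schedule, "its_schedule")) stop("schedule must be an 'its_schedule'")
  n <- schedule$n_months
  t <- seq_len(n)
  p <- ym_parse(ym_seq(schedule$origin, n))
  d <- data.frame(
    year = p$year,
    month = p$month,
    time = t,
    opip = as.integer(t >= schedule$opip_month),
    time_after_opip = pmax(0L, t - schedule$opip_month + 1L),
    sps = as.integer(t >= schedule$sps_month),
    time_after_sps = pmax(0L, t - schedule$sps_month + 1L),
    feb = as.integer(p$month == 2L)
  )
  attr(d, "schedule") <- schedule
  class(d) <- c("its_design", "data.frame")
  d
}

# Names of the regressors, in model order (intercept excluded).
its_terms <- function() {
  c("time", "opip", "time_after_opip", "sps", "time_after_sps", "feb")
}

# Numeric model matrix (with intercept) from an its_design data frame.
design_matrix <- function(design) {
  stopifnot(all(its_terms() %in% names(design)))
  X <- cbind(intercept = 1, as.matrix(design[, its_terms()]))
  storage.mode(X) <- "double"
  X
}

#' Write a design matrix audit file
#'
#' @param design An [its_design()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
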