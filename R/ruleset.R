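#' Phenotyping rule set
#'
#' Bundles every threshold used in trajectory reconstruction, adherence (MPR)
#' computation and persistence classification. Two dialects are supported:
#'
#' * `"finregistry"` — the Finnish register rules: purchases followed by at
#'   least `break_threshold_days` tablet-free days are treatment breaks and are
#'   excluded from the MPR (numerator and denominator); early discontinuation
#'   requires the single purchase to fall at least `censor_buffer_days` before
#'   end of follow-up.
#' * `"estbb"` — the Estonian rules: no break exclusion (every purchase gap
#'   counts as a true gap in treatment and stays in the MPR denominator);
#'   adherence additionally requires at least `estbb_min_tablets` tablets
#'   purchased in total; a single purchase only counts as early
#'   discontinuation when it contains fewer than
#'   `estbb_nonpersist_max_packages` packages and fewer than
#'   `estbb_nonpersist_max_tablets` tablets, was made before
#'   `estbb_censor_date`, and at least `estbb_death_buffer_days` before death.
#'
#' @param dialect `"finregistry"` or `"estbb"`.
#' @param daily_dose assumed consumption, tablets per day (default 1: one
#'   tablet a day, the convention for all five medication classes).
#' @param break_threshold_days tablet-free days that define a treatment break.
#' @param mpr_cap maximum admissible MPR; larger values flag stockpiling and
#'   exclude the person from the adherence analysis. Must exceed 1.
#' @param eligibility_min_days minimum first-to-last purchase span (days)
#'   required for the adherence analysis ("at least one year of purchases").
#' @param censor_buffer_days a single purchase counts as early discontinuation
#'   only when made at least this many days before end of follow-up.
#' @param sensitivity_censor_days observability window for the sensitivity
#'   persistence definition: the first purchase must precede end of follow-up
#'   by at least this many days.
#' @param estbb_min_tablets,estbb_nonpersist_max_packages,
#'   estbb_nonpersist_max_tablets,estbb_censor_date,estbb_death_buffer_days
#'   Estonian-dialect thresholds (see above); ignored under `"finregistry"`.
#' @param apply_break_exclusion overrides the dialect default (`TRUE` for
#'   `"finregistry"`, `FALSE` for `"estbb"`).
#'
#' @return An object of class `"ruleset"` (a validated list).
#' @examples
#' rs <- adherence_ruleset()
#' rs$break_threshold_days
#' adherence_ruleset("estbb")$apply_break_exclusion
#' @export
adherence_ruleset <- function(dialect = c("finregistry", "estbb"),
                              daily_dose = 1,
                              break_threshold_days = 150L,
                              mpr_cap = 1.1,
                              eligibility_min_days = 365L,
                              censor_buffer_days = 730L,
                              sensitivity_censor_days = 365L,
                              estbb_min_tablets = 150L,
                              estbb_nonpersist_max_packages = 3L,
                              estbb_nonpersist_max_tablets = 100L,
                              estbb_censor_date = as.Date("2022-01-01"),
                              estbb_death_buffer_days = 365L,
                              apply_break_exclusion = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(apply_break_exclusion))
    apply_break_exclusion <- (dialect == "finregistry")
  rs <- list(
    dialect = dialect,
    daily_dose = as.numeric(daily_dose),
    break_threshold_days = as.integer(break_threshold_days),
    mpr_cap = as.numeric(mpr_cap),
    eligibility_min_days = as.integer(eligibility_min_days),
    censor_buffer_days = as.integer(censor_buffer_days),
    sensitivity_censor_days = as.integer(sensitivity_censor_days),
    estbb_min_tablets = as.integer(estbb_min_tablets),
    estbb_nonpersist_max_packages = as.integer(estbb_nonpersist_max_packages),
    estbb_nonpersist_max_tablets = as.integer(estbb_nonpersist_max_tablets),
    estbb_censor_date = as.Date(estbb_censor_date),
    estbb_death_buffer_days = as.integer(estbb_death_buffer_days),
    apply_break_exclusion = isTRUE(apply_break_exclusion)
  )
  validate_ruleset(rs)
  class(rs) <- "ruleset"
  rs
}

validate_ruleset <- function(rs) {
  stopifnot(
    rs$daily_dose > 0,
    rs$break_threshold_days > 0L,
    rs$mpr_cap > 1,
    rs$eligibility_min_days > 0L,
    rs$censor_buffer_days > 0L,
    rs$sensitivity_censor_days > 0L,
    rs$estbb_min_tablets > 0L,
    rs$estbb_nonpersist_max_packages > 0L,
    rs$estbb_nonpersist_max_tablets > 0L,
    rs$estbb_death_buffer_days > 0L
  )
  invisible(rs)
}

#' @export
print.ruleset <- function(x, ...) {
  cat("Phenotyping rule set (dialect:", x$dialect, ")\n")
  cat("  daily dose:", x$daily_dose, "tablet(s)/day\n")
  cat("  break threshold:", x$break_threshold_days, "tablet-free days",
      if (!x$apply_break_exclusion) "(not excluded: gaps kept in denominator)",
      "\n")
  cat("  MPR cap:", x$mpr_cap,
      "| eligibility span >=", x$eligibility_min_days, "days\n")
  cat("  early-discontinuation censor buffer:", x$censor_buffer_days, "days\n")
  if (x$dialect == "estbb")
    cat("  EstBB: >=", x$estbb_min_tablets, "tablets for adherence; single",
        "purchase <", x$estbb_nonpersist_max_packages, "packages & <",
        x$estbb_nonpersist_max_tablets, "tablets for non-persistence\n")
  invisible(x)
}
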