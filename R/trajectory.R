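#' @import data.table
#' @importFrom stats as.formula coef complete.cases confint glm lm logLik
#'   pchisq pnorm pt qchisq qnorm qt rbinom rexp rnorm runif sd setNames
#'   binomial predict residuals vcov
NULL

# ---------------------------------------------------------------------------
# Trajectory reconstruction.
#
# One vectorized engine (traj_engine) computes, for every person in a purchase
# table at once: per-purchase supply days, interval to the next purchase,
# switch-truncated effective tablets, and inclusion flags with exclusion
# reasons. The per-person functions below (build_trajectory, detect_breaks,
# truncate_switch_overlap, compute_mpr) expose the same logic on a single
# person's purchases.
# ---------------------------------------------------------------------------

# purchases: data.table with person_id, date (Date), atc, tablets (numeric),
# dose_distribution (0/1). Returns the flagged trajectory table ordered by
# (person_id, date, atc). Dose-distribution rows are retained, flagged with
# reason "dose_distribution", and ignored by every later rule.
traj_engine <- function(purchases, ruleset) {
  stopifnot(inherits(ruleset, "ruleset"))
  dt <- as.data.table(purchases)
  if (!"dose_distribution" %in% names(dt)) dt[, dose_distribution := 0L]
  if (!"tablets" %in% names(dt)) {
    stopifnot(all(c("n_packages", "tablets_per_package") %in% names(dt)))
    dt[, tablets := as.numeric(n_packages) * as.numeric(tablets_per_package)]
  }
  if (any(dt$tablets <= 0)) stop("non-positive tablet quantity in purchases")
  if (ruleset$daily_dose <= 0) stop("daily_dose must be positive")
  dt <- dt[, .(person_id, date = as.Date(date), atc = as.character(atc),
               tablets = as.numeric(tablets),
               n_packages = if ("n_packages" %in% names(dt))
                 as.numeric(n_packages) else NA_real_,
               dose_distribution = as.integer(dose_distribution))]

  dd <- dt[dose_distribution == 1L]
  active <- dt[dose_distribution != 1L]
  if (nrow(active) == 0L) stop("no purchases left after exclusions")

  # merge same-day purchases of the same formulation; deterministic order:
  # date, then ATC lexicographically for same-day different formulations
  active <- active[, .(tablets = sum(tablets), n_packages = sum(n_packages)),
                   by = .(person_id, date, atc)]
  active[, dose_distribution := 0L]
  setorder(active, person_id, date, atc)

  # person boundaries handled without by-group evaluation (speed at scale)
  active[, supply_days := tablets / ruleset$daily_dose]
  nxt_same <- c(active$person_id[-1L] == active$person_id[-nrow(active)],
                FALSE)
  day <- as.integer(active$date)
  active[, interval_days := fifelse(nxt_same,
                                    as.numeric(shift(day, -1L) - day),
                                    NA_real_)]
  active[, next_atc := fifelse(nxt_same, shift(atc, -1L), NA_character_)]

  # switch truncation: leftover tablets of the previous formulation are
  # discarded when the next purchase is a different formulation and arrives
  # before supply exhaustion
  active[, effective_tablets := tablets]
  active[!is.na(interval_days) & next_atc != atc &
           interval_days < supply_days,
         effective_tablets := interval_days * ruleset$daily_dose]

  active[, reason := "none"]
  if (ruleset$apply_break_exclusion) {
    # a break: >= break_threshold_days with no tablets available before the
    # next purchase (gap measured against the untruncated supply)
    active[!is.na(interval_days) &
             interval_days - supply_days >= ruleset$break_threshold_days,
           reason := "break"]
  }
  active[!nxt_same, reason := "last_purchase"]
  active[, included := reason == "none"]

  if (nrow(dd)) {
    dd[, `:=`(supply_days = tablets / ruleset$daily_dose,
              interval_days = NA_real_, next_atc = NA_character_,
              effective_tablets = tablets, reason = "dose_distribution",
              included = FALSE)]
    active <- rbind(active, dd, fill = TRUE)
    setorder(active, person_id, date, atc)
  }
  active[, next_atc := NULL]
  active[]
}

# per-person MPR + eligibility from a flagged trajectory table.
# Reason precedence: span first, then purchase count, then the cap.
mpr_engine <- function(traj, ruleset) {
  act <- traj[reason != "dose_distribution"]
  act[, inc_tabs := fifelse(included, effective_tablets, 0)]
  act[, inc_int := fifelse(included, interval_days, 0)]
  stats <- act[, .(n_purchases = .N,
                   total_tablets = sum(tablets),
                   first_purchase_date = min(date),
                   last_purchase_date = max(date),
                   n_included = sum(included),
                   sum_inc_tabs = sum(inc_tabs),
                   obs_days = sum(inc_int)),
               by = person_id]
  stats[, span_days := as.numeric(last_purchase_date - first_purchase_date)]
  stats[, supply_num := sum_inc_tabs / ruleset$daily_dose]
  stats[, sum_inc_tabs := NULL]
  stats[, mpr := ifelse(n_included >= 1L & obs_days > 0,
                        supply_num / obs_days, NA_real_)]
  stats[, reason := "none"]
  stats[span_days < ruleset$eligibility_min_days, reason := "span_below_min"]
  stats[reason == "none" & (n_included < 2L | obs_days <= 0),
        reason := "too_few_purchases"]
  if (ruleset$dialect == "estbb")
    stats[reason == "none" & total_tablets < ruleset$estbb_min_tablets,
          reason := "too_few_purchases"]
  stats[reason == "none" & mpr > ruleset$mpr_cap, reason := "mpr_above_cap"]
  # mpr keeps the computed ratio even when ineligible (so callers can inspect
  # e.g. a capped value); phenotype records null it for ineligible persons
  stats[, eligible := reason == "none"]
  stats[]
}

as_purchase_dt <- function(purchases) {
  dt <- as.data.table(purchases)
  if (!"person_id" %in% names(dt)) dt[, person_id := "p1"]
  dt
}

#' Build a purchase trajectory for one person
#'
#' Orders a person's purchases by date (ties between formulations broken by
#' ATC code), merges same-day purchases of the same formulation by summing
#' tablets, drops dose-distribution-service purchases (flagged, reason
#' `"dose_distribution"`), and computes per-purchase days of supply
#' (tablets / daily dose). The final purchase is always flagged excluded with
#' reason `"last_purchase"`; break detection and switch truncation are applied
#' per the rule set.
#'
#' @param purchases data.frame with columns `date`, `atc`, and either
#'   `tablets` or `n_packages` + `tablets_per_package`; optional
#'   `dose_distribution` (0/1) and `person_id` (must be constant).
#' @param ruleset an [adherence_ruleset()].
#' @return A `data.frame` of class `"trajectory"`: one row per (merged)
#'   purchase with `date`, `atc`, `tablets`, `supply_days`, `interval_days`
#'   (to the next purchase), `effective_tablets` (after switch truncation),
#'   `included`, `reason`.
#' @examples
#' p <- data.frame(date = as.Date("2012-01-01") + c(0, 100, 200),
#'                 atc = "C10AA01", tablets = 100)
#' build_trajectory(p, adherence_ruleset())
#' @export
build_trajectory <- function(purchases, ruleset = adherence_ruleset()) {
  dt <- as_purchase_dt(purchases)
  if (length(unique(dt$person_id)) != 1L)
    stop("build_trajectory() expects purchases of a single person")
  out <- as.data.frame(traj_engine(dt, ruleset))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "ruleset") <- ruleset
  out
}

#' Flag treatment breaks in a trajectory
#'
#' A purchase is a treatment break when the interval to the next purchase
#' leaves at least `break_threshold_days` days (default 150) without tablets
#' available; break purchases are excluded from the adherence calculation
#' (reason `"break"`). Under the `"estbb"` dialect no purchases are excluded:
#' every gap is treated as a true gap in treatment and stays in the MPR
#' denominator.
#'
#' @inheritParams build_trajectory
#' @param traj a `"trajectory"` from [build_trajectory()] (flags are
#'   recomputed, so calling this again is idempotent).
#' @return The trajectory with updated `included`/`reason`.
#' @export
detect_breaks <- function(traj, ruleset = attr(traj, "ruleset")) {
  recompute_flags(traj, ruleset)
}

#' Truncate leftover supply at formulation switches
#'
#' When the next purchase is a different formulation (different full ATC code)
#' and arrives before the current supply is exhausted, the leftover tablets of
#' the previous formulation are discarded: `effective_tablets` becomes
#' `interval_days * daily_dose`. Same-formulation surplus carries over, which
#' is why the MPR can exceed 1.
#'
#' @inheritParams detect_breaks
#' @return The trajectory with updated `effective_tablets`.
#' @export
truncate_switch_overlap <- function(traj, ruleset = attr(traj, "ruleset")) {
  recompute_flags(traj, ruleset)
}

recompute_flags <- function(traj, ruleset) {
  stopifnot(inherits(traj, "data.frame"))
  if (is.null(ruleset)) ruleset <- adherence_ruleset()
  dt <- as.data.table(traj)[, .(person_id, date, atc, tablets,
                                dose_distribution =
                                  as.integer(reason == "dose_distribution"))]
  out <- as.data.frame(traj_engine(dt, ruleset))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "ruleset") <- ruleset
  out
}

#' Medication possession ratio of one trajectory
#'
#' MPR = days of supply during the observation period divided by days in the
#' observation period, where the numerator is the sum of (switch-truncated)
#' tablets over included purchases divided by the daily dose, and the
#' denominator is the sum of intervals to the next purchase over included
#' purchases. An excluded purchase (last purchase, treatment break,
#' dose-distribution service) contributes neither tablets nor its interval;
#' the trajectory is a single pooled ratio, not split into segments.
#'
#' Eligibility requires a first-to-last purchase span of at least
#' `eligibility_min_days` (computed before the last-purchase exclusion), at
#' least two included purchases, and MPR not above `mpr_cap`; the `"estbb"`
#' dialect additionally requires `estbb_min_tablets` tablets in total
#' (reported, like a failed purchase-count requirement, as
#' `"too_few_purchases"`). Reason precedence: span, then purchase count, then
#' the cap.
#'
#' @inheritParams detect_breaks
#' @return A list: `mpr` (the computed ratio, reported even when ineligible;
#'   NA when undefined), `eligible`, `reason` (one of
#'   `"none"`, `"span_below_min"`, `"too_few_purchases"`, `"mpr_above_cap"`),
#'   plus `n_purchases`, `n_included`, `supply_days` and `observation_days`.
#' @examples
#' p <- data.frame(date = as.Date("2012-01-01") + c(0, 100, 200, 300, 400),
#'                 atc = "C10AA01", tablets = 100)
#' compute_mpr(build_trajectory(p, adherence_ruleset()))
#' @export
compute_mpr <- function(traj, ruleset = attr(traj, "ruleset")) {
  if (is.null(ruleset)) ruleset <- adherence_ruleset()
  stats <- mpr_engine(as.data.table(traj), ruleset)
  list(mpr = stats$mpr, eligible = stats$eligible, reason = stats$reason,
       n_purchases = stats$n_purchases, n_included = stats$n_included,
       supply_days = stats$supply_num, observation_days = stats$obs_days)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Purchase trajectory:", nrow(x), "purchase(s),",
      sum(x$included), "included\n")
  print.data.frame(x, ...)
  invisible(x)
}
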