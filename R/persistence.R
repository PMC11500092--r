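# ---------------------------------------------------------------------------
# Persistence: binary early-discontinuation phenotypes.
#
# Primary definition: persistent = taking the medication for at least 12
# months (operationalized as adherence-eligibility, i.e. the >=1-year,
# MPR <= cap set) versus early discontinuation after a single purchase. To
# avoid right-censoring, a single purchase only counts as discontinuation
# when made at least censor_buffer_days (default 730) before end of
# follow-up = min(death, emigration, registry end).
#
# Sensitivity definition: non-persistent = stopping within one year of the
# first purchase, whatever the number of purchases, with no stockpiling
# exclusions; the person must be observable for a full year after the first
# purchase.
# ---------------------------------------------------------------------------

# vectorized core used by build_phenotypes(); one row per person
persistence_primary_vec <- function(stats, ruleset, end_of_followup,
                                    single_packages = NULL,
                                    single_tablets = NULL,
                                    death_date = NULL) {
  n <- stats$n_purchases
  first <- stats$first_purchase_date
  eligible <- stats$eligible
  if (any(is.na(end_of_followup))) stop("missing end_of_followup")
  status <- rep("excluded_intermediate", length(n))

  if (ruleset$dialect == "estbb") {
    if (is.null(single_packages)) single_packages <- rep(NA_real_, length(n))
    if (is.null(single_tablets)) single_tablets <- rep(NA_real_, length(n))
    ok_size <-
      (is.na(single_packages) |
         single_packages < ruleset$estbb_nonpersist_max_packages) &
      (is.na(single_tablets) |
         single_tablets < ruleset$estbb_nonpersist_max_tablets)
    before_censor <- first < ruleset$estbb_censor_date
    if (is.null(death_date)) death_date <- as.Date(rep(NA, length(n)))
    death_ok <- is.na(death_date) |
      as.numeric(death_date - first) >= ruleset$estbb_death_buffer_days
    single <- n == 1L
    status[single & before_censor & death_ok & ok_size] <- "non_persistent"
    status[single & !(before_censor & death_ok)] <- "excluded_censored"
    # single purchase failing the package/tablet cap: not countable as early
    # discontinuation -> excluded_intermediate (already the default)
  } else {
    buffer_ok <- as.numeric(end_of_followup - first) >=
      ruleset$censor_buffer_days
    status[n == 1L & buffer_ok] <- "non_persistent"
    status[n == 1L & !buffer_ok] <- "excluded_censored"
  }
  status[n > 1L & eligible] <- "persistent"
  status
}

persistence_sensitivity_vec <- function(stats, ruleset, end_of_followup) {
  first <- stats$first_purchase_date
  last <- stats$last_purchase_date
  if (any(is.na(end_of_followup))) stop("missing end_of_followup")
  observable <- as.numeric(end_of_followup - first) >=
    ruleset$sensitivity_censor_days
  status <- ifelse(!observable, "excluded_censored",
                   ifelse(as.numeric(last - first) <
                            ruleset$sensitivity_censor_days,
                          "non_persistent", "persistent"))
  status
}

person_stats <- function(purchases, ruleset) {
  dt <- as_purchase_dt(purchases)
  traj <- traj_engine(dt, ruleset)
  mpr_engine(traj, ruleset)
}

#' Primary persistence status of one person
#'
#' Classifies a person's purchase history for one medication class as
#' `"persistent"` (at least 12 months of purchases and included in the
#' adherence analysis), `"non_persistent"` (exactly one purchase, made at
#' least `censor_buffer_days` before end of follow-up), `"excluded_censored"`
#' (one purchase, but too close to end of follow-up to rule out a later
#' refill), or `"excluded_intermediate"` (two or more purchases but not
#' adherence-eligible, e.g. stockpilers or sub-year spans). Under the
#' `"estbb"` dialect the single discontinuation purchase must additionally
#' contain fewer than 3 packages and fewer than 100 tablets, be made before
#' the dialect's censoring date and at least a year before death.
#'
#' @param purchases one person's purchase records (see [build_trajectory()];
#'   `n_packages` is used by the `"estbb"` package-count rule).
#' @param ruleset an [adherence_ruleset()].
#' @param end_of_followup `Date`: min(death, emigration, end of registry).
#' @param death_date optional `Date`, used by the `"estbb"` death buffer.
#' @return A status string.
#' @examples
#' p <- data.frame(date = as.Date("2015-01-01"), atc = "C10AA01",
#'                 tablets = 100)
#' classify_persistence_primary(p, adherence_ruleset(),
#'                              as.Date("2020-01-01"))
#' @export
classify_persistence_primary <- function(purchases, ruleset,
                                         end_of_followup,
                                         death_date = as.Date(NA)) {
  dt <- as_purchase_dt(purchases)
  stats <- person_stats(dt, ruleset)
  single <- stats$n_purchases == 1L
  sp <- st <- NA_real_
  if (single) {
    act <- dt[if ("dose_distribution" %in% names(dt))
      dose_distribution != 1L else TRUE]
    sp <- if ("n_packages" %in% names(act)) sum(act$n_packages) else NA_real_
    st <- if ("tablets" %in% names(act)) sum(act$tablets) else
      sum(act$n_packages * act$tablets_per_package)
  }
  persistence_primary_vec(stats, ruleset, as.Date(end_of_followup),
                          single_packages = sp, single_tablets = st,
                          death_date = as.Date(death_date))
}

#' Sensitivity persistence status of one person
#'
#' Alternative definition: non-persistent = the last purchase occurs within
#' one year of the first and no further purchase is ever observed, whatever
#' the number of purchases (so stopping after two or three purchases counts
#' as non-persistence); persistent otherwise. No stockpiling/MPR exclusions
#' are applied. Persons whose first purchase is within
#' `sensitivity_censor_days` of end of follow-up are `"excluded_censored"`
#' (not observable for a full year).
#'
#' @inheritParams classify_persistence_primary
#' @return A status string.
#' @export
classify_persistence_sensitivity <- function(purchases, ruleset,
                                             end_of_followup) {
  stats <- person_stats(as_purchase_dt(purchases), ruleset)
  persistence_sensitivity_vec(stats, ruleset, as.Date(end_of_followup))
}
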