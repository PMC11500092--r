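# Independent day-by-day tablet-ledger oracle for the MPR.
#
# Deliberately written as plain scalar loops over purchases and days, with
# its own re-derivation of the inclusion/exclusion rules, so it shares no
# code with the package's vectorized interval accounting.

oracle_trajectory <- function(purchases, ruleset) {
  df <- as.data.frame(purchases)
  if (!"dose_distribution" %in% names(df)) df$dose_distribution <- 0L
  if (!"tablets" %in% names(df))
    df$tablets <- df$n_packages * df$tablets_per_package
  df$date <- as.Date(df$date)
  df <- df[df$dose_distribution != 1L, , drop = FALSE]
  df <- df[order(df$date, df$atc), , drop = FALSE]
  # merge same-day same-formulation
  key <- paste(df$date, df$atc)
  agg <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    r <- rows[1, , drop = FALSE]
    r$tablets <- sum(rows$tablets)
    agg[[k]] <- r
  }
  df <- do.call(rbind, agg)
  df <- df[order(df$date, df$atc), , drop = FALSE]
  n <- nrow(df)
  df$supply <- df$tablets / ruleset$daily_dose
  df$effective <- df$tablets
  df$reason <- "none"
  for (i in seq_len(n)) {
    if (i == n) { df$reason[i] <- "last_purchase"; next }
    interval <- as.numeric(df$date[i + 1] - df$date[i])
    if (df$atc[i + 1] != df$atc[i] && interval < df$supply[i])
      df$effective[i] <- interval * ruleset$daily_dose
    tablet_free <- interval - df$supply[i]
    if (ruleset$apply_break_exclusion &&
        tablet_free >= ruleset$break_threshold_days)
      df$reason[i] <- "break"
  }
  df$included <- df$reason == "none"
  df
}

# MPR as tablet-days dispensed / observation days, counted day by day
oracle_mpr <- function(purchases, ruleset) {
  df <- oracle_trajectory(purchases, ruleset)
  n <- nrow(df)
  day <- as.integer(df$date)
  tablets_dispensed <- 0
  obs_days <- 0
  for (i in seq_len(n)) {
    if (!df$included[i]) next
    d <- day[i]
    while (d < day[i + 1]) {       # one observation day at a time
      obs_days <- obs_days + 1
      d <- d + 1L
    }
    tablets_dispensed <- tablets_dispensed + df$effective[i]
  }
  supply_days <- tablets_dispensed / ruleset$daily_dose
  span <- as.numeric(max(df$date) - min(df$date))
  n_inc <- sum(df$included)
  mpr <- if (n_inc >= 1 && obs_days > 0) supply_days / obs_days else NA_real_
  reason <- "none"
  if (span < ruleset$eligibility_min_days) reason <- "span_below_min"
  else if (n_inc < 2 || obs_days <= 0) reason <- "too_few_purchases"
  else if (ruleset$dialect == "estbb" &&
           sum(df$tablets) < ruleset$estbb_min_tablets)
    reason <- "too_few_purchases"
  else if (mpr > ruleset$mpr_cap) reason <- "mpr_above_cap"
  list(mpr = mpr, eligible = reason == "none", reason = reason,
       flags = df$reason)
}

# quick purchase-table builders
purchase_days <- function(days, tablets = 100, atc = "C10AA01",
                          start = as.Date("2012-01-01"), person = "p1") {
  data.frame(person_id = person, date = start + days, atc = atc,
             tablets = tablets)
}

random_trajectory_cohort <- function(n, seed) {
  cfg <- sim_config(
    n_persons = n, seed = seed,
    archetype_mix = c(regular = 0.35, early_discontinuer = 0.1,
                      break_taker = 0.2, stockpiler = 0.15,
                      switcher = 0.15, short_course = 0.05),
    package_sizes = c(30L, 98L, 100L))
  simulate_cohort(cfg)
}
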