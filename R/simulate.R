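# ---------------------------------------------------------------------------
# Synthetic register generator.
#
# Emulates a nationwide drug purchase register with known ground truth.
# Adherence is induced mechanistically: each person has a latent target MPR
# and refills a package of `supply` days after `supply / mpr` days (plus
# jitter), so the phenotyping stage is exercised end to end instead of
# passing labels through. Behavioural archetypes:
#   regular            refill near supply exhaustion with jitter
#   early_discontinuer exactly one purchase
#   break_taker        one >=150-tablet-free-day gap mid-trajectory
#   stockpiler         cadence dense enough that MPR > 1.1
#   switcher           one formulation change with overlapping supply
#   short_course       2-3 purchases, stops within a year
# Covariate effects shift the refill cadence (adherence) and the odds of the
# early-discontinuer archetype (persistence).
# ---------------------------------------------------------------------------

sim_atc_codes <- function(medication_class) {
  switch(medication_class,
         statins       = c("C10AA01", "C10AA05", "C10AA07"),
         bp            = c("C03CA01", "C08CA01", "C09AA02"),
         antiplatelets = c("B01AC04", "B01AC30"),
         doac          = c("B01AF01", "B01AF02"),
         breast_cancer = c("L02BA01", "L02BG04"),
         stop("unknown medication class: ", medication_class))
}

archetype_names <- function() {
  c("regular", "early_discontinuer", "break_taker", "stockpiler",
    "switcher", "short_course")
}

#' Simulation configuration
#'
#' Validated parameter bundle for [simulate_cohort()]. Defaults describe a
#' statin-like cohort: one tablet a day, 100-tablet packages, a latent mean
#' MPR of 0.92 with person SD 0.05 (matching register-scale statin adherence
#' around 0.9), 10-day refill jitter, 10 years of register coverage ending
#' 2020-01-01, and a small fraction of deaths/emigrations for right-censoring.
#'
#' @param n_persons number of persons to simulate.
#' @param medication_class one of [atc_classes()] names.
#' @param study_start,study_end register coverage window (`study_end` is the
#'   end-of-registry censoring date).
#' @param archetype_mix named probabilities over the behavioural archetypes
#'   (must sum to 1).
#' @param base_mpr latent mean target MPR for refill-driven archetypes.
#' @param mpr_person_sd between-person SD of the latent target MPR.
#' @param refill_interval_mean_days optional override: when given, `base_mpr`
#'   is derived as mean package supply / this interval.
#' @param refill_jitter_sd_days SD of the per-refill timing jitter (days).
#' @param package_sizes tablets per package; each purchase draws one package.
#' @param daily_dose assumed consumption, tablets/day.
#' @param covariate_effects named list; each element has `adherence_effect`
#'   (absolute change in target MPR when the binary covariate is 1) and
#'   `persistence_logodds_effect` (shift of the log-odds of persisting, i.e.
#'   minus the early-discontinuer log-odds).
#' @param covariate_prevalences named probabilities for the binary person
#'   covariates; must cover every name in `covariate_effects`.
#' @param death_fraction,emigration_fraction fractions of persons assigned a
#'   death/emigration date inside the study window.
#' @param dose_distribution_fraction fraction of persons whose purchases are
#'   biweekly dose-distribution-service micro-purchases (flagged, and
#'   excluded by the phenotyping stage).
#' @param secondary_prevention_fraction fraction of persons given a
#'   class-qualifying diagnosis before their first purchase.
#' @param cci_burden target expected Charlson comorbidity index injected by
#'   [simulate_diagnoses()] (0 to 12).
#' @param init_window_days first purchases are drawn uniformly within this
#'   many days after `study_start`.
#' @param seed integer seed; mandatory (reproducibility is not optional).
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_persons = 100, seed = 1)
#' @export
sim_config <- function(n_persons,
                       medication_class = "statins",
                       study_start = as.Date("2010-01-01"),
                       study_end = as.Date("2020-01-01"),
                       archetype_mix = c(regular = 0.80,
                                         early_discontinuer = 0.05,
                                         break_taker = 0.05,
                                         stockpiler = 0.05,
                                         switcher = 0.03,
                                         short_course = 0.02),
                       base_mpr = 0.92,
                       mpr_person_sd = 0.05,
                       refill_interval_mean_days = NULL,
                       refill_jitter_sd_days = 10,
                       package_sizes = 100L,
                       daily_dose = 1,
                       covariate_effects = list(),
                       covariate_prevalences = c(sex_female = 0.5,
                                                 language_fi_sv = 0.95,
                                                 social_assistance = 0.08,
                                                 urban = 0.72),
                       death_fraction = 0.04,
                       emigration_fraction = 0.01,
                       dose_distribution_fraction = 0,
                       secondary_prevention_fraction = 0.3,
                       cci_burden = 0.5,
                       init_window_days = 730L,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory: reproducibility is not optional")
  if (missing(n_persons) || n_persons < 1)
    stop("n_persons must be a positive integer")
  archetype_mix <- unlist(archetype_mix)  # accept YAML-style nested lists
  covariate_prevalences <- unlist(covariate_prevalences)
  bad <- setdiff(names(archetype_mix), archetype_names())
  if (length(bad))
    stop("unknown archetype name(s): ", paste(bad, collapse = ", "))
  if (abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix probabilities must sum to 1")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  missing_prev <- setdiff(names(covariate_effects),
                          names(covariate_prevalences))
  if (length(missing_prev))
    stop("covariate_effects name(s) without a prevalence: ",
         paste(missing_prev, collapse = ", "))
  stopifnot(all(package_sizes > 0), daily_dose > 0,
            refill_jitter_sd_days >= 0, mpr_person_sd >= 0,
            death_fraction >= 0, death_fraction <= 1,
            emigration_fraction >= 0, emigration_fraction <= 1,
            dose_distribution_fraction >= 0, dose_distribution_fraction <= 1,
            secondary_prevention_fraction >= 0,
            secondary_prevention_fraction <= 1,
            cci_burden >= 0, cci_burden <= 12)
  if (!is.null(refill_interval_mean_days)) {
    stopifnot(refill_interval_mean_days > 0)
    base_mpr <- mean(package_sizes) / daily_dose / refill_interval_mean_days
  }
  full_mix <- setNames(numeric(length(archetype_names())), archetype_names())
  full_mix[names(archetype_mix)] <- archetype_mix
  cfg <- list(n_persons = as.integer(n_persons),
              medication_class = medication_class,
              study_start = study_start, study_end = study_end,
              archetype_mix = full_mix, base_mpr = base_mpr,
              mpr_person_sd = mpr_person_sd,
              refill_jitter_sd_days = refill_jitter_sd_days,
              package_sizes = as.integer(package_sizes),
              daily_dose = daily_dose,
              covariate_effects = covariate_effects,
              covariate_prevalences = covariate_prevalences,
              death_fraction = death_fraction,
              emigration_fraction = emigration_fraction,
              dose_distribution_fraction = dose_distribution_fraction,
              secondary_prevention_fraction = secondary_prevention_fraction,
              cci_burden = cci_burden,
              init_window_days = as.integer(init_window_days),
              seed = as.integer(seed))
  sim_atc_codes(medication_class)  # validates the class name
  class(cfg) <- "sim_config"
  cfg
}

effect_of <- function(eff, which) {
  v <- eff[[which]]
  if (is.null(v) || is.na(v)) 0 else as.numeric(v)
}

#' Simulate a purchase / diagnosis / person register with known ground truth
#'
#' Generates a synthetic cohort under the behavioural archetypes and injected
#' covariate effects of the configuration; deterministic given the seed. See
#' [sim_config()] for the generative model.
#'
#' @param config a [sim_config()].
#' @return A list of class `"sim_cohort"` with `purchases`, `diagnoses`,
#'   `persons` (register-schema `data.frame`s) and `groundtruth` (per person:
#'   archetype, latent target MPR, true consumption rate in tablets/day, the
#'   covariate values, and the injected effects as an attribute).
#' @examples
#' coh <- simulate_cohort(sim_config(n_persons = 20, seed = 42))
#' head(coh$purchases)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  start <- config$study_start; end <- config$study_end
  span <- as.numeric(end - start)

  ids <- sprintf("P%07d", seq_len(n))
  prev <- config$covariate_prevalences
  covn <- names(prev)
  X <- vapply(covn, function(cv) rbinom(n, 1L, prev[[cv]]), integer(n))
  if (is.null(dim(X))) X <- matrix(X, nrow = n, dimnames = list(NULL, covn))

  persons <- data.table(
    person_id = ids,
    sex = if ("sex_female" %in% covn)
      ifelse(X[, "sex_female"] == 1L, "female", "male")
    else sample(c("female", "male"), n, replace = TRUE),
    birth_date = start - round(runif(n, 26 * 365.25, 80 * 365.25)),
    death_date = as.Date(NA), emigration_date = as.Date(NA),
    language_fi_sv = if ("language_fi_sv" %in% covn)
      X[, "language_fi_sv"] else rbinom(n, 1L, 0.95),
    education_years = as.numeric(sample(9:21, n, replace = TRUE)),
    social_assistance = if ("social_assistance" %in% covn)
      X[, "social_assistance"] else rbinom(n, 1L, 0.08),
    urban = if ("urban" %in% covn) X[, "urban"] else rbinom(n, 1L, 0.72)
  )
  dies <- runif(n) < config$death_fraction
  persons$death_date[dies] <- start +
    round(runif(sum(dies), 365, span - 1))
  emig <- !dies & runif(n) < config$emigration_fraction
  persons$emigration_date[emig] <- start +
    round(runif(sum(emig), 365, span - 1))
  end_i <- pmin(fifelse(is.na(persons$death_date), end, persons$death_date),
                fifelse(is.na(persons$emigration_date), end,
                        persons$emigration_date))

  # latent target MPR: base + injected covariate effects + person noise
  eff <- config$covariate_effects
  adh_shift <- rep(0, n); logodds_shift <- rep(0, n)
  for (cv in names(eff)) {
    adh_shift <- adh_shift + effect_of(eff[[cv]], "adherence_effect") * X[, cv]
    logodds_shift <- logodds_shift +
      effect_of(eff[[cv]], "persistence_logodds_effect") * X[, cv]
  }
  m <- config$base_mpr + adh_shift + rnorm(n, 0, config$mpr_person_sd)
  m <- pmin(pmax(m, 0.40), 1.05)

  # archetypes; persistence effects shift the early-discontinuer odds
  # (lower persistence log-odds -> higher discontinuation probability),
  # remaining archetypes keep their relative proportions
  mix <- config$archetype_mix
  p_ed <- rep(mix[["early_discontinuer"]], n)
  shift <- logodds_shift != 0
  if (any(shift) && mix[["early_discontinuer"]] > 0 &&
      mix[["early_discontinuer"]] < 1) {
    lo <- log(p_ed / (1 - p_ed)) - logodds_shift
    p_ed <- 1 / (1 + exp(-lo))
  }
  others <- mix[setdiff(archetype_names(), "early_discontinuer")]
  if (sum(others) > 0) {
    w <- others / sum(others)
    probs <- (1 - p_ed) %o% w
  } else probs <- matrix(0, n, length(others),
                         dimnames = list(NULL, names(others)))
  probmat <- cbind(early_discontinuer = p_ed, probs)
  cum <- probmat
  for (j in seq_len(ncol(cum))[-1L]) cum[, j] <- cum[, j - 1L] + probmat[, j]
  cum[, ncol(cum)] <- 1  # guard against floating-point undershoot
  u <- runif(n)
  arch <- colnames(probmat)[max.col(u <= cum, ties.method = "first")]

  # cadence factor: days waited per day of supply = 1 / mpr
  f <- 1 / m
  f[arch == "stockpiler"] <- runif(sum(arch == "stockpiler"), 0.60, 0.72)

  first <- start + floor(runif(n) *
                           pmin(config$init_window_days,
                                pmax(as.numeric(end_i - start) - 30, 1)))
  follow <- pmax(as.numeric(end_i - first), 0)

  atcs <- sim_atc_codes(config$medication_class)
  home_idx <- sample.int(length(atcs), n, replace = TRUE)
  home_atc <- atcs[home_idx]
  alt_atc <- if (length(atcs) > 1) {
    # uniform over the non-home codes, vectorized
    step <- sample.int(length(atcs) - 1L, n, replace = TRUE)
    atcs[((home_idx - 1L + step) %% length(atcs)) + 1L]
  } else home_atc

  min_supply <- min(config$package_sizes) / config$daily_dose
  kmax <- pmin(ceiling(follow / (min_supply * 0.55)) + 3L, 500L)
  kmax[arch == "early_discontinuer"] <- 1L
  n_sc <- sample(2:3, n, replace = TRUE)
  kmax[arch == "short_course"] <- n_sc[arch == "short_course"]

  long <- data.table(person_id = rep(ids, kmax),
                     row = sequence(kmax),
                     arch = rep(arch, kmax),
                     f = rep(f, kmax),
                     home = rep(home_atc, kmax),
                     alt = rep(alt_atc, kmax),
                     first_date = rep(first, kmax),
                     end_date = rep(end_i, kmax))
  N <- nrow(long)
  long[, size := config$package_sizes[sample.int(length(config$package_sizes),
                                                 N, replace = TRUE)]]
  long[, supply := size / config$daily_dose]
  long[, interval := pmax(round(supply * f +
                                  rnorm(N, 0, config$refill_jitter_sd_days)),
                          7)]
  # break takers: the gap after their 3rd purchase leaves >=150 tablet-free
  # days; switchers: an early refill (overlapping supply) at the switch
  long[arch == "break_taker" & row == 3L,
       interval := round(supply) + 150L + sample(0:90, .N, replace = TRUE)]
  long[arch == "switcher" & row == 3L,
       interval := pmax(round(supply * 0.5), 7)]
  long[, offset := cumsum(shift(interval, 1L, fill = 0)), by = person_id]
  long[, date := first_date + offset]
  long <- long[row == 1L | date <= end_date]
  long[, atc := fifelse(arch == "switcher" & row >= 4L, alt, home)]

  purchases <- long[, .(person_id, date, atc,
                        n_packages = 1L, tablets_per_package = size,
                        dose_distribution = 0L)]

  # dose-distribution persons: biweekly flagged micro-purchases instead
  if (config$dose_distribution_fraction > 0) {
    dd_ids <- ids[runif(n) < config$dose_distribution_fraction]
    if (length(dd_ids)) {
      purchases <- purchases[!person_id %in% dd_ids]
      idx <- match(dd_ids, ids)
      reps <- pmax(floor(pmax(as.numeric(end_i[idx] - first[idx]), 0) / 14), 1)
      ddt <- data.table(person_id = rep(dd_ids, reps),
                        k = sequence(reps),
                        first_date = rep(first[idx], reps),
                        atc = rep(home_atc[idx], reps))
      ddt[, date := first_date + (k - 1L) * 14L]
      purchases <- rbind(purchases,
                         ddt[, .(person_id, date, atc, n_packages = 1L,
                                 tablets_per_package = 14L,
                                 dose_distribution = 1L)])
    }
  }
  setorder(purchases, person_id, date, atc)

  groundtruth <- data.table(person_id = ids, archetype = arch,
                            target_mpr = m,
                            true_rate = m * config$daily_dose,
                            first_purchase_date = first,
                            end_of_followup = end_i)
  for (cv in covn) groundtruth[[cv]] <- X[, cv]

  diagnoses <- simulate_diagnoses(as.data.frame(persons), config,
                                  first_purchase_date = first)

  out <- list(purchases = as.data.frame(purchases),
              diagnoses = diagnoses,
              persons = as.data.frame(persons),
              groundtruth = as.data.frame(groundtruth))
  attr(out$groundtruth, "injected_effects") <- config$covariate_effects
  class(out) <- "sim_cohort"
  out
}

#' Simulate a diagnosis register
#'
#' Two generative components: (1) a `secondary_prevention_fraction` of persons
#' receive one class-qualifying ICD-10 code dated before their first purchase;
#' (2) a comorbidity burden targeting an expected Charlson comorbidity index
#' of `cci_burden`, injected by drawing nine non-hierarchical Charlson
#' conditions (total weight 12) independently with probability
#' `cci_burden / 12` each, so E\[CCI\] equals `cci_burden` exactly.
#'
#' @param persons person register (used for ids).
#' @param config a [sim_config()]; `secondary_prevention_fraction` and
#'   `cci_burden` are read from it.
#' @param first_purchase_date `Date` vector aligned with `persons` (diagnoses
#'   are dated before it); defaults to `study_start`.
#' @return Diagnosis register `data.frame`: `person_id`, `date`, `icd10`.
#' @export
simulate_diagnoses <- function(persons, config, first_purchase_date = NULL) {
  stopifnot(inherits(config, "sim_config"))
  frac <- config$secondary_prevention_fraction
  if (frac < 0 || frac > 1) stop("fraction outside [0, 1]")
  n <- nrow(persons)
  ids <- persons$person_id
  if (is.null(first_purchase_date))
    first_purchase_date <- rep(config$study_start, n)
  first_purchase_date <- as.Date(first_purchase_date)

  out <- list()
  codes <- medication_codelist(config$medication_class)
  if (!is.null(codes) && frac > 0) {
    sel <- runif(n) < frac
    if (frac >= 1) sel <- rep(TRUE, n)
    k <- sum(sel)
    if (k) out$sp <- data.table(
      person_id = ids[sel],
      date = first_purchase_date[sel] - sample(30:2000, k, replace = TRUE),
      icd10 = sample(codes, k, replace = TRUE))
  }
  # nine Charlson conditions without severity-hierarchy interactions:
  # weight-1 CHF/dementia/COPD/rheumatic/peptic ulcer/mild liver,
  # weight-2 hemiplegia/renal/malignancy; total weight 12
  cci_codes <- c(I50 = 1L, F03 = 1L, J44 = 1L, M05 = 1L, K25 = 1L, K73 = 1L,
                 G81 = 2L, N18 = 2L, C34 = 2L)
  if (config$cci_burden > 0) {
    p <- config$cci_burden / sum(cci_codes)
    hit <- matrix(runif(n * length(cci_codes)) < p, nrow = n)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) out$cci <- data.table(
      person_id = ids[idx[, 1]],
      date = first_purchase_date[idx[, 1]] -
        sample(30:3000, nrow(idx), replace = TRUE),
      icd10 = names(cci_codes)[idx[, 2]])
  }
  if (!length(out))
    return(data.frame(person_id = character(),
                      date = as.Date(character()), icd10 = character()))
  dt <- rbindlist(out)
  setorder(dt, person_id, date, icd10)
  as.data.frame(dt)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic register cohort:", nrow(x$persons), "persons,",
      nrow(x$purchases), "purchases,", nrow(x$diagnoses), "diagnoses\n")
  cat("archetypes:\n")
  print(table(x$groundtruth$archetype))
  invisible(x)
}
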