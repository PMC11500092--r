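#' Phenotype a register: adherence and persistence per person
#'
#' Runs the full phenotyping stage for one medication class on register
#' tables: filters purchases to the class ATC codes, applies cohort inclusion
#' rules (age >= 18 at first purchase; breast cancer medications: females with
#' a prior C50 diagnosis; DOAC: a prior atrial fibrillation / venous
#' thromboembolism diagnosis), reconstructs trajectories, computes the MPR
#' with all exclusion rules, and classifies primary and sensitivity
#' persistence. For antiplatelets persistence is not analyzed (the class is
#' often prescribed for 6–12-month courses): statuses are set to
#' `"not_applicable"`.
#'
#' @param purchases purchase register: `person_id`, `date`, `atc`,
#'   `n_packages`, `tablets_per_package`, `dose_distribution`.
#' @param persons person register: `person_id`, `sex`, `birth_date`,
#'   `death_date`, `emigration_date`, ... (see [read_register()]).
#' @param diagnoses diagnosis register: `person_id`, `date`, `icd10`; only
#'   needed for classes with a prerequisite diagnosis (may be `NULL`
#'   otherwise).
#' @param medication_class one of [atc_classes()] names.
#' @param ruleset an [adherence_ruleset()].
#' @param registry_end last date with register coverage (end of follow-up for
#'   persons without death/emigration), default 2020-01-01.
#' @return A `data.frame` (one row per included person) with `person_id`,
#'   `medication_class`, `adherence` (NA unless `adherence_eligible`),
#'   `adherence_eligible`, `adherence_excluded_reason`, `persistence_primary`,
#'   `persistence_sensitivity`, `first_purchase_date`,
#'   `treatment_length_years` (last minus first purchase over 365.25, all
#'   purchases pre-exclusion), `n_purchases`. Attribute `"exclusions"` holds
#'   the attrition audit (`data.frame` reason/count), including persons
#'   dropped before phenotyping; `rows_in = rows_out + sum(exclusions)`.
#' @examples
#' cfg <- sim_config(n_persons = 50, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' ph <- build_phenotypes(cohort$purchases, cohort$persons, cohort$diagnoses,
#'                        "statins", adherence_ruleset())
#' table(ph$persistence_primary)
#' @export
build_phenotypes <- function(purchases, persons, diagnoses = NULL,
                             medication_class = "statins",
                             ruleset = adherence_ruleset(),
                             registry_end = as.Date("2020-01-01")) {
  prefixes <- atc_classes(medication_class)
  pur <- as.data.table(purchases)
  per <- as.data.table(persons)
  stopifnot(all(c("person_id", "date", "atc") %in% names(pur)),
            all(c("person_id", "sex", "birth_date") %in% names(per)))
  pur[, date := as.Date(date)]
  keep <- rep(FALSE, nrow(pur))
  for (p in prefixes) keep <- keep | startsWith(as.character(pur$atc), p)
  pur <- pur[keep]
  if (nrow(pur) == 0L) stop("no purchases for class ", medication_class)
  if (!all(pur$person_id %in% per$person_id))
    stop("purchase register contains persons absent from the person table")

  exclusions <- list()
  n_start <- length(unique(pur$person_id))

  # dose-distribution purchases never enter the trajectory; a person left
  # with only such purchases is dropped
  if ("dose_distribution" %in% names(pur)) {
    act <- pur[dose_distribution != 1L]
  } else act <- copy(pur)
  gone <- setdiff(unique(pur$person_id), unique(act$person_id))
  if (length(gone)) exclusions$only_dose_distribution <- length(gone)
  pur <- pur[!person_id %in% gone]

  firsts <- act[, .(first_purchase_date = min(date)), by = person_id]
  per[, birth_date := as.Date(birth_date)]
  firsts <- merge(firsts, per, by = "person_id")
  firsts[, age_at_init :=
           as.numeric(first_purchase_date - birth_date) / 365.25]

  drop_persons <- function(ids, reason) {
    ids <- unique(ids)
    if (length(ids)) {
      exclusions[[reason]] <<- length(ids)
      firsts <<- firsts[!person_id %in% ids]
      pur <<- pur[!person_id %in% ids]
    }
  }
  drop_persons(firsts[age_at_init < 18, person_id], "age_below_18")

  if (medication_class == "breast_cancer") {
    drop_persons(firsts[tolower(substr(as.character(sex), 1, 1)) != "f",
                        person_id], "not_female")
  }
  if (medication_class %in% c("breast_cancer", "doac")) {
    codes <- medication_codelist(medication_class)
    dia <- if (is.null(diagnoses)) {
      data.table(person_id = character(), date = as.Date(character()),
                 icd10 = character())
    } else as.data.table(diagnoses)[, date := as.Date(date)]
    dia <- dia[icd10_matches(icd10, codes)]
    qual <- merge(dia, firsts[, .(person_id, first_purchase_date)],
                  by = "person_id")
    qual <- unique(qual[date < first_purchase_date, person_id])
    drop_persons(setdiff(firsts$person_id, qual), "no_prior_diagnosis")
  }
  if (nrow(firsts) == 0L) stop("empty cohort after inclusion filters")

  traj <- traj_engine(pur, ruleset)
  stats <- mpr_engine(traj, ruleset)
  stats <- merge(stats,
                 firsts[, .(person_id, death_date =
                              if ("death_date" %in% names(firsts))
                                as.Date(death_date) else as.Date(NA),
                            emigration_date =
                              if ("emigration_date" %in% names(firsts))
                                as.Date(emigration_date) else as.Date(NA))],
                 by = "person_id")
  stats[, end_of_followup := pmin(fifelse(is.na(death_date),
                                          as.Date(registry_end), death_date),
                                  fifelse(is.na(emigration_date),
                                          as.Date(registry_end),
                                          emigration_date))]

  # package/tablet content of the single purchase (EstBB non-persistence rule)
  single_ids <- stats[n_purchases == 1L, person_id]
  singles <- traj[reason != "dose_distribution" & person_id %in% single_ids,
                  .(sp = sum(n_packages), st = sum(tablets)),
                  by = person_id]
  stats <- merge(stats, singles, by = "person_id", all.x = TRUE)

  stats[, persistence_primary :=
          persistence_primary_vec(.SD, ruleset, end_of_followup,
                                  single_packages = sp, single_tablets = st,
                                  death_date = death_date)]
  stats[, persistence_sensitivity :=
          persistence_sensitivity_vec(.SD, ruleset, end_of_followup)]
  if (medication_class == "antiplatelets") {
    stats[, persistence_primary := "not_applicable"]
    stats[, persistence_sensitivity := "not_applicable"]
  }

  out <- stats[, .(person_id, medication_class = medication_class,
                   adherence = fifelse(eligible, mpr, NA_real_),
                   adherence_eligible = eligible,
                   adherence_excluded_reason = reason,
                   persistence_primary, persistence_sensitivity,
                   first_purchase_date,
                   treatment_length_years = span_days / 365.25,
                   n_purchases)]
  setorder(out, person_id)
  out <- as.data.frame(out)
  excl <- data.frame(reason = names(exclusions),
                     count = as.integer(unlist(exclusions %||% integer())))
  if (nrow(excl) == 0L)
    excl <- data.frame(reason = character(), count = integer())
  attr(out, "exclusions") <- excl
  attr(out, "n_persons_in") <- n_start
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
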