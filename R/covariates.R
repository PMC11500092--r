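# ---------------------------------------------------------------------------
# Baseline risk factors at treatment initiation.
# ---------------------------------------------------------------------------

# Quan (2005) ICD-10 coding algorithm for the 17 Charlson condition groups,
# with the original Charlson weights (1/2/3/6). Prefix matching on codes with
# decimal points removed.
quan_charlson_map <- function() {
  list(
    mi        = list(w = 1L, p = c("I21", "I22", "I252")),
    chf       = list(w = 1L, p = c("I099", "I110", "I130", "I132", "I255",
                                   "I420", "I425", "I426", "I427", "I428",
                                   "I429", "I43", "I50", "P290")),
    pvd       = list(w = 1L, p = c("I70", "I71", "I731", "I738", "I739",
                                   "I771", "I790", "I792", "K551", "K558",
                                   "K559", "Z958", "Z959")),
    cevd      = list(w = 1L, p = c("G45", "G46", "H340",
                                   expand_icd_range("I60", "I69"))),
    dementia  = list(w = 1L, p = c("F00", "F01", "F02", "F03", "F051",
                                   "G30", "G311")),
    copd      = list(w = 1L, p = c("I278", "I279",
                                   expand_icd_range("J40", "J47"),
                                   expand_icd_range("J60", "J67"),
                                   "J684", "J701", "J703")),
    rheum     = list(w = 1L, p = c("M05", "M06", "M315", "M32", "M33",
                                   "M34", "M351", "M353", "M360")),
    pud       = list(w = 1L, p = c("K25", "K26", "K27", "K28")),
    mld       = list(w = 1L, p = c("B18", "K700", "K701", "K702", "K703",
                                   "K709", "K713", "K714", "K715", "K717",
                                   "K73", "K74", "K760", "K762", "K763",
                                   "K764", "K768", "K769", "Z944")),
    diab      = list(w = 1L, p = c(t(outer(c("E10", "E11", "E12", "E13",
                                             "E14"),
                                           c("0", "1", "6", "8", "9"),
                                           paste0)))),
    diabwc    = list(w = 2L, p = c(t(outer(c("E10", "E11", "E12", "E13",
                                             "E14"),
                                           c("2", "3", "4", "5", "7"),
                                           paste0)))),
    hp        = list(w = 2L, p = c("G041", "G114", "G801", "G802", "G81",
                                   "G82", "G830", "G831", "G832", "G833",
                                   "G834", "G839")),
    rend      = list(w = 2L, p = c("I120", "I131", "N032", "N033", "N034",
                                   "N035", "N036", "N037", "N052", "N053",
                                   "N054", "N055", "N056", "N057", "N18",
                                   "N19", "N250", "Z490", "Z491", "Z492",
                                   "Z940", "Z992")),
    cancer    = list(w = 2L, p = c(expand_icd_range("C00", "C26"),
                                   expand_icd_range("C30", "C34"),
                                   expand_icd_range("C37", "C41"), "C43",
                                   expand_icd_range("C45", "C58"),
                                   expand_icd_range("C60", "C76"),
                                   expand_icd_range("C81", "C85"), "C88",
                                   expand_icd_range("C90", "C97"))),
    msld      = list(w = 3L, p = c("I850", "I859", "I864", "I982", "K704",
                                   "K711", "K721", "K729", "K765", "K766",
                                   "K767")),
    metacanc  = list(w = 6L, p = c("C77", "C78", "C79", "C80")),
    aids      = list(w = 6L, p = c("B20", "B21", "B22", "B24"))
  )
}

#' Charlson comorbidity index from ICD-10 codes
#'
#' Weighted sum over the 17 Charlson condition groups, each counted once,
#' using the Quan (2005) ICD-10 coding algorithm and the original Charlson
#' weights (1, 2, 3, 6). The standard severity hierarchy applies: complicated
#' diabetes supersedes uncomplicated, moderate/severe liver disease supersedes
#' mild, and metastatic solid tumour supersedes non-metastatic malignancy.
#' Unmapped codes contribute 0; the result is order-invariant and idempotent
#' under duplicated codes.
#'
#' @param icd10 character vector of ICD-10 codes (decimal points optional),
#'   e.g. all diagnoses registered before the first purchase.
#' @return Non-negative integer.
#' @examples
#' compute_cci(character())        # 0
#' compute_cci("I21")              # myocardial infarction: 1
#' compute_cci(c("C78", "I50"))    # metastatic tumour + CHF: 6 + 1
#' @export
compute_cci <- function(icd10) {
  if (!length(icd10)) return(0L)
  map <- quan_charlson_map()
  present <- vapply(map, function(g) any(icd10_matches(icd10, g$p)), logical(1))
  # severity hierarchy: keep the more severe member only
  if (present[["diabwc"]]) present[["diab"]] <- FALSE
  if (present[["msld"]]) present[["mld"]] <- FALSE
  if (present[["metacanc"]]) present[["cancer"]] <- FALSE
  sum(vapply(map[present], function(g) g$w, integer(1)))
}

#' Secondary-prevention status at treatment initiation
#'
#' `TRUE` when any class-qualifying diagnosis (see [medication_codelist()])
#' strictly precedes the first purchase, `FALSE` otherwise; `NA` for blood
#' pressure medications, for which no qualifying event is defined.
#'
#' @param diagnoses data.frame with `icd10` and `date` (one person's
#'   diagnoses), or `NULL`.
#' @param first_purchase_date `Date` of treatment initiation.
#' @param medication_class class name.
#' @param codelist ICD-10 prefixes; defaults to the class list.
#' @return `TRUE`/`FALSE`, or `NA` when not applicable.
#' @examples
#' d <- data.frame(icd10 = "I21", date = as.Date("2010-05-01"))
#' classify_secondary_prevention(d, as.Date("2012-01-01"), "statins")
#' @export
classify_secondary_prevention <- function(diagnoses, first_purchase_date,
                                          medication_class,
                                          codelist =
                                            medication_codelist(medication_class)) {
  if (!medication_class %in% medication_class_names())
    stop("unknown medication class: ", medication_class)
  if (is.null(codelist)) return(NA)  # bp: no qualifying event defined
  if (is.null(diagnoses) || nrow(diagnoses) == 0L) return(FALSE)
  hit <- icd10_matches(diagnoses$icd10, codelist) &
    as.Date(diagnoses$date) < as.Date(first_purchase_date)
  any(hit)
}

#' Number of concurrent study-medication treatments
#'
#' Counts how many of the other four study medication classes have at least
#' one purchase by the person within a window around treatment initiation
#' (default +/- 365 days) — the polytherapy covariate.
#'
#' @param purchases the full purchase register (all classes).
#' @param person one `person_id`.
#' @param medication_class the index class (not counted).
#' @param first_purchase_date `Date` of initiation of the index class.
#' @param window_days half-width of the window, days.
#' @return Integer in 0..4.
#' @export
count_polytherapy <- function(purchases, person, medication_class,
                              first_purchase_date, window_days = 365L) {
  pur <- as.data.table(purchases)[person_id == person]
  if (nrow(pur) == 0L) return(0L)
  pur[, date := as.Date(date)]
  pur <- pur[abs(as.numeric(date - as.Date(first_purchase_date))) <=
               window_days]
  other <- setdiff(medication_class_names(), medication_class)
  sum(vapply(other, function(cl) {
    pf <- atc_classes(cl)
    any(Reduce(`|`, lapply(pf, function(p)
      startsWith(as.character(pur$atc), p))))
  }, logical(1)))
}

#' Derive the baseline covariate table for a phenotyped cohort
#'
#' Joins the person register to phenotype records and computes the eight
#' baseline risk factors at treatment initiation: sex, age at initiation,
#' secondary prevention, Charlson comorbidity index (all diagnoses before the
#' first purchase), years of education, living area (urban), mother tongue
#' (Finnish/Swedish vs other), and social assistance in the year before
#' initiation, plus the polytherapy count.
#'
#' @param phenotypes output of [build_phenotypes()].
#' @param persons,diagnoses,purchases register tables; `purchases` should be
#'   the full register (all classes) so polytherapy can be counted.
#' @param university_min_years education years at or above which a person is
#'   coded "university degree or higher" (default 16).
#' @param polytherapy_window_days window for [count_polytherapy()].
#' @return `data.frame`, one row per phenotyped person, with raw covariates
#'   (`sex`, `age_at_init`, `year_of_birth`, `secondary_prevention`, `cci`,
#'   `education_years`, `urban`, `language_fi_sv`, `social_assistance`,
#'   `n_concurrent_treatments`).
#' @export
derive_covariates <- function(phenotypes, persons, diagnoses = NULL,
                              purchases = NULL, university_min_years = 16,
                              polytherapy_window_days = 365L) {
  ph <- as.data.table(phenotypes)
  per <- as.data.table(persons)
  cl <- ph$medication_class[1]
  out <- merge(ph[, .(person_id, medication_class, first_purchase_date)],
               per, by = "person_id")
  out[, birth_date := as.Date(birth_date)]
  out[, first_purchase_date := as.Date(first_purchase_date)]
  out[, age_at_init := as.numeric(first_purchase_date - birth_date) / 365.25]
  out[, year_of_birth := as.integer(format(birth_date, "%Y"))]

  codes <- medication_codelist(cl)
  if (is.null(diagnoses)) {
    out[, secondary_prevention := if (is.null(codes)) NA else FALSE]
    out[, cci := 0L]
  } else {
    dia <- as.data.table(diagnoses)[, date := as.Date(date)]
    dia <- merge(dia, out[, .(person_id, first_purchase_date)],
                 by = "person_id")
    dia <- dia[date < first_purchase_date]
    if (is.null(codes)) {
      out[, secondary_prevention := NA]  # bp: no qualifying event defined
    } else {
      sp <- dia[icd10_matches(icd10, codes), unique(person_id)]
      out[, secondary_prevention := person_id %in% sp]
    }
    cci <- dia[, .(cci = compute_cci(icd10)), by = person_id]
    out <- merge(out, cci, by = "person_id", all.x = TRUE)
    out[is.na(cci), cci := 0L]
  }

  if (!is.null(purchases)) {
    pur <- as.data.table(purchases)[, date := as.Date(date)]
    other <- setdiff(medication_class_names(), cl)
    counts <- rep(0L, nrow(out))
    setkey(pur, person_id)
    pur <- pur[J(out$person_id), nomatch = 0L]
    fp <- out[, .(person_id, first_purchase_date)]
    pur <- merge(pur, fp, by = "person_id")
    pur <- pur[abs(as.numeric(date - first_purchase_date)) <=
                 polytherapy_window_days]
    for (ocl in other) {
      pf <- atc_classes(ocl)
      hit <- Reduce(`|`, lapply(pf, function(p)
        startsWith(as.character(pur$atc), p)))
      ids <- unique(pur$person_id[hit])
      counts <- counts + as.integer(out$person_id %in% ids)
    }
    out[, n_concurrent_treatments := counts]
  } else out[, n_concurrent_treatments := 0L]

  keep <- c("person_id", "medication_class", "sex", "age_at_init",
            "year_of_birth", "secondary_prevention", "cci",
            "education_years", "urban", "language_fi_sv",
            "social_assistance", "n_concurrent_treatments")
  keep <- intersect(keep, names(out))
  res <- as.data.frame(out[, ..keep])
  attr(res, "university_min_years") <- university_min_years
  res
}

#' Encode covariates for modelling
#'
#' Complete-case filter (persons with any missing covariate are dropped and
#' counted), then either `"dichotomized"` encoding — `age_gt_60` (strictly
#' greater than 60), `cci_gt_5` (strictly greater than 5),
#' `university_or_higher` (education years at or above the threshold recorded
#' by [derive_covariates()]) — or `"continuous"` encoding, where age, CCI and
#' education years are standardized within the analysis cohort (mean 0,
#' SD 1: `z_age`, `z_cci`, `z_education`). `year_of_birth` is always carried
#' through (it is the standing model adjustment). A `secondary_prevention`
#' column that is all-`NA` (class without a definition, or by-design constant
#' by cohort inclusion) is dropped rather than treated as missingness.
#'
#' @param covariates output of [derive_covariates()].
#' @param mode `"dichotomized"` or `"continuous"`.
#' @param university_min_years threshold for the education cutpoint; defaults
#'   to the value recorded on `covariates`.
#' @return `data.frame` with the encoded columns; attribute `"dropped"` holds
#'   the number of incomplete rows removed.
#' @export
encode_covariates <- function(covariates,
                              mode = c("dichotomized", "continuous"),
                              university_min_years =
                                attr(covariates, "university_min_years")) {
  mode <- match.arg(mode)
  if (is.null(university_min_years)) university_min_years <- 16
  dt <- as.data.table(covariates)
  if ("secondary_prevention" %in% names(dt) &&
      all(is.na(dt$secondary_prevention)))
    dt[, secondary_prevention := NULL]
  if ("secondary_prevention" %in% names(dt))
    dt[, secondary_prevention := as.integer(secondary_prevention)]
  if ("sex" %in% names(dt))
    dt[, sex_female := as.integer(tolower(substr(as.character(sex), 1, 1))
                                  == "f")][, sex := NULL]
  n_in <- nrow(dt)
  cc <- complete.cases(dt)
  dt <- dt[cc]
  if (nrow(dt) == 0L) stop("no complete-case rows")

  zstd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance column in standardization")
    (x - mean(x)) / s
  }
  if (mode == "dichotomized") {
    dt[, age_gt_60 := as.integer(age_at_init > 60)]
    dt[, cci_gt_5 := as.integer(cci > 5)]
    dt[, university_or_higher :=
         as.integer(education_years >= university_min_years)]
    dt[, c("age_at_init", "cci", "education_years") := NULL]
  } else {
    dt[, z_age := zstd(age_at_init)]
    dt[, z_cci := zstd(as.numeric(cci))]
    dt[, z_education := zstd(education_years)]
    dt[, c("age_at_init", "cci", "education_years") := NULL]
  }
  out <- as.data.frame(dt)
  attr(out, "dropped") <- n_in - nrow(out)
  attr(out, "mode") <- mode
  out
}
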