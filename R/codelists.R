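#' ATC code prefixes for the five medication classes
#'
#' Statins (C10AA), blood-pressure medications (antihypertensives, diuretics,
#' calcium-channel blockers, renin-angiotensin agents), antiplatelets
#' (clopidogrel, ASA+dipyridamole), direct oral anticoagulants, and breast
#' cancer endocrine therapy (tamoxifen and aromatase inhibitors). A purchase
#' belongs to a class when its ATC code starts with one of the class prefixes.
#'
#' @param medication_class optional class name; when given, returns that
#'   class's prefix vector instead of the full list.
#' @return A named list of character vectors of ATC prefixes, or one vector.
#' @examples
#' atc_classes("statins")
#' @export
atc_classes <- function(medication_class = NULL) {
  classes <- list(
    statins       = "C10AA",
    bp            = c("C02", "C03", "C08", "C09"),
    antiplatelets = c("B01AC04", "B01AC30"),
    doac          = c("B01AF01", "B01AF02", "B01AF03", "B01AE07"),
    breast_cancer = c("L02BA01", "L02BG03", "L02BG04", "L02BG06")
  )
  if (is.null(medication_class)) return(classes)
  if (!medication_class %in% names(classes))
    stop("unknown medication class: ", medication_class)
  classes[[medication_class]]
}

medication_class_names <- function() names(atc_classes())

# expand "I60-I69" style ranges to explicit 3-character prefixes
expand_icd_range <- function(from, to) {
  letter <- substr(from, 1, 1)
  sprintf("%s%02d", letter, seq(as.integer(substr(from, 2, 3)),
                                as.integer(substr(to, 2, 3))))
}

#' Secondary-prevention ICD-10 code lists
#'
#' Diagnosis codes defining a prior "major event related to the medication":
#' statins — major coronary heart disease (I20.0, I21, I22), cerebrovascular
#' disease (I60–I69), atherosclerosis (I70); antiplatelets — stroke (I60–I64),
#' transient ischaemic attack (G45), myocardial infarction (I21, I22); breast
#' cancer medications — breast cancer (C50); DOAC — atrial fibrillation (I48),
#' pulmonary embolism / venous thromboembolism (I26, I80, I87.1). Blood
#' pressure medications have no secondary-prevention definition (`NULL`): the
#' class is too broad for a single qualifying event.
#'
#' Ranges are expanded to explicit 3-character prefixes; a diagnosis matches
#' when its code starts with any listed prefix (decimal points ignored).
#'
#' @param medication_class one of `"statins"`, `"bp"`, `"antiplatelets"`,
#'   `"doac"`, `"breast_cancer"`; `NULL` returns the full list.
#' @return Character vector of ICD-10 prefixes (or `NULL` for `"bp"`), or the
#'   named list of all five.
#' @examples
#' medication_codelist("statins")
#' @export
medication_codelist <- function(medication_class = NULL) {
  lists <- list(
    statins       = c("I20.0", "I21", "I22",
                      expand_icd_range("I60", "I69"), "I70"),
    bp            = NULL,
    antiplatelets = c(expand_icd_range("I60", "I64"), "G45", "I21", "I22"),
    doac          = c("I48", "I26", "I80", "I87.1"),
    breast_cancer = "C50"
  )
  if (is.null(medication_class)) return(lists)
  if (!medication_class %in% names(lists))
    stop("unknown medication class: ", medication_class)
  lists[[medication_class]]
}

# TRUE where any code in `codes` starts with any prefix in `prefixes`;
# decimal points are stripped on both sides ("I87.1" matches "I871").
icd10_matches <- function(codes, prefixes) {
  if (is.null(prefixes) || !length(codes)) return(logical(length(codes)))
  codes <- gsub(".", "", toupper(codes), fixed = TRUE)
  prefixes <- gsub(".", "", toupper(prefixes), fixed = TRUE)
  out <- logical(length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
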