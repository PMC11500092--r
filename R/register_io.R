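# Register files: UTF-8 CSV with ISO-8601 dates.
register_schema <- function() {
  list(
    purchase = list(file = "purchase.csv",
                    cols = c(person_id = "character", date = "Date",
                             atc = "character", n_packages = "integer",
                             tablets_per_package = "integer",
                             dose_distribution = "integer"),
                    date_cols = "date"),
    diagnosis = list(file = "diagnosis.csv",
                     cols = c(person_id = "character", date = "Date",
                              icd10 = "character"),
                     date_cols = "date"),
    person = list(file = "person.csv",
                  cols = c(person_id = "character", sex = "character",
                           birth_date = "Date", death_date = "Date",
                           emigration_date = "Date",
                           language_fi_sv = "integer",
                           education_years = "numeric",
                           social_assistance = "integer",
                           urban = "integer"),
                  date_cols = c("birth_date", "death_date",
                                "emigration_date"))
  )
}

#' Write register tables to a directory
#'
#' Writes `purchase.csv`, `diagnosis.csv` and `person.csv` (plus
#' `groundtruth.csv` for simulated cohorts) as UTF-8 CSV with ISO-8601 dates.
#' Columns are validated against the register schema; negative quantities are
#' rejected. [read_register()] round-trips the files to identical tables
#' (dates at day precision).
#'
#' @param tables a named list with `purchases`, `diagnoses`, `persons`
#'   (e.g. a [simulate_cohort()] result; `groundtruth` is written when
#'   present).
#' @param directory output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_register <- function(tables, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  schema <- register_schema()
  spec <- list(purchases = schema$purchase, diagnoses = schema$diagnosis,
               persons = schema$person)
  paths <- character()
  for (nm in names(spec)) {
    tab <- tables[[nm]]
    if (is.null(tab)) stop("missing table: ", nm)
    need <- names(spec[[nm]]$cols)
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("table '", nm, "' missing required column(s): ",
           paste(miss, collapse = ", "))
    if (nm == "purchases" && nrow(tab) &&
        (any(tab$n_packages < 0, na.rm = TRUE) ||
         any(tab$tablets_per_package < 0, na.rm = TRUE)))
      stop("negative quantities in purchase table")
    dt <- as.data.table(tab)[, ..need]
    for (dc in spec[[nm]]$date_cols) dt[[dc]] <- as.Date(dt[[dc]])
    p <- file.path(directory, spec[[nm]]$file)
    fwrite(dt, p, dateTimeAs = "ISO")
    paths <- c(paths, p)
  }
  if (!is.null(tables$groundtruth)) {
    p <- file.path(directory, "groundtruth.csv")
    fwrite(as.data.table(tables$groundtruth), p, dateTimeAs = "ISO")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read register tables from a directory
#'
#' Inverse of [write_register()]; enforces the register schema (required
#' columns, parseable ISO dates, non-negative quantities).
#'
#' @param directory directory holding `purchase.csv`, `diagnosis.csv`,
#'   `person.csv` (and optionally `groundtruth.csv`).
#' @return A list with `purchases`, `diagnoses`, `persons` (and
#'   `groundtruth` when present) as `data.frame`s.
#' @export
read_register <- function(directory) {
  schema <- register_schema()
  out <- list()
  for (nm in names(schema)) {
    p <- file.path(directory, schema[[nm]]$file)
    if (!file.exists(p)) stop("missing register file: ", p)
    cls <- schema[[nm]]$cols
    dt <- fread(p, colClasses = cls, na.strings = c("", "NA"))
    miss <- setdiff(names(cls), names(dt))
    if (length(miss))
      stop("file '", p, "' missing required column(s): ",
           paste(miss, collapse = ", "))
    for (dc in schema[[nm]]$date_cols) {
      d <- as.Date(dt[[dc]])
      if (any(is.na(d) & !is.na(dt[[dc]]) & nzchar(as.character(dt[[dc]]))))
        stop("unparseable date in ", p, " column ", dc)
      dt[[dc]] <- d
    }
    out[[nm]] <- as.data.frame(dt)
  }
  names(out) <- c("purchases", "diagnoses", "persons")
  if (nrow(out$purchases) &&
      (any(out$purchases$n_packages < 0, na.rm = TRUE) ||
       any(out$purchases$tablets_per_package < 0, na.rm = TRUE)))
    stop("negative quantities in purchase table")
  gt <- file.path(directory, "groundtruth.csv")
  if (file.exists(gt)) {
    g <- fread(gt)
    for (dc in intersect(c("first_purchase_date", "end_of_followup"),
                         names(g)))
      g[[dc]] <- as.Date(g[[dc]])
    out$groundtruth <- as.data.frame(g)
  }
  out
}
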