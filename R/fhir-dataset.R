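#' In-memory FHIR dataset
#'
#' Container for the minimal FHIR R4 subset the quality checks inspect:
#' Patient, Condition and Specimen resources, plus an explicit reference date
#' used by all "now"-relative checks (timeliness, future birth dates). The
#' reference date is always an explicit input, never the wall clock, so that
#' reports are reproducible.
#'
#' Records are kept verbatim as read: gender tokens and codes are not
#' normalised, duplicate ids are retained (uniqueness is a check, not a
#' cleaning step), and optional fields are `NA` when absent.
#'
#' @param patients Tibble with columns `id`, `gender`, `birth_date`,
#'   `deceased`, `last_updated`. Dates and instants are ISO-8601 strings;
#'   partial dates (`"1975"`, `"1975-03"`) are permitted.
#' @param conditions Tibble with columns `id`, `patient_ref`, `code`,
#'   `coding_system`. `patient_ref` stores the bare patient id.
#' @param specimens Tibble with columns `id`, `patient_ref`, `type_code`,
#'   `collected`.
#' @param reference_date A `Date`; the evaluation date for relative checks.
#'
#' @return An object of class `fhir_dataset`.
#' @export
fhir_dataset <- function(patients = empty_patients(),
                         conditions = empty_conditions(),
                         specimens = empty_specimens(),
                         reference_date) {
  stopifnot(inherits(reference_date <- as.Date(reference_date), "Date"))
  ds <- structure(
    list(
      patients = tibble::as_tibble(patients),
      conditions = tibble::as_tibble(conditions),
      specimens = tibble::as_tibble(specimens),
      reference_date = reference_date
    ),
    class = "fhir_dataset"
  )
  validate_fhir_dataset(ds)
  ds
}

empty_patients <- function() {
  tibble::tibble(id = character(), gender = character(),
                 birth_date = character(), deceased = logical(),
                 last_updated = character())
}

empty_conditions <- function() {
  tibble::tibble(id = character(), patient_ref = character(),
                 code = character(), coding_system = character())
}

empty_specimens <- function() {
  tibble::tibble(id = character(), patient_ref = character(),
                 type_code = character(), collected = character())
}

validate_fhir_dataset <- function(ds) {
  p <- ds$patients
  req <- c("id", "gender", "birth_date", "deceased", "last_updated")
  if (!all(req %in% names(p))) {
    stop("patients must have columns: ", paste(req, collapse = ", "))
  }
  if (any(is.na(p$id) | !nzchar(p$id))) {
    stop("every patient in a dataset must carry a non-empty id")
  }
  if (!all(c("id", "patient_ref", "code", "coding_system") %in%
           names(ds$conditions))) {
    stop("conditions must have columns: id, patient_ref, code, coding_system")
  }
  if (!all(c("id", "patient_ref", "type_code", "collected") %in%
           names(ds$specimens))) {
    stop("specimens must have columns: id, patient_ref, type_code, collected")
  }
  lu <- ds$patients$last_updated
  bad <- !is.na(lu) & nzchar(lu) & is.na(parse_fhir_instant(lu))
  if (any(bad)) {
    stop("last_updated values must parse as ISO-8601 instants; offending: ",
         paste(utils::head(lu[bad], 3), collapse = ", "))
  }
  invisible(ds)
}

#' @export
print.fhir_dataset <- function(x, ...) {
  cat("<fhir_dataset>\n")
  cat("  patients:  ", nrow(x$patients),
      " (", length(unique(x$patients$id)), " distinct ids)\n", sep = "")
  cat("  conditions:", nrow(x$conditions), "\n")
  cat("  specimens: ", nrow(x$specimens), "\n")
  cat("  reference date:", format(x$reference_date), "\n")
  invisible(x)
}

#' Referential-integrity report for a dataset
#'
#' Lists every Condition or Specimen whose `patient_ref` resolves to no
#' patient id in the dataset. Reporting, not raising: an empty result means
#' the dataset is referentially consistent.
#'
#' @param dataset A [fhir_dataset()].
#' @return Tibble with columns `resource_type`, `id`, `patient_ref`; zero rows
#'   when all references resolve.
#' @export
validate_references <- function(dataset) {
  ids <- unique(dataset$patients$id)
  dangling <- function(tbl, type) {
    bad <- !(tbl$patient_ref %in% ids) | is.na(tbl$patient_ref)
    tibble::tibble(resource_type = rep(type, sum(bad)),
                   id = tbl$id[bad], patient_ref = tbl$patient_ref[bad])
  }
  dplyr::bind_rows(dangling(dataset$conditions, "Condition"),
                   dangling(dataset$specimens, "Specimen"))
}
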