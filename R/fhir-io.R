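#' Read a FHIR R4 file into a dataset
#'
#' Parses a JSON Bundle (type "collection") or an NDJSON export (one resource
#' per line) and returns every Patient, Condition and Specimen resource in
#' file order. Unknown resource types are skipped with a message reporting the
#' count. Duplicate ids are preserved: uniqueness is one of the quality checks
#' and must see the raw records. No value is normalised at read time — checks
#' see the raw gender tokens and codes.
#'
#' Field mapping (FHIR R4): `Patient.gender`, `Patient.birthDate`,
#' `Patient.deceasedBoolean` (a `deceasedDateTime` maps to `deceased = TRUE`),
#' `meta.lastUpdated`, `Condition.code.coding[0].code` with its `system`,
#' `subject.reference` of the form `"Patient/<id>"` (a bare id is accepted;
#' the bare id is stored).
#'
#' @param path Path to the file.
#' @param format `"bundle"` or `"ndjson"`.
#' @param reference_date A `Date` used by "now"-relative checks.
#' @return A [fhir_dataset()].
#' @export
read_dataset <- function(path, format = c("bundle", "ndjson"), reference_date) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  resources <- if (format == "bundle") {
    bundle <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                       error = function(e) stop("unparsable bundle: ",
                                                conditionMessage(e)))
    lapply(bundle$entry %||% list(), function(e) e$resource)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
               error = function(e) stop("unparsable NDJSON line: ",
                                        conditionMessage(e)))
    })
  }
  resources_to_dataset(resources, reference_date)
}

resources_to_dataset <- function(resources, reference_date) {
  patients <- list(); conditions <- list(); specimens <- list()
  skipped <- 0L
  for (i in seq_along(resources)) {
    res <- resources[[i]]
    rt <- res$resourceType
    if (is.null(rt)) stop("resource at index ", i, " has no resourceType")
    if (rt == "Patient") {
      patients[[length(patients) + 1L]] <- parse_patient(res)
    } else if (rt == "Condition") {
      conditions[[length(conditions) + 1L]] <- parse_condition(res)
    } else if (rt == "Specimen") {
      specimens[[length(specimens) + 1L]] <- parse_specimen(res)
    } else {
      skipped <- skipped + 1L
    }
  }
  if (skipped > 0L) {
    message("skipped ", skipped, " resource(s) of unhandled types")
  }
  fhir_dataset(
    patients = if (length(patients)) dplyr::bind_rows(patients) else empty_patients(),
    conditions = if (length(conditions)) dplyr::bind_rows(conditions) else empty_conditions(),
    specimens = if (length(specimens)) dplyr::bind_rows(specimens) else empty_specimens(),
    reference_date = reference_date
  )
}

parse_patient <- function(res) {
  deceased <- if (!is.null(res$deceasedBoolean)) {
    json_lgl(res$deceasedBoolean)
  } else if (!is.null(res$deceasedDateTime)) TRUE else NA
  tibble::tibble(
    id = json_chr(res$id),
    gender = json_chr(res$gender),
    birth_date = json_chr(res$birthDate),
    deceased = deceased,
    last_updated = json_chr(res$meta$lastUpdated)
  )
}

strip_patient_prefix <- function(ref) {
  if (is.na(ref)) return(NA_character_)
  sub("^Patient/", "", ref)
}

parse_condition <- function(res) {
  coding <- res$code$coding
  first <- if (length(coding)) coding[[1]] else NULL
  tibble::tibble(
    id = json_chr(res$id),
    patient_ref = strip_patient_prefix(json_chr(res$subject$reference)),
    code = json_chr(first$code),
    coding_system = json_chr(first$system)
  )
}

parse_specimen <- function(res) {
  coding <- res$type$coding
  first <- if (length(coding)) coding[[1]] else NULL
  tibble::tibble(
    id = json_chr(res$id),
    patient_ref = strip_patient_prefix(json_chr(res$subject$reference)),
    type_code = json_chr(first$code),
    collected = json_chr(res$collection$collectedDateTime)
  )
}

#' Write a dataset back to FHIR R4 JSON
#'
#' Inverse of [read_dataset()]: emits a Bundle (type "collection") or NDJSON.
#' Absent optional fields are omitted from the output, never emitted as null,
#' so a read/write cycle reproduces the dataset field for field.
#'
#' @param dataset A [fhir_dataset()].
#' @param path Output path.
#' @param format `"bundle"` or `"ndjson"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("bundle", "ndjson")) {
  format <- match.arg(format)
  resources <- c(
    lapply(seq_len(nrow(dataset$patients)),
           function(i) patient_resource(dataset$patients[i, ])),
    lapply(seq_len(nrow(dataset$conditions)),
           function(i) condition_resource(dataset$conditions[i, ])),
    lapply(seq_len(nrow(dataset$specimens)),
           function(i) specimen_resource(dataset$specimens[i, ]))
  )
  ok <- tryCatch({
    if (format == "bundle") {
      bundle <- list(resourceType = "Bundle", type = "collection",
                     entry = lapply(resources, function(r) list(resource = r)))
      writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA),
                 path)
    } else {
      writeLines(vapply(resources, function(r) {
        as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
      }, character(1)), path)
    }
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

drop_absent <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                       (length(v) == 1 && is.na(v)), logical(1))]

patient_resource <- function(row) {
  drop_absent(list(
    resourceType = "Patient",
    id = row$id,
    meta = if (!is.na(row$last_updated)) list(lastUpdated = row$last_updated),
    gender = row$gender,
    birthDate = row$birth_date,
    deceasedBoolean = row$deceased
  ))
}

condition_resource <- function(row) {
  coding <- drop_absent(list(system = row$coding_system, code = row$code))
  drop_absent(list(
    resourceType = "Condition",
    id = row$id,
    code = if (length(coding)) list(coding = list(coding)),
    subject = if (!is.na(row$patient_ref))
      list(reference = paste0("Patient/", row$patient_ref))
  ))
}

specimen_resource <- function(row) {
  drop_absent(list(
    resourceType = "Specimen",
    id = row$id,
    type = if (!is.na(row$type_code))
      list(coding = list(list(code = row$type_code))),
    subject = if (!is.na(row$patient_ref))
      list(reference = paste0("Patient/", row$patient_ref)),
    collection = if (!is.na(row$collected))
      list(collectedDateTime = row$collected)
  ))
}
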