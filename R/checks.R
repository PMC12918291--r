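#' Quality check definitions and execution
#'
#' A check is a pure counting query over a dataset: it returns a numerator
#' (records failing, or for rate-style checks satisfying, the predicate), a
#' denominator (the population the check is computed over) and the raw
#' percentage. No randomness is involved at this stage; privacy protection is
#' applied downstream by the Laplace mechanism.
#'
#' @param check_id Canonical identifier, e.g. `"completeness-1"`.
#' @param dimension One of the six implemented quality dimensions.
#' @param description Human-readable description.
#' @param counter Function `(dataset, stratum)` returning
#'   `list(numerator =, denominator =)`.
#' @param sensitivity Query sensitivity Δf: the maximum change one
#'   individual's record causes in the numerator. 1 for patient-level counts.
#' @param strata Optional character vector of stratum labels.
#' @param warn_threshold,error_threshold Status thresholds in percent;
#'   `warn_threshold <= error_threshold`.
#' @param alias Optional alternate id (used to keep legacy spellings such as
#'   `"completness-1"` resolvable).
#' @return An object of class `check_definition`.
#' @export
check_definition <- function(check_id, dimension, description, counter,
                             sensitivity = 1L, strata = NULL,
                             warn_threshold = 10, error_threshold = 30,
                             alias = NULL) {
  dimension <- match.arg(dimension, quality_dimensions())
  stopifnot(is.function(counter), sensitivity >= 1)
  if (warn_threshold > error_threshold) {
    stop("warn_threshold must not exceed error_threshold")
  }
  structure(
    list(check_id = check_id, dimension = dimension,
         description = description, counter = counter,
         sensitivity = as.integer(sensitivity), strata = strata,
         warn_threshold = warn_threshold, error_threshold = error_threshold,
         alias = alias),
    class = "check_definition"
  )
}

#' @export
print.check_definition <- function(x, ...) {
  cat("<check_definition> ", x$check_id, " [", x$dimension, "]\n", sep = "")
  cat("  ", x$description, "\n", sep = "")
  if (!is.null(x$strata)) cat("  strata:", paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname check_definition
#' @export
quality_dimensions <- function() {
  c("accuracy", "completeness", "consistency", "timeliness", "validity",
    "uniqueness")
}

#' Supported FHIR administrative gender tokens
#' @return Character vector `c("male", "female", "other", "unknown")`.
#' @export
supported_genders <- function() c("male", "female", "other", "unknown")

# A record's gender is "missing" when absent or empty-string; a present,
# non-empty token outside the AdministrativeGender value set is "unsupported".
# The two numerators are disjoint by construction.
gender_missing <- function(gender) is.na(gender) | !nzchar(gender)
gender_unsupported <- function(gender) {
  !gender_missing(gender) & !(gender %in% supported_genders())
}

#' The built-in check catalogue
#'
#' Returns the nine predefined patient-level checks spanning the six
#' implemented quality dimensions. All have sensitivity Δf = 1 (each patient
#' contributes at most once to each numerator). Denominators are total patient
#' records — duplicates included — except `validity-1`, whose population is
#' patients with at least one linked condition (a patient without conditions
#' cannot carry an invalid code, and the two completeness/validity rates are
#' only jointly coherent over that population), and the stratified `accuracy-3`.
#'
#' * `accuracy-1` — gender-incompatible diagnosis (e.g. prostate cancer
#'   recorded for a female patient)
#' * `accuracy-2` — birth date before 1900 or after the reference date
#' * `completeness-1` — missing gender (absent or empty token)
#' * `completeness-2` — no linked Condition resource
#' * `consistency-1` — gender token outside the supported value set
#' * `timeliness-1` — last updated more than `timeliness_days` before the
#'   reference date (records without provenance count as stale)
#' * `validity-1` — any linked Condition code failing structural ICD-10
#'   validity, among patients with conditions
#' * `uniqueness-1` — surplus records sharing an id (total minus distinct)
#' * `accuracy-3` — survival rate (deceased not true), stratified by gender
#'
#' @param incompatibility Incompatibility table as in
#'   [default_incompatibility_table()].
#' @param icd10_codes Optional character vector switching `validity-1` from
#'   structural validation to terminology membership.
#' @param timeliness_days Staleness window in days (default 365).
#' @param warn_threshold,error_threshold Default status thresholds in percent.
#' @return List of [check_definition()] objects, in catalogue order.
#' @export
builtin_checks <- function(incompatibility = default_incompatibility_table(),
                           icd10_codes = NULL, timeliness_days = 365,
                           warn_threshold = 10, error_threshold = 30) {
  def <- function(...) {
    check_definition(..., warn_threshold = warn_threshold,
                     error_threshold = error_threshold)
  }
  all_patients <- function(ds) nrow(ds$patients)
  count_patients <- function(flag_fn) {
    function(ds, stratum) {
      list(numerator = sum(flag_fn(ds)), denominator = all_patients(ds))
    }
  }
  list(
    def("accuracy-1", "accuracy",
        "How many patients have an incompatible Diagnosis (e.g. Prostate Cancer for Female)",
        count_patients(function(ds) incompatible_diagnosis_flags(ds, incompatibility))),
    def("accuracy-2", "accuracy",
        "Date of Birth before 1900 or in the future",
        count_patients(function(ds) {
          bd <- parse_fhir_date(ds$patients$birth_date)
          !is.na(bd) & (bd < as.Date("1900-01-01") | bd > ds$reference_date)
        })),
    def("completeness-1", "completeness",
        "How many patients have missing gender info",
        count_patients(function(ds) gender_missing(ds$patients$gender)),
        alias = "completness-1"),
    def("completeness-2", "completeness",
        "How many patients do not have a condition",
        count_patients(function(ds) {
          !(ds$patients$id %in% ds$conditions$patient_ref)
        }),
        alias = "completness-2"),
    def("consistency-1", "consistency",
        "How many patients do not have a supported gender value",
        count_patients(function(ds) gender_unsupported(ds$patients$gender))),
    def("timeliness-1", "timeliness",
        "How many patients were last updated more than a year ago",
        count_patients(function(ds) {
          lu <- parse_fhir_instant(ds$patients$last_updated)
          cutoff <- as.POSIXct(ds$reference_date, tz = "UTC") -
            as.difftime(timeliness_days, units = "days")
          is.na(lu) | lu < cutoff
        })),
    def("validity-1", "validity",
        "How many patients have conditions with invalid ICD-10 codes",
        function(ds, stratum) {
          has_invalid <- tapply(!icd10_valid(ds$conditions$code, icd10_codes),
                                ds$conditions$patient_ref, any)
          with_cond <- ds$patients$id %in% ds$conditions$patient_ref
          list(
            numerator = sum(unlist(has_invalid[ds$patients$id[with_cond]])),
            denominator = sum(with_cond)
          )
        }),
    def("uniqueness-1", "uniqueness",
        "How many patients are duplicated in the dataset based on IDs",
        function(ds, stratum) {
          list(numerator = nrow(ds$patients) - length(unique(ds$patients$id)),
               denominator = nrow(ds$patients))
        },
        alias = "uniqness-1"),
    def("accuracy-3", "accuracy", "Survival rate",
        function(ds, stratum) {
          in_stratum <- !is.na(ds$patients$gender) &
            ds$patients$gender == stratum
          alive <- is.na(ds$patients$deceased) | !ds$patients$deceased
          list(numerator = sum(in_stratum & alive),
               denominator = sum(in_stratum))
        },
        strata = c("female", "male"))
  )
}

incompatible_diagnosis_flags <- function(ds, incompatibility) {
  roots <- substr(ds$conditions$code, 1, 3)
  required <- incompatibility$required_gender[match(roots, incompatibility$root)]
  g <- ds$patients$gender
  known <- !gender_missing(g) & g %in% c("male", "female")
  flags <- logical(nrow(ds$patients))
  for (i in which(!is.na(required))) {
    pid <- ds$conditions$patient_ref[i]
    hit <- which(ds$patients$id == pid & known & g != required[i])
    flags[hit] <- TRUE
  }
  flags
}

#' Execute one check
#'
#' Pure counting: deterministic, no noise. Stratified definitions yield one
#' result row per stratum; unstratified ones a single row.
#'
#' @param definition A [check_definition()].
#' @param dataset A [fhir_dataset()].
#' @return Tibble with columns `check_id`, `dimension`, `description`,
#'   `stratum`, `numerator`, `denominator`, `raw_percent`.
#' @export
run_check <- function(definition, dataset) {
  strata <- definition$strata
  if (is.null(strata)) strata <- list(NULL)
  rows <- lapply(strata, function(s) {
    counts <- definition$counter(dataset, s)
    if (counts$denominator <= 0) {
      stop("insufficient population for check ", definition$check_id,
           if (!is.null(s)) paste0(" (stratum ", s, ")"),
           ": empty denominator", call. = FALSE)
    }
    desc <- definition$description
    if (!is.null(s)) desc <- paste0(desc, " for ", s, " patients")
    tibble::tibble(
      check_id = definition$check_id,
      dimension = definition$dimension,
      description = desc,
      stratum = if (is.null(s)) NA_character_ else s,
      numerator = as.integer(counts$numerator),
      denominator = as.integer(counts$denominator),
      raw_percent = round(100 * counts$numerator / counts$denominator, 2)
    )
  })
  dplyr::bind_rows(rows)
}

#' Execute a battery of checks
#'
#' Runs the definitions in order. A failure of an individual check (for
#' example an empty denominator population) is captured in that check's row —
#' it does not abort the battery.
#'
#' @param definitions List of [check_definition()] objects.
#' @param dataset A [fhir_dataset()].
#' @return Tibble as in [run_check()] plus an `error` column, `NA` for
#'   successful checks.
#' @export
run_battery <- function(definitions, dataset) {
  stopifnot(length(definitions) > 0)
  rows <- lapply(definitions, function(def) {
    tryCatch(
      dplyr::mutate(run_check(def, dataset), error = NA_character_),
      error = function(e) tibble::tibble(
        check_id = def$check_id, dimension = def$dimension,
        description = def$description, stratum = NA_character_,
        numerator = NA_integer_, denominator = NA_integer_,
        raw_percent = NA_real_, error = conditionMessage(e)
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Register a custom check
#'
#' Extends a registry of definitions; the built-in catalogue is never
#' modified in place. Ids (including aliases) must be unique.
#'
#' @param definition A [check_definition()].
#' @param registry List of existing definitions (default the built-ins).
#' @return The extended registry.
#' @export
register_check <- function(definition, registry = builtin_checks()) {
  known <- unlist(lapply(registry, function(d) c(d$check_id, d$alias)))
  if (definition$check_id %in% known ||
      (!is.null(definition$alias) && definition$alias %in% known)) {
    stop("check id already registered: ", definition$check_id)
  }
  c(registry, list(definition))
}

#' Sample-level query sensitivity
#'
#' For checks counting records at sample rather than patient granularity, the
#' sensitivity Δf must equal the largest number of specimens any single
#' patient contributes, so that removing one patient still changes the count
#' by at most Δf.
#'
#' @param dataset A [fhir_dataset()].
#' @return Integer Δf (at least 1).
#' @export
sample_sensitivity <- function(dataset) {
  if (nrow(dataset$specimens) == 0) return(1L)
  max(1L, max(table(dataset$specimens$patient_ref)))
}
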