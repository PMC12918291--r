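#' Error-injection profile for synthetic cohorts
#'
#' Per-patient probabilities for each class of purposefully injected data
#' quality error, plus the survival rate per gender stratum. Every rate must
#' lie in [0, 1].
#'
#' @param rate_missing_gender Gender element absent.
#' @param rate_unsupported_gender Gender token outside the supported set
#'   (drawn from a fixed pool such as `"F"`, `"MALE"`, `"x"`). When a patient
#'   draws both a missing and an unsupported gender, missing takes precedence
#'   (a record cannot exhibit both); only materialised errors are counted.
#' @param rate_missing_condition No Condition resource linked.
#' @param rate_invalid_icd10 Condition code failing structural ICD-10
#'   validity, among patients that have conditions.
#' @param rate_duplicate_id Fraction of clone records appended re-using an
#'   existing id; `ceiling(rate * n_patients)` clones are added after the
#'   base population.
#' @param rate_dob_anomaly Birth date before 1900 (half of the injected
#'   anomalies) or after the reference date (the other half).
#' @param rate_incompatible_diagnosis Gender-incompatible diagnosis code
#'   (male-only code for a female patient or vice versa), materialised only
#'   for patients with a supported binary gender.
#' @param rate_stale_update `meta.lastUpdated` set 400 days before the
#'   reference date; fresh records get 30 days before.
#' @param survival_rate_by_gender Named probabilities of `deceased != TRUE`
#'   per gender stratum.
#' @return Object of class `error_profile`.
#' @export
error_profile <- function(rate_missing_gender = 0,
                          rate_unsupported_gender = 0,
                          rate_missing_condition = 0,
                          rate_invalid_icd10 = 0,
                          rate_duplicate_id = 0,
                          rate_dob_anomaly = 0,
                          rate_incompatible_diagnosis = 0,
                          rate_stale_update = 0,
                          survival_rate_by_gender = c(female = 0.5,
                                                      male = 0.5)) {
  profile <- list(
    rate_missing_gender = rate_missing_gender,
    rate_unsupported_gender = rate_unsupported_gender,
    rate_missing_condition = rate_missing_condition,
    rate_invalid_icd10 = rate_invalid_icd10,
    rate_duplicate_id = rate_duplicate_id,
    rate_dob_anomaly = rate_dob_anomaly,
    rate_incompatible_diagnosis = rate_incompatible_diagnosis,
    rate_stale_update = rate_stale_update,
    survival_rate_by_gender = survival_rate_by_gender
  )
  rates <- c(unlist(profile[1:8]), survival_rate_by_gender)
  if (any(!is.finite(rates) | rates < 0 | rates > 1)) {
    stop("every profile rate must lie in [0, 1]")
  }
  if (!all(names(survival_rate_by_gender) %in% supported_genders())) {
    stop("survival strata must be supported gender tokens")
  }
  structure(profile, class = "error_profile")
}

#' Default error profile
#'
#' The rates the built-in checks are exercised against by default: each
#' error class at the raw prevalence observed in the reference quality-check
#' battery over the 1,000-patient synthetic evaluation cohort (missing gender
#' 3.7%, no condition 20%, unsupported gender 9.6%, duplicate ids 9.7%,
#' invalid ICD-10 codes 96.9% of condition-bearing patients, incompatible
#' diagnosis 0.1%, birth-date anomalies 5.6%, stale updates 0%), with
#' survival rates of 27.6% (female) and 30.9% (male).
#'
#' @return An [error_profile()].
#' @export
default_profile <- function() {
  error_profile(
    rate_missing_gender = 0.037,
    rate_unsupported_gender = 0.096,
    rate_missing_condition = 0.200,
    rate_invalid_icd10 = 0.969,
    rate_duplicate_id = 0.097,
    rate_dob_anomaly = 0.056,
    rate_incompatible_diagnosis = 0.001,
    rate_stale_update = 0.0,
    survival_rate_by_gender = c(female = 0.276, male = 0.309)
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of base patient records (at least 1); duplicate
#'   clones are appended on top of these.
#' @param n_specimens Total specimens, distributed multinomially over the
#'   base patients (enables sensitivities Δf > 1 for sample-level queries).
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @param profile An [error_profile()].
#' @param reference_date Evaluation date for "now"-relative fields.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_specimens = 0, seed = 1,
                        profile = default_profile(),
                        reference_date = as.Date("2025-01-01")) {
  stopifnot(n_patients >= 1, n_specimens >= 0,
            inherits(profile, "error_profile"))
  structure(list(n_patients = as.integer(n_patients),
                 n_specimens = as.integer(n_specimens),
                 seed = as.integer(seed), profile = profile,
                 reference_date = as.Date(reference_date)),
            class = "cohort_spec")
}

unsupported_gender_pool <- function() c("F", "M", "MALE", "FEMALE", "w", "x")

random_invalid_icd10 <- function(n) {
  # deliberately loose pattern: letter + three digits + lowercase suffix,
  # guaranteed to fail structural validation. The letter C is excluded so a
  # malformed code can never collide with a gender-specific C5x/C6x root and
  # leak into the incompatible-diagnosis numerator.
  paste0(sample(setdiff(LETTERS, "C"), n, replace = TRUE),
         sprintf("%03d", sample.int(1000, n, replace = TRUE) - 1L),
         sample(letters, n, replace = TRUE))
}

#' Generate a synthetic FHIR cohort with injected quality errors
#'
#' Deterministic given the spec's seed. Draws happen in a documented fixed
#' order, class by class over patients: base gender, deceased flag, missing
#' gender, unsupported gender, missing condition, invalid ICD-10, incompatible
#' diagnosis, birth dates, stale updates, duplicate clones, specimens. Each
#' error class is drawn independently per patient at its profile rate, so a
#' patient may carry several; where two classes cannot coexist on one record
#' (missing vs unsupported gender; a condition-level error on a patient
#' without conditions) the materialised subset is recorded, and
#' [describe_cohort()] reports exactly those materialised counts.
#'
#' Duplicate injection appends `ceiling(rate * n_patients)` clone records
#' (field-for-field copies re-using an existing id) after the base
#' population; linked conditions attach to the shared id, so clones mirror
#' their original in every check.
#'
#' @param spec A [cohort_spec()].
#' @return A [fhir_dataset()] carrying an `injection` attribute (one row of
#'   materialised error flags per patient record) consumed by
#'   [describe_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$profile
  n <- spec$n_patients
  ref <- spec$reference_date
  set.seed(spec$seed)

  strata <- names(p$survival_rate_by_gender)
  base_gender <- sample(strata, n, replace = TRUE)
  deceased <- unname(stats::runif(n) >= p$survival_rate_by_gender[base_gender])

  flag_missing_gender <- stats::runif(n) < p$rate_missing_gender
  flag_unsupported <- (stats::runif(n) < p$rate_unsupported_gender) &
    !flag_missing_gender
  unsupported_token <- sample(unsupported_gender_pool(), n, replace = TRUE)

  flag_missing_condition <- stats::runif(n) < p$rate_missing_condition
  flag_invalid <- (stats::runif(n) < p$rate_invalid_icd10) &
    !flag_missing_condition
  flag_incompatible <- (stats::runif(n) < p$rate_incompatible_diagnosis) &
    !flag_missing_condition & !flag_missing_gender & !flag_unsupported &
    base_gender %in% c("female", "male")

  flag_dob <- stats::runif(n) < p$rate_dob_anomaly
  dob <- ref - 1 - floor(stats::runif(n) * as.numeric(ref - as.Date("1900-01-01")) * 0.9)
  idx_dob <- which(flag_dob)
  if (length(idx_dob)) {
    pre <- idx_dob[seq_along(idx_dob) %% 2 == 1]  # half before 1900
    post <- setdiff(idx_dob, pre)                 # half after reference date
    dob[pre] <- as.Date("1850-01-01") +
      floor(stats::runif(length(pre)) * as.numeric(as.Date("1899-12-31") - as.Date("1850-01-01")))
    dob[post] <- ref + 1 + floor(stats::runif(length(post)) * 1000)
  }

  flag_stale <- stats::runif(n) < p$rate_stale_update
  last_updated <- ifelse(flag_stale,
                         paste0(format(ref - 400), "T00:00:00Z"),
                         paste0(format(ref - 30), "T00:00:00Z"))

  gender <- base_gender
  gender[flag_unsupported] <- unsupported_token[flag_unsupported]
  gender[flag_missing_gender] <- NA_character_

  ids <- sprintf("P%05d", seq_len(n))
  patients <- tibble::tibble(
    id = ids, gender = gender, birth_date = format(dob),
    deceased = ifelse(deceased, TRUE, NA),
    last_updated = last_updated
  )

  # conditions: one primary per condition-bearing patient, plus an extra
  # incompatible diagnosis where injected
  has_cond <- !flag_missing_condition
  n_cond <- sum(has_cond)
  primary_code <- character(n)
  valid_pool <- icd10_code_pool(neutral_only = TRUE)
  primary_code[has_cond] <- sample(valid_pool, n_cond, replace = TRUE)
  invalid_codes <- random_invalid_icd10(n)
  primary_code[flag_invalid] <- invalid_codes[flag_invalid]
  conditions <- tibble::tibble(
    id = sprintf("C%05d", seq_len(n_cond)),
    patient_ref = ids[has_cond],
    code = primary_code[has_cond],
    coding_system = "http://hl7.org/fhir/sid/icd-10"
  )
  idx_incomp <- which(flag_incompatible)
  if (length(idx_incomp)) {
    extra <- tibble::tibble(
      id = sprintf("CX%04d", seq_along(idx_incomp)),
      patient_ref = ids[idx_incomp],
      code = ifelse(base_gender[idx_incomp] == "female", "C61", "C56"),
      coding_system = "http://hl7.org/fhir/sid/icd-10"
    )
    conditions <- dplyr::bind_rows(conditions, extra)
  }

  flags <- tibble::tibble(
    missing_gender = flag_missing_gender,
    unsupported_gender = flag_unsupported,
    missing_condition = flag_missing_condition,
    invalid_icd10 = flag_invalid,
    incompatible_diagnosis = flag_incompatible,
    dob_anomaly = flag_dob,
    stale_update = flag_stale,
    is_duplicate = FALSE,
    gender = gender,
    deceased = deceased
  )

  n_dup <- if (p$rate_duplicate_id > 0) {
    as.integer(ceiling(p$rate_duplicate_id * n))
  } else 0L
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = TRUE)
    clones <- patients[src, ]
    patients <- dplyr::bind_rows(patients, clones)
    clone_flags <- flags[src, ]
    clone_flags$is_duplicate <- TRUE
    flags <- dplyr::bind_rows(flags, clone_flags)
  }

  specimens <- empty_specimens()
  if (spec$n_specimens > 0) {
    counts <- as.vector(stats::rmultinom(1, spec$n_specimens, rep(1, n)))
    owner <- rep(ids, counts)
    specimens <- tibble::tibble(
      id = sprintf("S%06d", seq_len(spec$n_specimens)),
      patient_ref = owner,
      type_code = sample(c("blood-plasma", "blood-serum", "tissue-ffpe",
                           "dna", "urine"),
                         spec$n_specimens, replace = TRUE),
      collected = format(ref - sample.int(3650, spec$n_specimens,
                                          replace = TRUE))
    )
  }

  ds <- fhir_dataset(patients = patients, conditions = conditions,
                     specimens = specimens, reference_date = ref)
  attr(ds, "injection") <- flags
  ds
}

#' Summarise the errors injected into a generated cohort
#'
#' Reports the exact materialised injected count per error class, over all
#' patient records (duplicate clones mirror their original and are counted).
#' These counts equal the corresponding check numerators by construction and
#' serve as the generator-vs-engine cross-validation oracle.
#'
#' @param dataset A dataset produced by [generate_cohort()].
#' @return Tibble with columns `error_class`, `count`, `denominator`.
#' @export
describe_cohort <- function(dataset) {
  flags <- attr(dataset, "injection")
  if (is.null(flags)) {
    stop("describe_cohort needs a dataset produced by generate_cohort()")
  }
  n_records <- nrow(flags)
  with_cond <- !flags$missing_condition
  strata <- sort(unique(flags$gender[flags$gender %in% c("female", "male")]))
  survival <- lapply(strata, function(s) {
    in_s <- !is.na(flags$gender) & flags$gender == s
    tibble::tibble(error_class = paste0("alive_", s),
                   count = sum(in_s & !flags$deceased),
                   denominator = sum(in_s))
  })
  dplyr::bind_rows(
    tibble::tibble(
      error_class = c("missing_gender", "unsupported_gender",
                      "missing_condition", "invalid_icd10",
                      "incompatible_diagnosis", "dob_anomaly",
                      "stale_update", "duplicate_records"),
      count = c(sum(flags$missing_gender), sum(flags$unsupported_gender),
                sum(flags$missing_condition), sum(flags$invalid_icd10),
                sum(flags$incompatible_diagnosis), sum(flags$dob_anomaly),
                sum(flags$stale_update), sum(flags$is_duplicate)),
      denominator = c(rep(n_records, 3), sum(with_cond), rep(n_records, 4))
    ),
    dplyr::bind_rows(survival)
  )
}

#' Deterministic reference cohort with fixed error counts
#'
#' A synthetic stand-in (not the deposited evaluation dataset) constructed so
#' that the built-in battery reproduces the reference raw values exactly over
#' 1,000 total patient records: 97 duplicate clones (903 distinct ids,
#' uniqueness 9.70%), 37 records with missing gender (3.70%), 96 with an
#' unsupported gender token (9.60%), 200 without conditions (20.00%), 775 of
#' the 800 condition-bearing records carrying an invalid ICD-10 code
#' (96.88%), 1 gender-incompatible diagnosis (0.10%), 56 birth-date anomalies
#' (5.60%) and no stale updates. Useful for validating check semantics
#' against known counts.
#'
#' @param reference_date Evaluation date.
#' @param seed RNG seed for the incidental attribute draws; the error counts
#'   above are fixed regardless of seed.
#' @return A [fhir_dataset()].
#' @export
synthetic_reference_cohort <- function(reference_date = as.Date("2025-01-01"),
                                       seed = 20250101) {
  ref <- as.Date(reference_date)
  set.seed(seed %% .Machine$integer.max)
  n_base <- 903L

  ids <- sprintf("R%05d", seq_len(n_base))
  gender <- sample(c("female", "male"), n_base, replace = TRUE)
  dob <- ref - sample.int(30000, n_base, replace = TRUE)  # all post-1900
  deceased <- ifelse(stats::runif(n_base) < 0.7, TRUE, NA)
  patients <- tibble::tibble(
    id = ids, gender = gender, birth_date = format(dob), deceased = deceased,
    last_updated = paste0(format(ref - 30), "T00:00:00Z")
  )

  # disjoint error blocks over base records:
  #   1..37    missing gender        38..133  unsupported gender
  #   134..189 birth-date anomaly    190      incompatible diagnosis
  #   704..903 no condition          ids 1..678 carry invalid primary codes
  #   191..287 clean rows cloned as duplicates (with conditions, invalid
  #            codes), giving 678 + 97 = 775 invalid of 800 condition records
  idx_missing <- 1:37
  idx_unsupported <- 38:133
  idx_dob <- 134:189
  idx_incomp <- 190L
  clone_src <- 191:287
  no_cond_idx <- 704:903
  n_invalid_ids <- 678L

  patients$gender[idx_missing] <- NA_character_
  patients$gender[idx_unsupported] <- sample(unsupported_gender_pool(),
                                             length(idx_unsupported),
                                             replace = TRUE)
  half <- length(idx_dob) %/% 2
  patients$birth_date[idx_dob[seq_len(half)]] <-
    format(as.Date("1850-01-01") +
             sample.int(18000, half, replace = TRUE))
  patients$birth_date[idx_dob[-seq_len(half)]] <-
    format(ref + sample.int(1000, length(idx_dob) - half, replace = TRUE))
  patients$gender[idx_incomp] <- "female"

  patients <- dplyr::bind_rows(patients, patients[clone_src, ])

  cond_idx <- setdiff(seq_len(n_base), no_cond_idx)
  cond_ids <- ids[cond_idx]
  codes <- c(random_invalid_icd10(n_invalid_ids),
             sample(icd10_code_pool(), length(cond_ids) - n_invalid_ids,
                    replace = TRUE))
  conditions <- tibble::tibble(
    id = sprintf("RC%05d", seq_along(cond_ids)),
    patient_ref = cond_ids,
    code = codes,
    coding_system = "http://hl7.org/fhir/sid/icd-10"
  )
  conditions <- dplyr::bind_rows(conditions, tibble::tibble(
    id = "RCX0001", patient_ref = ids[idx_incomp], code = "C61",
    coding_system = "http://hl7.org/fhir/sid/icd-10"
  ))
  fhir_dataset(patients = patients, conditions = conditions,
               specimens = empty_specimens(), reference_date = ref)
}
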