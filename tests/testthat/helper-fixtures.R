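# Small in-code fixtures shared across test files.

REF_DATE <- as.Date("2025-01-01")

patient_row <- function(id, gender = "female", birth_date = "1970-06-15",
                        deceased = NA, last_updated = "2024-12-02T00:00:00Z") {
  tibble::tibble(id = id, gender = gender, birth_date = birth_date,
                 deceased = deceased, last_updated = last_updated)
}

condition_row <- function(id, patient_ref, code = "E11.9",
                          coding_system = "http://hl7.org/fhir/sid/icd-10") {
  tibble::tibble(id = id, patient_ref = patient_ref, code = code,
                 coding_system = coding_system)
}

specimen_row <- function(id, patient_ref, type_code = "blood-plasma",
                         collected = "2020-05-01") {
  tibble::tibble(id = id, patient_ref = patient_ref, type_code = type_code,
                 collected = collected)
}

# three patients: one missing gender, one with a condition, deterministic
tiny_dataset <- function() {
  fhir_dataset(
    patients = dplyr::bind_rows(
      patient_row("p1", gender = "female"),
      patient_row("p2", gender = NA_character_),
      patient_row("p3", gender = "male", deceased = TRUE)
    ),
    conditions = dplyr::bind_rows(
      condition_row("c1", "p1"),
      condition_row("c2", "p3", code = "I10")
    ),
    specimens = specimen_row("s1", "p1"),
    reference_date = REF_DATE
  )
}

battery_tbl <- function(dataset, defs = builtin_checks()) {
  run_battery(defs, dataset)
}

get_row <- function(tbl, id, stratum = NA_character_) {
  hit <- tbl$check_id == id &
    (is.na(stratum) & is.na(tbl$stratum) |
       (!is.na(stratum) & !is.na(tbl$stratum) & tbl$stratum == stratum))
  tbl[which(hit), ]
}

zero_profile <- function() error_profile()
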