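# ICD-10 structural validity and the gender-incompatibility table.

#' Structural ICD-10 code validation
#'
#' Tests codes against the structural ICD-10 pattern
#' `^[A-TV-Z][0-9][0-9A-B](\.[0-9A-TV-Z]{1,4})?$` (the letter U is reserved).
#' When a code list is supplied, validity becomes terminology membership
#' instead. `NA` and empty codes are invalid under either mode.
#'
#' @param codes Character vector of codes.
#' @param code_list Optional character vector; when given, a code is valid iff
#'   it is a member.
#' @return Logical vector.
#' @export
icd10_valid <- function(codes, code_list = NULL) {
  present <- !is.na(codes) & nzchar(codes)
  if (!is.null(code_list)) return(present & codes %in% code_list)
  present & grepl("^[A-TV-Z][0-9][0-9A-B](\\.[0-9A-TV-Z]{1,4})?$", codes)
}

#' Built-in pool of real ICD-10 codes
#'
#' A small curated pool of structurally valid, real ICD-10 codes used by the
#' synthetic cohort generator. Codes in the gender-specific blocks (C51-C58,
#' C60-C63) are included for incompatibility injection but are excluded from
#' the gender-neutral sampling pool.
#'
#' @param neutral_only If `TRUE` (default), exclude codes from the
#'   gender-specific blocks.
#' @return Character vector of codes.
#' @export
icd10_code_pool <- function(neutral_only = TRUE) {
  pool <- c(
    "A09", "A41.9", "B18.2", "B20", "C16.9", "C18.7", "C25.9", "C34.1",
    "C43.5", "C50.9", "C56", "C61", "C64.9", "C71.9", "C78.0", "C80.1",
    "D50.9", "D64.9", "E03.9", "E10.9", "E11.9", "E66.9", "E78.5", "F10.2",
    "F20.9", "F32.9", "F41.1", "G20", "G35", "G40.9", "I10", "I21.9",
    "I25.1", "I48.9", "I50.9", "I63.9", "J18.9", "J44.9", "J45.9", "K21.9",
    "K50.9", "K70.3", "K80.2", "M06.9", "M17.9", "M54.5", "N18.3", "N39.0",
    "R55", "Z51.1"
  )
  if (neutral_only) {
    pool[!substr(pool, 1, 3) %in% c(male_only_roots(), female_only_roots())]
  } else {
    pool
  }
}

male_only_roots <- function() paste0("C6", 0:3)
female_only_roots <- function() paste0("C5", 1:8)

#' Default gender-incompatibility table
#'
#' Maps ICD-10 three-character roots to the only administrative gender they
#' are compatible with: the male genital organ block C60-C63 (e.g. prostate
#' cancer, C61) and the female genital organ block C51-C58. Configurable:
#' checks accept a user-supplied table of the same shape.
#'
#' @return Tibble with columns `root` and `required_gender`.
#' @export
default_incompatibility_table <- function() {
  tibble::tibble(
    root = c(male_only_roots(), female_only_roots()),
    required_gender = c(rep("male", 4), rep("female", 8))
  )
}
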