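test_that("the built-in catalogue covers the nine checks across six dimensions", {
  defs <- builtin_checks()
  expect_length(defs, 9L)
  ids <- vapply(defs, function(d) d$check_id, character(1))
  expect_setequal(
    ids,
    c("accuracy-1", "accuracy-2", "accuracy-3", "completeness-1",
      "completeness-2", "consistency-1", "timeliness-1", "validity-1",
      "uniqueness-1")
  )
  dims <- vapply(defs, function(d) d$dimension, character(1))
  expect_setequal(unique(dims), quality_dimensions())
  expect_true(all(vapply(defs, function(d) d$sensitivity, integer(1)) == 1L))
  strat <- defs[[which(ids == "accuracy-3")]]
  expect_equal(strat$strata, c("female", "male"))
  # legacy spellings stay resolvable as aliases
  aliases <- unlist(lapply(defs, function(d) d$alias))
  expect_true(all(c("completness-1", "completness-2", "uniqness-1") %in%
                    aliases))
})

test_that("missing and unsupported gender are disjoint numerators", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(
      patient_row("p1", gender = NA_character_),
      patient_row("p2", gender = ""),
      patient_row("p3", gender = "MALE"),
      patient_row("p4", gender = "unknown"),
      patient_row("p5", gender = "female")
    ),
    reference_date = REF_DATE
  )
  bat <- battery_tbl(ds)
  expect_equal(get_row(bat, "completeness-1")$numerator, 2L)  # NA and ""
  expect_equal(get_row(bat, "consistency-1")$numerator, 1L)   # "MALE" only
  expect_equal(get_row(bat, "completeness-1")$raw_percent, 40)
})

test_that("one of three patients missing gender gives 33.33 percent", {
  ds <- tiny_dataset()
  res <- run_check(builtin_checks()[[3]], ds)
  expect_equal(res$numerator, 1L)
  expect_equal(res$denominator, 3L)
  expect_equal(res$raw_percent, 33.33)
})

test_that("uniqueness counts surplus records over total records", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(patient_row("A"), patient_row("A"),
                                patient_row("B")),
    reference_date = REF_DATE
  )
  res <- run_check(builtin_checks()[[8]], ds)
  expect_equal(res$numerator, 1L)
  expect_equal(res$raw_percent, 33.33)
})

test_that("ICD-10 structural validation follows the documented pattern", {
  expect_true(all(icd10_valid(c("C61", "C50.9", "E11.9", "A09", "M54.5"))))
  expect_false(any(icd10_valid(c("U07.1",       # U excluded
                                 "c61",         # lower case
                                 "C6",          # too short
                                 "C611x",       # junk suffix
                                 "1A2", "", NA))))
  expect_true(all(icd10_valid(icd10_code_pool(neutral_only = FALSE))))
  # terminology mode: membership replaces the pattern
  expect_equal(icd10_valid(c("C61", "XYZ"), code_list = c("XYZ")),
               c(FALSE, TRUE))
})

test_that("validity-1 flags patients over the condition-bearing population", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(patient_row("p1"), patient_row("p2"),
                                patient_row("p3"), patient_row("p4")),
    conditions = dplyr::bind_rows(
      condition_row("c1", "p1", code = "E11.9"),   # valid
      condition_row("c2", "p2", code = "bogus"),   # invalid
      condition_row("c3", "p2", code = "I10"),     # same patient, counted once
      condition_row("c4", "p3", code = NA_character_)  # missing code: invalid
    ),
    reference_date = REF_DATE
  )
  res <- run_check(builtin_checks()[[7]], ds)
  expect_equal(res$numerator, 2L)
  expect_equal(res$denominator, 3L)  # p4 has no conditions
})

test_that("gender-incompatible diagnoses respect the incompatibility table", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(
      patient_row("f1", gender = "female"),
      patient_row("m1", gender = "male"),
      patient_row("u1", gender = NA_character_),
      patient_row("x1", gender = "MALE")
    ),
    conditions = dplyr::bind_rows(
      condition_row("c1", "f1", code = "C61"),    # prostate for female: hit
      condition_row("c2", "m1", code = "C56.9"),  # ovary for male: hit
      condition_row("c3", "u1", code = "C61"),    # unknown gender: no hit
      condition_row("c4", "x1", code = "C61"),    # unsupported token: no hit
      condition_row("c5", "m1", code = "C61")     # compatible: no hit
    ),
    reference_date = REF_DATE
  )
  res <- run_check(builtin_checks()[[1]], ds)
  expect_equal(res$numerator, 2L)
})

test_that("timeliness counts stale and provenance-free records", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(
      patient_row("p1", last_updated = "2024-12-20T10:00:00Z"),  # fresh
      patient_row("p2", last_updated = "2023-06-01T00:00:00Z"),  # stale
      patient_row("p3", last_updated = NA_character_)            # missing
    ),
    reference_date = REF_DATE
  )
  res <- run_check(builtin_checks()[[6]], ds)
  expect_equal(res$numerator, 2L)
})

test_that("survival rate is the percent of stratum patients not known deceased", {
  ds <- fhir_dataset(
    patients = dplyr::bind_rows(
      patient_row("f1", gender = "female", deceased = TRUE),
      patient_row("f2", gender = "female", deceased = FALSE),
      patient_row("f3", gender = "female", deceased = NA),
      patient_row("m1", gender = "male", deceased = TRUE)
    ),
    reference_date = REF_DATE
  )
  res <- run_check(builtin_checks()[[9]], ds)
  expect_equal(res$stratum, c("female", "male"))
  expect_equal(res$numerator, c(2L, 0L))
  expect_equal(res$denominator, c(3L, 1L))
  expect_equal(res$raw_percent, c(66.67, 0))
})

test_that("empty denominator populations raise, distinct from a zero rate", {
  no_males <- fhir_dataset(patients = patient_row("f1", gender = "female"),
                           reference_date = REF_DATE)
  expect_error(run_check(builtin_checks()[[9]], no_males),
               "insufficient population")
  # but the battery captures it instead of aborting
  bat <- battery_tbl(no_males)
  row <- get_row(bat, "accuracy-3")
  expect_match(row$error, "insufficient population")
  expect_true(all(is.na(row$raw_percent)))
  expect_equal(get_row(bat, "completeness-1")$raw_percent, 0)
})

test_that("checks are deterministic and bounded", {
  co <- generate_cohort(cohort_spec(300, seed = 9))
  a <- battery_tbl(co); b <- battery_tbl(co)
  expect_identical(a, b)
  ok <- !is.na(a$raw_percent)
  expect_true(all(a$raw_percent[ok] >= 0 & a$raw_percent[ok] <= 100))
  expect_true(all(a$numerator[ok] <= a$denominator[ok]))
})

test_that("adding a failing patient never decreases a check's numerator", {
  co <- generate_cohort(cohort_spec(50, seed = 2))
  before <- get_row(battery_tbl(co), "completeness-1")$numerator
  co$patients <- dplyr::bind_rows(co$patients,
                                  patient_row("extra", gender = NA_character_))
  after <- get_row(battery_tbl(co), "completeness-1")$numerator
  expect_equal(after, before + 1L)
})

test_that("custom checks register and run like built-ins", {
  custom <- check_definition(
    "completeness-3", "completeness", "patients without a birth date",
    function(ds, stratum) {
      list(numerator = sum(is.na(ds$patients$birth_date)),
           denominator = nrow(ds$patients))
    }
  )
  registry <- register_check(custom)
  expect_length(registry, 10L)
  expect_length(builtin_checks(), 9L)  # built-ins untouched
  expect_error(register_check(custom, registry), "already registered")
  # legacy alias spellings are reserved too
  dup_alias <- check_definition("completness-1", "completeness", "dup",
                                function(ds, stratum) list(numerator = 0,
                                                           denominator = 1))
  expect_error(register_check(dup_alias), "already registered")

  ds <- tiny_dataset()
  ds$patients$birth_date[1] <- NA_character_
  bat <- run_battery(registry, ds)
  expect_equal(get_row(bat, "completeness-3")$raw_percent, 33.33)
})
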