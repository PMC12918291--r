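#' Report configuration
#'
#' Bundles the disclosure settings of one quality report. Defaults follow the
#' reference study configuration: ε = 0.2 per check, ε = 0.3 for the
#' stratified check, a total cap of 2.0, warning/error thresholds of 10%/30%,
#' suppression disabled, and a minimum cohort size of 30 for the release
#' gate.
#'
#' @param cap Total privacy budget per report.
#' @param per_check_epsilon Budget per unstratified check.
#' @param stratified_epsilon Budget per stratified check (spent once; the
#'   stratum split is internal).
#' @param warn_threshold,error_threshold Status thresholds in percent.
#' @param suppression_threshold Raw-numerator threshold below which released
#'   percentages are rounded down to 0; 0 disables suppression.
#' @param min_n Minimum cohort size for the release gate.
#' @param pair_split Noise both numerator and denominator (halving each
#'   check's ε between them) or the numerator only.
#' @return List of class `dq_config`.
#' @export
dq_config <- function(cap = 2.0, per_check_epsilon = 0.2,
                      stratified_epsilon = 0.3, warn_threshold = 10,
                      error_threshold = 30, suppression_threshold = 0,
                      min_n = 30, pair_split = TRUE) {
  if (warn_threshold > error_threshold) {
    stop("warn_threshold must not exceed error_threshold")
  }
  stopifnot(cap > 0, per_check_epsilon > 0, stratified_epsilon > 0,
            suppression_threshold >= 0, min_n >= 1)
  structure(list(cap = cap, per_check_epsilon = per_check_epsilon,
                 stratified_epsilon = stratified_epsilon,
                 warn_threshold = warn_threshold,
                 error_threshold = error_threshold,
                 suppression_threshold = suppression_threshold,
                 min_n = min_n, pair_split = isTRUE(pair_split)),
            class = "dq_config")
}

#' Read a report configuration from YAML or JSON
#'
#' Accepts a file with any subset of the [dq_config()] fields; unknown keys
#' are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `dq_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(dq_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(dq_config, raw)
}

#' Map a disclosed percentage to a status
#'
#' Pure function of the DP value and the thresholds, so any consumer of the
#' public report can recompute it: `ok` when the value is at or below the
#' warning threshold, `warning` when above it but at or below the error
#' threshold, `error` above that.
#'
#' @param dp_percent Disclosed percentage (vectorised).
#' @param warn,error Thresholds in percent, `warn <= error`.
#' @return Character vector of statuses.
#' @export
status_for <- function(dp_percent, warn = 10, error = 30) {
  if (warn > error) stop("warn threshold must not exceed error threshold")
  ifelse(dp_percent <= warn, "ok",
         ifelse(dp_percent <= error, "warning", "error"))
}

#' Build a quality report with DP disclosure
#'
#' Runs a check battery under budget accounting: for every definition the
#' ledger is charged first (fail-closed — a check whose charge is refused
#' does not run and appears in the report with status `"error"` and reason
#' `"budget exhausted"`), the check is executed, and its result is perturbed
#' with the Laplace mechanism. Stratified checks are charged their ε once and
#' split it internally across strata. Raw values are retained in the local
#' view only; [export_public()] never serialises them.
#'
#' @param dataset A non-empty [fhir_dataset()].
#' @param definitions List of [check_definition()]s (default the built-ins).
#' @param config A [dq_config()].
#' @param node_id Identifier of the reporting node.
#' @param seed Optional integer; when given, seeds the noise stream and is
#'   recorded (local-only) as the seed tag.
#' @param epsilon_plan Optional named vector overriding the per-check ε
#'   allocation (as from [allocation_plan()]).
#' @return Object of class `quality_report`.
#' @export
build_report <- function(dataset, definitions = builtin_checks(),
                         config = dq_config(), node_id = "node-1",
                         seed = NULL, epsilon_plan = NULL) {
  stopifnot(inherits(dataset, "fhir_dataset"))
  if (nrow(dataset$patients) == 0) stop("empty dataset: nothing to report on")
  seed_tag <- NA_character_
  if (!is.null(seed)) {
    set.seed(seed)
    seed_tag <- paste0("seed:", seed)
  }
  ledger <- open_ledger(config$cap)
  entries <- list()
  for (def in definitions) {
    eps <- if (!is.null(epsilon_plan) && def$check_id %in% names(epsilon_plan)) {
      unname(epsilon_plan[[def$check_id]])
    } else if (is.null(def$strata)) {
      config$per_check_epsilon
    } else {
      config$stratified_epsilon
    }
    charged <- tryCatch({
      ledger <- charge(ledger, def$check_id, eps)
      TRUE
    }, dpquality_budget_exhausted = function(e) FALSE)
    if (!charged) {
      entries[[length(entries) + 1L]] <- tibble::tibble(
        check_id = def$check_id, dimension = def$dimension,
        description = def$description, stratum = NA_character_,
        numerator = NA_integer_, denominator = NA_integer_,
        raw_percent = NA_real_, dp_percent = NA_real_,
        epsilon_spent = NA_real_, status = "error", suppressed = FALSE,
        reason = "budget exhausted"
      )
      next
    }
    entry <- tryCatch({
      res <- run_check(def, dataset)
      noised <- stratified_noisy_rates(res, eps, def$sensitivity,
                                       pair_split = config$pair_split)
      noised <- lapply(seq_along(noised), function(i) {
        suppress_low_count(noised[[i]], res$numerator[i],
                           config$suppression_threshold)
      })
      shares <- split_stratum_budget(eps, nrow(res))
      dplyr::mutate(
        res,
        dp_percent = vapply(noised, `[[`, numeric(1), "dp_percent"),
        epsilon_spent = shares,
        status = status_for(vapply(noised, `[[`, numeric(1), "dp_percent"),
                            def$warn_threshold, def$error_threshold),
        suppressed = vapply(noised, `[[`, logical(1), "suppressed"),
        reason = NA_character_
      )
    }, error = function(e) tibble::tibble(
      check_id = def$check_id, dimension = def$dimension,
      description = def$description, stratum = NA_character_,
      numerator = NA_integer_, denominator = NA_integer_,
      raw_percent = NA_real_, dp_percent = NA_real_,
      epsilon_spent = eps, status = "error", suppressed = FALSE,
      reason = conditionMessage(e)
    ))
    entries[[length(entries) + 1L]] <- entry
  }
  structure(list(
    node_id = node_id,
    created_at = dataset$reference_date,  # truncated to the day by design
    entries = dplyr::bind_rows(entries),
    budget_cap = ledger$cap,
    budget_consumed = ledger$consumed,
    ledger = ledger,
    seed_tag = seed_tag
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> node ", x$node_id, ", ",
      nrow(x$entries), " entries, budget ",
      format(round(x$budget_consumed, 6)), "/", format(x$budget_cap),
      "\n", sep = "")
  cols <- intersect(c("check_id", "stratum", "raw_percent", "dp_percent",
                      "epsilon_spent", "status"), names(x$entries))
  print(x$entries[, cols])
  invisible(x)
}

public_entry_fields <- c("check_id", "dimension", "description", "stratum",
                         "dp_percent", "epsilon_spent", "status", "suppressed")
local_only_fields <- c("raw_percent", "numerator", "denominator", "seed_tag")

report_to_list <- function(report, public) {
  fields <- if (public) public_entry_fields else
    c(public_entry_fields, "raw_percent", "numerator", "denominator", "reason")
  entries <- lapply(seq_len(nrow(report$entries)), function(i) {
    row <- report$entries[i, ]
    e <- lapply(fields[fields %in% names(row)], function(f) row[[f]])
    names(e) <- fields[fields %in% names(row)]
    if (public && !is.na(row$reason)) e$reason <- row$reason
    drop_absent(e)
  })
  out <- list(
    node_id = report$node_id,
    created_at = format(report$created_at),
    budget_cap = report$budget_cap,
    budget_consumed = report$budget_consumed,
    entries = entries
  )
  if (!public) out$seed_tag <- report$seed_tag
  out
}

#' Export the public (DP-only) view of a report
#'
#' Writes JSON containing only the disclosed quantities: DP percentages,
#' statuses and the ε accounting. Raw percentages, raw counts and seed
#' material never appear in the emitted bytes. Serialisation uses a fixed
#' key order, so re-exporting the same report is byte-identical.
#'
#' @param report A [build_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_public <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  writeLines(jsonlite::toJSON(report_to_list(report, public = TRUE),
                              auto_unbox = TRUE, digits = NA, null = "null",
                              na = "null", pretty = TRUE), path)
  invisible(path)
}

#' Export the local (raw + DP) view of a report
#'
#' Same layout as [export_public()] plus the raw percentages, raw counts and
#' the seed tag. For site-local storage only; never share this file.
#'
#' @inheritParams export_public
#' @return `path`, invisibly.
#' @export
export_local <- function(report, path) {
  stopifnot(inherits(report, "quality_report"))
  writeLines(jsonlite::toJSON(report_to_list(report, public = FALSE),
                              auto_unbox = TRUE, digits = NA, null = "null",
                              na = "null", pretty = TRUE), path)
  invisible(path)
}

#' Read and validate a public report file
#'
#' Enforces the privacy boundary of the federation schema: a file containing
#' any local-only field (raw percentages, raw counts, seed material) is
#' rejected as malformed, so local reports can never be aggregated by
#' accident.
#'
#' @param path Path to a public report JSON file.
#' @return The parsed report list.
#' @export
read_public_report <- function(path) {
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  req <- c("node_id", "created_at", "budget_cap", "budget_consumed", "entries")
  missing <- setdiff(req, names(parsed))
  if (length(missing)) {
    stop("malformed public report ", path, ": missing ",
         paste(missing, collapse = ", "))
  }
  leaked <- intersect(local_only_fields,
                      unique(c(names(parsed),
                               unlist(lapply(parsed$entries, names)))))
  if (length(leaked)) {
    stop("refusing ", path, ": contains local-only fields (",
         paste(leaked, collapse = ", "), ")")
  }
  parsed
}
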