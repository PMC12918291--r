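#' Privacy-budget ledger
#'
#' Tracks per-report privacy expenditure under sequential composition: k
#' mechanisms at ε_1, ..., ε_k jointly satisfy (Σ ε_i)-DP, so the ledger's
#' consumed total is the report's overall privacy loss and must never exceed
#' the configured cap. Charges are atomic: a charge that would exceed the cap
#' is refused and leaves the ledger unchanged (fail-closed — an unpaid check
#' does not run).
#'
#' @param cap Positive total budget ε for one report (the study configuration
#'   uses 2.0).
#' @return Object of class `budget_ledger` with fields `cap`, `entries`
#'   (tibble of `check_id`, `epsilon`), `consumed`, `remaining`.
#' @export
open_ledger <- function(cap) {
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0) {
    stop("cap must be a single positive number")
  }
  structure(list(cap = cap,
                 entries = tibble::tibble(check_id = character(),
                                          epsilon = numeric()),
                 consumed = 0, remaining = cap),
            class = "budget_ledger")
}

#' @export
print.budget_ledger <- function(x, ...) {
  cat("<budget_ledger> cap ", format(x$cap), ": consumed ",
      format(round(x$consumed, 6)), ", remaining ",
      format(round(x$remaining, 6)), " over ", nrow(x$entries),
      " charge(s)\n", sep = "")
  invisible(x)
}

# absolute tolerance for cap comparisons, so binary-float charge sequences
# such as seven 0.2s plus 0.3 against cap 2.0 are not refused spuriously
.budget_tol <- 1e-9

#' Charge a check's budget against the ledger
#'
#' @param ledger A [open_ledger()] ledger.
#' @param check_id Identifier of the check being paid for.
#' @param epsilon Positive budget to consume.
#' @return The updated ledger; on an over-cap charge an error of class
#'   `dpquality_budget_exhausted` is raised and the ledger is unchanged.
#' @export
charge <- function(ledger, check_id, epsilon) {
  stopifnot(inherits(ledger, "budget_ledger"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("epsilon must be a single positive number")
  }
  if (ledger$consumed + epsilon > ledger$cap + .budget_tol) {
    stop(errorCondition(
      paste0("budget exhausted: charging ", epsilon, " for ", check_id,
             " would exceed cap ", ledger$cap, " (consumed ",
             round(ledger$consumed, 6), ")"),
      class = "dpquality_budget_exhausted"
    ))
  }
  ledger$entries <- dplyr::bind_rows(
    ledger$entries, tibble::tibble(check_id = check_id, epsilon = epsilon)
  )
  ledger$consumed <- sum(ledger$entries$epsilon)
  ledger$remaining <- ledger$cap - ledger$consumed
  ledger
}

#' Plan the ε allocation across a check battery
#'
#' Overridden checks take their stated ε. The remaining checks either share
#' the leftover budget uniformly (the default) or, when `default_epsilon` is
#' given, each take that flat value — the study configuration is reproduced
#' with `default_epsilon = 0.2` and the stratified check overridden to 0.3.
#'
#' @param definitions List of [check_definition()] objects.
#' @param cap Positive total budget.
#' @param overrides Named list/vector mapping check ids to ε values.
#' @param default_epsilon Optional flat ε for non-overridden checks.
#' @return Named numeric vector, one ε per check id; total never exceeds
#'   `cap`.
#' @export
allocation_plan <- function(definitions, cap, overrides = list(),
                            default_epsilon = NULL) {
  ids <- vapply(definitions, function(d) d$check_id, character(1))
  overrides <- unlist(overrides)
  unknown <- setdiff(names(overrides), ids)
  if (length(unknown)) {
    stop("overrides name unknown checks: ", paste(unknown, collapse = ", "))
  }
  if (sum(overrides) > cap + .budget_tol) {
    stop("overrides alone exceed the cap")
  }
  plan <- stats::setNames(numeric(length(ids)), ids)
  plan[names(overrides)] <- overrides
  rest <- setdiff(ids, names(overrides))
  if (length(rest)) {
    if (is.null(default_epsilon)) {
      plan[rest] <- (cap - sum(overrides)) / length(rest)
    } else {
      plan[rest] <- default_epsilon
      if (sum(plan) > cap + .budget_tol) {
        stop("plan total ", round(sum(plan), 6), " exceeds cap ", cap)
      }
    }
  }
  plan
}
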