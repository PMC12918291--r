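#' Aggregate public reports from federated nodes
#'
#' Emulates the central server of the agent/server architecture: it consumes
#' public (DP-only) report files exclusively — [read_public_report()] rejects
#' any file carrying local-only fields — and builds a cross-node table of
#' disclosed values per check. A malformed file is reported and skipped;
#' aggregation continues with the remaining nodes. Nodes missing a check are
#' marked absent (`NA`), never zero.
#'
#' @param paths Character vector of public report file paths (at least one).
#' @return Object of class `federation_view`: `reports` (named list of parsed
#'   public reports), `table` (tibble with one row per check/stratum/node),
#'   `errors` (named character vector of per-file failures).
#' @export
aggregate_nodes <- function(paths) {
  stopifnot(length(paths) >= 1)
  reports <- list()
  errors <- character()
  for (p in paths) {
    parsed <- tryCatch(read_public_report(p), error = function(e) e)
    if (inherits(parsed, "error")) {
      errors[p] <- conditionMessage(parsed)
      next
    }
    reports[[parsed$node_id]] <- parsed
  }
  if (!length(reports)) stop("no readable public reports among the inputs")
  per_node <- lapply(names(reports), function(node) {
    entries <- reports[[node]]$entries
    dplyr::bind_rows(lapply(entries, function(e) {
      tibble::tibble(
        node_id = node,
        check_id = e$check_id,
        stratum = e$stratum %||% NA_character_,
        dp_percent = as.numeric(e$dp_percent %||% NA_real_),
        status = e$status %||% NA_character_
      )
    }))
  })
  long <- dplyr::bind_rows(per_node)
  # absent checks become explicit NA rows for every node missing them
  keys <- dplyr::distinct(long[, c("check_id", "stratum")])
  grid <- dplyr::cross_join(tibble::tibble(node_id = names(reports)), keys)
  table <- dplyr::left_join(grid, long,
                            by = c("node_id", "check_id", "stratum"))
  structure(list(reports = reports, table = table, errors = errors),
            class = "federation_view")
}

#' @export
print.federation_view <- function(x, ...) {
  cat("<federation_view> ", length(x$reports), " node(s)",
      if (length(x$errors)) paste0(", ", length(x$errors), " failed file(s)"),
      "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Simulate a federation of quality agents
#'
#' Runs k node-local agents end to end: each generates its own synthetic
#' cohort (per-node seed), builds a DP report against a fresh budget ledger,
#' and writes only the public view into its node directory. The server then
#' aggregates the public files. Transport is the filesystem — one directory
#' per node — standing in for the network layer of the architecture.
#'
#' @param n_nodes Number of nodes.
#' @param out_dir Directory to place `node-<i>/public-report.json` files in.
#' @param n_patients,n_specimens Cohort size per node.
#' @param profile An [error_profile()] shared by all nodes.
#' @param config A [dq_config()].
#' @param seed Base seed; node i uses `seed + i` for both cohort and noise.
#' @param reference_date Evaluation date shared by all nodes.
#' @return The [aggregate_nodes()] view over the generated public reports.
#' @export
federate <- function(n_nodes, out_dir = tempfile("federation"),
                     n_patients = 1000, n_specimens = 0,
                     profile = default_profile(), config = dq_config(),
                     seed = 1, reference_date = as.Date("2025-01-01")) {
  stopifnot(n_nodes >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_nodes)
  for (i in seq_len(n_nodes)) {
    node <- paste0("node-", i)
    node_dir <- file.path(out_dir, node)
    dir.create(node_dir, showWarnings = FALSE)
    cohort <- generate_cohort(cohort_spec(
      n_patients = n_patients, n_specimens = n_specimens, seed = seed + i,
      profile = profile, reference_date = reference_date
    ))
    report <- build_report(cohort, config = config, node_id = node,
                           seed = seed + i)
    export_local(report, file.path(node_dir, "local-report.json"))
    paths[i] <- file.path(node_dir, "public-report.json")
    export_public(report, paths[i])
  }
  aggregate_nodes(paths)
}
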