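# Internal helpers shared across modules.

utils::globalVariables(c("p_in", "lower", "upper", "epsilon"))

# FHIR permits partial dates (YYYY or YYYY-MM); comparisons use the earliest
# instant of the stated period, so "1975" sorts as 1975-01-01.
parse_fhir_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & nzchar(x)
  if (!any(ok)) return(out)
  padded <- vapply(x[ok], function(d) {
    n <- nchar(d)
    if (n == 4) paste0(d, "-01-01") else if (n == 7) paste0(d, "-01") else d
  }, character(1), USE.NAMES = FALSE)
  out[ok] <- as.Date(padded, format = "%Y-%m-%d")
  out
}

parse_fhir_instant <- function(x) {
  out <- rep(as.POSIXct(NA), length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.POSIXct(sub("Z$", "", x[ok]), tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%S")
  }
  out
}

format_fhir_instant <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar-or-NA extraction from parsed JSON: absent and null both map to NA.
json_chr <- function(x) {
  if (is.null(x) || length(x) == 0) NA_character_ else as.character(x[[1]])
}
json_lgl <- function(x) {
  if (is.null(x) || length(x) == 0) NA else as.logical(x[[1]])
}
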