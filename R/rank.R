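#' Rank an id/value table into a RankedProfile
#'
#' Sorts records by value ascending and assigns 1-based ranks. Equal values
#' are ordered by identifier in C-locale lexicographic order, so the ranking
#' is canonical: any permutation of the same records yields an identical
#' profile. Zero-valued records are kept — the cutoff is computed on the
#' complete ranked distribution.
#'
#' @param x either a data.frame containing identifier and value columns, or a
#'   character vector of identifiers.
#' @param values numeric vector of values when `x` is a character vector;
#'   ignored otherwise.
#' @param idCol,valueCol column names used when `x` is a data.frame.
#' @return a validated [RankedProfile-class].
#'
#' @details Inputs are rejected with classed errors: fewer than 3 records
#' (`kneecut_size_error`), non-finite or negative values, duplicated or empty
#' identifiers (`kneecut_validation_error`, naming the offending records).
#'
#' @examples
#' rankProfile(c("g1", "g2", "g3"), c(10, 0, 1))
#' df <- data.frame(id = c("a", "b", "c"), value = c(5, 5, 0))
#' rankProfile(df)   # tie at 5 broken by identifier: c, a, b
#' @export
rankProfile <- function(x, values = NULL, idCol = "id", valueCol = "value") {
  if (is.data.frame(x)) {
    missing <- setdiff(c(idCol, valueCol), names(x))
    if (length(missing))
      stopKneecut("format_error", sprintf(
        "column(s) %s not found; available columns: %s",
        paste(sQuote(missing), collapse = ", "),
        paste(sQuote(names(x)), collapse = ", ")))
    ids <- as.character(x[[idCol]])
    vals <- x[[valueCol]]
  } else {
    ids <- as.character(x)
    vals <- values
  }
  if (!is.numeric(vals))
    stopKneecut("validation_error", "values must be numeric")
  vals <- as.numeric(vals)

  if (length(ids) != length(vals))
    stopKneecut("validation_error",
                "identifiers and values must have the same length")
  if (length(vals) < 3L)
    stopKneecut("size_error", sprintf(
      "at least 3 records are required to fit a chord, got %d", length(vals)))
  if (anyNA(ids) || any(!nzchar(ids)))
    stopKneecut("validation_error", "identifiers must be non-empty")
  bad <- !is.finite(vals) | vals < 0
  if (any(bad))
    stopKneecut("validation_error", sprintf(
      "values must be finite and non-negative; offending identifier(s): %s",
      paste(sQuote(utils::head(ids[bad], 5L)), collapse = ", ")))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopKneecut("validation_error", sprintf(
      "duplicated identifier(s): %s",
      paste(sQuote(utils::head(dup, 5L)), collapse = ", ")))

  ord <- order(vals, ids, method = "radix")
  new("RankedProfile", ids = ids[ord], values = vals[ord])
}
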