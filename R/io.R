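#' Read an id/value table from TSV or CSV
#'
#' Reads a delimited UTF-8 table with a header row, skipping blank lines and
#' `#` comment lines, and returns one record per data row. Column names are
#' configurable; the two required columns are an identifier and a numeric
#' value.
#'
#' Malformed input is rejected with classed errors: a missing column raises a
#' format error naming the available columns; an unparsable value cell raises
#' a validation error citing the data row number(s); duplicated identifiers
#' raise a validation error listing them (aggregation of duplicates would be
#' an arbitrary biological choice, so it is refused).
#'
#' @param path file path.
#' @param idCol,valueCol names of the identifier and value columns.
#' @param delimiter field separator; `NULL` (default) picks `","` for
#'   `.csv` files and tab otherwise.
#' @return data.frame with character column `id` and numeric column `value`,
#'   in file order.
#' @seealso [rankProfile()]
#' @export
readValueTable <- function(path, idCol = "id", valueCol = "value",
                           delimiter = NULL) {
  if (!file.exists(path))
    stopKneecut("format_error", sprintf("input file not found: %s", path))
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      comment.char = "#", blank.lines.skip = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "\"", colClasses = "character",
                      encoding = "UTF-8"),
    error = function(e) stopKneecut("format_error", sprintf(
      "could not parse %s: %s", path, conditionMessage(e))))
  missing <- setdiff(c(idCol, valueCol), names(tab))
  if (length(missing))
    stopKneecut("format_error", sprintf(
      "column(s) %s not found in %s; available columns: %s",
      paste(sQuote(missing), collapse = ", "), path,
      paste(sQuote(names(tab)), collapse = ", ")))

  ids <- tab[[idCol]]
  raw <- tab[[valueCol]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !(raw %in% c("NA", "NaN")))
  if (length(bad))
    stopKneecut("validation_error", sprintf(
      "unparsable value(s) in column '%s' at data row(s) %s (e.g. %s)",
      valueCol, paste(utils::head(bad, 5L), collapse = ", "),
      sQuote(raw[bad[1L]])))
  if (anyNA(vals))
    stopKneecut("validation_error", sprintf(
      "missing value(s) at data row(s) %s",
      paste(utils::head(which(is.na(vals)), 5L), collapse = ", ")))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopKneecut("validation_error", sprintf(
      "duplicated identifier(s): %s",
      paste(sQuote(utils::head(dup, 5L)), collapse = ", ")))
  data.frame(id = as.character(ids), value = vals, stringsAsFactors = FALSE)
}

# Distances are serialized with 6 significant digits; ranks and values keep
# full precision so a written table ranks identically when read back.
.formatDistance <- function(d) formatC(signif(d, 6), format = "g",
                                       digits = 6)

#' Write a shortlist (or any record table) as TSV
#'
#' @param shortlist data.frame from [extractShortlist()] (columns `id`,
#'   `rank`, `value`, `distance`) or [lowTailControlList()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeShortlist <- function(shortlist, path) {
  out <- shortlist
  if ("distance" %in% names(out))
    out$distance <- .formatDistance(out$distance)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the full per-rank distance profile as TSV
#'
#' @param profile a [RankedProfile-class].
#' @param cutoff the matching [CutoffResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDistanceTable <- function(profile, cutoff, path) {
  out <- data.frame(rank = ranks(profile), id = recordIds(profile),
                    value = recordValues(profile),
                    distance = .formatDistance(distances(cutoff)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Captures everything needed to trace a shortlist back to its input: record
#' count, chord coefficients, cutoff rank/identifier/value, maximum
#' distance, shortlist size, tie count, tool version and the MD5 checksum of
#' the input file. Numbers are carried at full double precision. For a
#' stringency-adjusted result the reference (unadjusted) rank and the offset
#' are included as well.
#'
#' @param cutoff a [CutoffResult-class].
#' @param path output file path.
#' @param inputPath optional path of the input table, for the checksum.
#' @return the summary list, invisibly.
#' @export
writeSummary <- function(cutoff, path, inputPath = NULL) {
  s <- list(
    n = cutoff@n,
    m_B = chordSlope(cutoff),
    b_B = chordIntercept(cutoff),
    cutoff_rank = cutoffRank(cutoff),
    cutoff_id = cutoffId(cutoff),
    cutoff_value = cutoffValue(cutoff),
    max_distance = maxDistance(cutoff),
    shortlist_size = shortlistSize(cutoff),
    tie_count = tieCount(cutoff),
    tool_version = as.character(utils::packageVersion("kneecut")))
  if (cutoff@rank != cutoff@referenceRank ||
      cutoff@stringencyOffset != 0) {
    s$reference_rank <- referenceRank(cutoff)
    s$stringency_offset <- cutoff@stringencyOffset
    s$distance_at_cutoff <- cutoff@distance
  }
  s$input_checksum <- if (!is.null(inputPath))
    unname(tools::md5sum(inputPath)) else NA
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(s)
}

#' Write a truncation-stability table as TSV
#'
#' @param stability a [StabilityTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStabilityTable <- function(stability, path) {
  utils::write.table(stabilitySteps(stability), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
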