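#' RankedProfile: a ranked set of non-negative continuous values
#'
#' Stores identifiers and values sorted ascending by value, with 1-based ranks
#' implied by position. This is the ranked distribution curve of a descriptive
#' omics dataset: rank on the x axis, value (expression, abundance,
#' sensitivity score) on the y axis. Equal values are ordered by identifier
#' (C-locale lexicographic) so ranking is canonical and bit-reproducible.
#'
#' Objects are created with [rankProfile()], which sorts and validates; the
#' validity method re-checks the canonical order, so a hand-built object in
#' the wrong order is rejected.
#'
#' @slot ids character vector of unique, non-empty identifiers, aligned with
#'   `values`.
#' @slot values numeric vector of finite, non-negative values, non-decreasing.
#'
#' @seealso [rankProfile()], [findCutoff()]
#' @export
setClass("RankedProfile",
  slots = c(ids = "character", values = "numeric"))

setValidity("RankedProfile", function(object) {
  n <- length(object@values)
  if (length(object@ids) != n)
    return("ids and values must have the same length")
  if (n < 3L)
    return("a RankedProfile needs at least 3 records")
  if (anyNA(object@ids) || any(!nzchar(object@ids)))
    return("identifiers must be non-empty and non-missing")
  if (any(!is.finite(object@values)))
    return("values must be finite")
  if (any(object@values < 0))
    return("values must be non-negative")
  if (anyDuplicated(object@ids))
    return("identifiers must be unique")
  ord <- order(object@values, object@ids, method = "radix")
  if (!identical(ord, seq_len(n)))
    return("records must be sorted by value ascending, ties by identifier")
  TRUE
})

#' Chord: the linear shortcut through the ends of a ranked curve
#'
#' The straight line connecting the first ranked point `(1, V_min)` and the
#' last ranked point `(N, V_max)` of a [RankedProfile-class]. The cutoff is
#' the rank maximizing the perpendicular distance from the ranked curve to
#' this chord.
#'
#' @slot slope numeric scalar; `(V_max - V_min) / (N - 1)`, non-negative and
#'   strictly positive for any non-flat profile.
#' @slot intercept numeric scalar; `V_min - slope`, so the line passes through
#'   `(1, V_min)`.
#'
#' @seealso [fitChord()]
#' @export
setClass("Chord", slots = c(slope = "numeric", intercept = "numeric"))

setValidity("Chord", function(object) {
  if (length(object@slope) != 1L || length(object@intercept) != 1L)
    return("slope and intercept must be scalars")
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  TRUE
})

#' CutoffResult: the identified cutoff and derived shortlist boundary
#'
#' Result of [findCutoff()] (or [adjustCutoff()]): the rank maximizing the
#' perpendicular distance to the chord, the record at that rank, and the size
#' of the shortlist of records ranked strictly above it. The record at the
#' cutoff rank itself is *not* part of the shortlist.
#'
#' When several ranks tie for the maximum distance (exact binary equality),
#' the largest rank is returned — the most stringent shortlist — and
#' `tieCount` reports how many ranks tied. An adjusted result (see
#' [adjustCutoff()]) keeps the unadjusted rank in `referenceRank`.
#'
#' @slot rank integer; the cutoff rank in `[1, n]`.
#' @slot id character; identifier of the record at the cutoff rank.
#' @slot value numeric; value of the record at the cutoff rank.
#' @slot distance numeric; perpendicular distance at the cutoff rank (equals
#'   `maxDistance` unless the cutoff was shifted by a stringency offset).
#' @slot maxDistance numeric; maximum of the distance profile.
#' @slot shortlistSize integer; `n - rank`.
#' @slot tieCount integer; number of ranks attaining `maxDistance` exactly.
#' @slot n integer; number of records in the profile.
#' @slot chord the fitted [Chord-class].
#' @slot distances numeric; per-rank perpendicular distances (length `n`).
#' @slot referenceRank integer; the unadjusted cutoff rank (equal to `rank`
#'   for an unadjusted result).
#' @slot stringencyOffset numeric; the signed fraction of `n` applied by
#'   [adjustCutoff()]; 0 for an unadjusted result.
#'
#' @seealso [findCutoff()], [extractShortlist()], [adjustCutoff()]
#' @export
setClass("CutoffResult",
  slots = c(rank = "integer", id = "character", value = "numeric",
            distance = "numeric", maxDistance = "numeric",
            shortlistSize = "integer", tieCount = "integer", n = "integer",
            chord = "Chord", distances = "numeric",
            referenceRank = "integer", stringencyOffset = "numeric"))

setValidity("CutoffResult", function(object) {
  if (object@n < 3L) return("n must be at least 3")
  if (object@rank < 1L || object@rank > object@n)
    return("cutoff rank must lie in [1, n]")
  if (object@referenceRank < 1L || object@referenceRank > object@n)
    return("reference rank must lie in [1, n]")
  if (object@shortlistSize != object@n - object@rank)
    return("shortlistSize must equal n - rank")
  if (length(object@distances) != object@n)
    return("distances must have one entry per rank")
  if (object@tieCount < 1L) return("tieCount must be at least 1")
  if (abs(object@maxDistance - max(object@distances)) > 1e-9)
    return("maxDistance must equal the maximum of the distance profile")
  TRUE
})

#' StabilityTable: cutoff behavior under stepwise low-tail truncation
#'
#' Result of [truncationSweep()]: for each step, the lowest-ranked records are
#' removed, the remainder re-ranked, the chord re-fit and the cutoff
#' recomputed, and the new shortlist compared as an identifier set against the
#' full-data shortlist. This emulates the detection dropout of low-abundance
#' variables in high-throughput assays.
#'
#' @slot steps data.frame with one row per truncation step and columns
#'   `removed_count`, `removed_fraction`, `cutoff_rank`, `cutoff_id`,
#'   `shortlist_size`, `shortlist_percent_of_full`, `overlap_with_full`,
#'   `stable`.
#' @slot increment integer; number of records removed per step.
#' @slot fullShortlistSize integer; shortlist size on the complete data.
#' @slot maxStableFraction numeric; largest removed fraction within the
#'   contiguous run of stable steps starting at zero removal.
#'
#' @seealso [truncationSweep()]
#' @export
setClass("StabilityTable",
  slots = c(steps = "data.frame", increment = "integer",
            fullShortlistSize = "integer", maxStableFraction = "numeric"))

setValidity("StabilityTable", function(object) {
  need <- c("removed_count", "removed_fraction", "cutoff_rank", "cutoff_id",
            "shortlist_size", "shortlist_percent_of_full",
            "overlap_with_full", "stable")
  if (!all(need %in% names(object@steps)))
    return(paste("steps must have columns:", paste(need, collapse = ", ")))
  rc <- object@steps$removed_count
  if (length(rc) && (rc[1L] != 0L || is.unsorted(rc, strictly = TRUE)))
    return("removed_count must start at 0 and increase strictly")
  if (object@increment < 1L) return("increment must be at least 1")
  TRUE
})
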