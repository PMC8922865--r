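#' Stability of the cutoff under stepwise low-tail truncation
#'
#' High-throughput assays detect low-abundance variables unreliably, so the
#' size of a dataset varies at its low-value end. This sweep emulates that
#' dropout deterministically: at each step the `removed_count` lowest-ranked
#' records are dropped, the remainder re-ranked `1..N'`, the chord re-fit and
#' the cutoff recomputed from scratch, and the resulting shortlist compared —
#' as an identifier set — with the full-data shortlist.
#'
#' Stability is judged on shortlist identity (the biologically meaningful
#' output); the per-step cutoff identifier and rank are also reported so
#' rank-based and variable-based readings can be inspected. The sweep stops
#' before the remaining profile becomes invalid (fewer than 3 records, or
#' flat).
#'
#' @param profile a [RankedProfile-class].
#' @param increment records removed per step; default 1000, the granularity
#'   used for genome-scale expression tables. For small datasets use
#'   `incrementFrac` instead.
#' @param incrementFrac optional fraction of N to use as the increment
#'   (overrides `increment` when given).
#' @return a [StabilityTable-class]. Step 0 (no removal) always reproduces
#'   the full-data cutoff, with `shortlist_percent_of_full = 100` and
#'   `stable = TRUE`.
#' @examples
#' prof <- rankProfile(generateBiphasic(n = 2000, kneeRank = 1900))
#' truncationSweep(prof, increment = 100)
#' @export
truncationSweep <- function(profile, increment = 1000L,
                            incrementFrac = NULL) {
  stopifnot(is(profile, "RankedProfile"))
  n <- length(profile)
  if (!is.null(incrementFrac)) {
    if (!is.numeric(incrementFrac) || incrementFrac <= 0 ||
        incrementFrac >= 1)
      stopKneecut("validation_error",
                  "incrementFrac must lie strictly between 0 and 1")
    increment <- max(1L, as.integer(round(incrementFrac * n)))
  }
  increment <- as.integer(increment)
  if (length(increment) != 1L || is.na(increment) || increment < 1L)
    stopKneecut("validation_error", "increment must be a positive integer")

  full <- findCutoff(profile)
  fullSet <- profile@ids[seq_len(n) > full@rank]
  fullSize <- length(fullSet)

  removed <- 0L
  rows <- list()
  while (n - removed >= 3L) {
    ids <- profile@ids[(removed + 1L):n]
    vals <- profile@values[(removed + 1L):n]
    if (vals[length(vals)] == vals[1L]) {
      message(sprintf(
        "truncation sweep stopped at %d removed: remaining profile is flat",
        removed))
      break
    }
    # fresh, independent recomputation on the truncated data -- no
    # incremental shortcuts that could drift from a direct run
    sub <- rankProfile(ids, vals)
    cut <- findCutoff(sub)
    set <- recordIds(sub)[ranks(sub) > cutoffRank(cut)]
    rows[[length(rows) + 1L]] <- data.frame(
      removed_count = removed,
      removed_fraction = removed / n,
      cutoff_rank = cutoffRank(cut),
      cutoff_id = cutoffId(cut),
      shortlist_size = shortlistSize(cut),
      shortlist_percent_of_full =
        if (fullSize > 0) 100 * length(set) / fullSize
        else if (length(set) == 0L) 100 else Inf,
      overlap_with_full = shortlistOverlap(set, fullSet),
      stable = setequal(set, fullSet),
      stringsAsFactors = FALSE)
    removed <- removed + increment
  }
  steps <- do.call(rbind, rows)

  stablePrefix <- cumprod(steps$stable) > 0
  new("StabilityTable", steps = steps, increment = increment,
      fullShortlistSize = as.integer(fullSize),
      maxStableFraction = max(steps$removed_fraction[stablePrefix]))
}

#' Fractional overlap of a shortlist with a reference shortlist
#'
#' `|a intersect b| / |b|`, with `b` the reference (full-data) shortlist.
#' Returns 1 when the sets are identical and, by convention, 1 when both are
#' empty (an empty shortlist trivially reproduces an empty reference);
#' 0 when only the reference is empty.
#'
#' @param a character vector of identifiers (set semantics; duplicates
#'   ignored).
#' @param b reference identifier set.
#' @return fraction in `[0, 1]`.
#' @examples
#' shortlistOverlap(c("x", "y"), c("x", "y", "z", "w"))   # 0.5
#' @export
shortlistOverlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(b) == 0L) return(if (length(a) == 0L) 1 else 0)
  length(intersect(a, b)) / length(b)
}
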