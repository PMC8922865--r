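#' Per-rank perpendicular distances to the chord
#'
#' Computes, for every rank of the profile, the length of the perpendicular
#' segment from the ranked curve to the chord. The distances at rank 1 and
#' rank N are zero (the chord passes through those points); the cutoff is the
#' rank where the distance peaks.
#'
#' @param profile a [RankedProfile-class].
#' @param chord optionally, a pre-fit [Chord-class]; fit from `profile` when
#'   `NULL`.
#' @return numeric vector of non-negative distances aligned with ranks
#'   `1..N`.
#' @examples
#' prof <- rankProfile(paste0("g", 1:5), c(0, 0, 0, 0, 10))
#' distanceProfile(prof)
#' @export
distanceProfile <- function(profile, chord = NULL) {
  stopifnot(is(profile, "RankedProfile"))
  if (is.null(chord)) chord <- fitChord(profile)
  .chordDistance(seq_along(profile@values), profile@values, chord)
}

#' Locate the cutoff rank of a ranked profile
#'
#' Identifies the bending point of the biphasic ranked curve: the rank whose
#' perpendicular distance to the chord (first ranked point to last) is
#' largest. Records ranked strictly above the cutoff form the shortlist of
#' variables assumed to dominate the system; the cutoff record itself is
#' excluded.
#'
#' Ties for the maximum distance (exact binary equality) are resolved to the
#' largest rank, giving the smallest — most stringent — shortlist; the number
#' of tied ranks is reported in `tieCount`. On a profile that is exactly a
#' straight line every distance is zero, so all N ranks tie, rank N is
#' returned and the shortlist is empty.
#'
#' @param profile a [RankedProfile-class]; must not be flat (see
#'   [fitChord()]).
#' @return a [CutoffResult-class].
#' @examples
#' prof <- rankProfile(paste0("g", 1:5), c(0, 0, 0, 0, 10))
#' findCutoff(prof)   # cutoff at rank 4, shortlist of 1
#' @export
findCutoff <- function(profile) {
  stopifnot(is(profile, "RankedProfile"))
  chord <- fitChord(profile)
  d <- .chordDistance(seq_along(profile@values), profile@values, chord)
  dmax <- max(d)
  tied <- which(d == dmax)
  rank <- tied[length(tied)]
  n <- length(d)
  new("CutoffResult",
      rank = as.integer(rank), id = profile@ids[rank],
      value = profile@values[rank], distance = d[rank], maxDistance = dmax,
      shortlistSize = as.integer(n - rank), tieCount = length(tied),
      n = as.integer(n), chord = chord, distances = d,
      referenceRank = as.integer(rank), stringencyOffset = 0)
}

#' Extract the shortlist of records above the cutoff
#'
#' Returns the records ranked strictly above the cutoff rank — the small
#' dominant set — ordered by rank descending, so the highest value comes
#' first. With N records and cutoff rank k the shortlist spans ranks
#' `k+1 .. N` and has `N - k` members.
#'
#' @param profile the [RankedProfile-class] the cutoff was computed from.
#' @param cutoff the matching [CutoffResult-class].
#' @return data.frame with columns `id`, `rank`, `value`, `distance`,
#'   highest-ranked record first; zero rows when the cutoff rank is N.
#' @examples
#' prof <- rankProfile(paste0("g", 1:5), c(0, 0, 0, 0, 10))
#' extractShortlist(prof, findCutoff(prof))
#' @export
extractShortlist <- function(profile, cutoff) {
  stopifnot(is(profile, "RankedProfile"), is(cutoff, "CutoffResult"))
  if (length(profile) != cutoff@n)
    stopKneecut("validation_error",
                "cutoff was computed from a profile of different size")
  idx <- rev(seq_len(length(profile)))
  idx <- idx[idx > cutoff@rank]
  data.frame(id = profile@ids[idx], rank = idx, value = profile@values[idx],
             distance = cutoff@distances[idx], stringsAsFactors = FALSE)
}

#' Low-tail control list of lowest-ranked non-zero records
#'
#' Builds the negative-control list used to contrast a shortlist: the `size`
#' lowest-ranked records among those with value strictly greater than zero.
#' Zero-valued records take part in the cutoff computation but are excluded
#' here, since an all-zero "control" carries no signal.
#'
#' @param profile a [RankedProfile-class].
#' @param size number of records requested; must not exceed the number of
#'   records with positive value.
#' @return data.frame with columns `id`, `rank`, `value`, lowest rank first.
#' @examples
#' prof <- rankProfile(paste0("g", 1:6), c(0, 0, 1, 2, 3, 9))
#' lowTailControlList(prof, 2)   # the records valued 1 and 2
#' @export
lowTailControlList <- function(profile, size) {
  stopifnot(is(profile, "RankedProfile"))
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L)
    stopKneecut("validation_error", "size must be a positive integer")
  nonzero <- which(profile@values > 0)
  if (size > length(nonzero))
    stopKneecut("size_error", sprintf(
      "requested %d records but only %d have non-zero values",
      size, length(nonzero)))
  idx <- nonzero[seq_len(size)]
  data.frame(id = profile@ids[idx], rank = idx, value = profile@values[idx],
             stringsAsFactors = FALSE)
}

#' Shift a cutoff by a stringency offset
#'
#' The identified cutoff is a reproducible reference point; applications
#' wanting a more or less stringent shortlist can shift it by a signed
#' fraction of the profile size. The new rank is
#' `clamp(round(referenceRank + offset * N), 1, N)`; the unadjusted rank is
#' retained in `referenceRank` for reporting. A positive offset moves the
#' cutoff up-rank (smaller shortlist).
#'
#' @param cutoff a [CutoffResult-class].
#' @param profile the [RankedProfile-class] it was computed from.
#' @param stringencyOffset signed fraction in (-1, 1).
#' @return a [CutoffResult-class] with all rank-derived fields recomputed;
#'   `maxDistance` still reports the global maximum while `distance` gives
#'   the distance at the adjusted rank.
#' @examples
#' prof <- rankProfile(paste0("g", 1:100), c(rep(0, 90), 1:10))
#' cut <- findCutoff(prof)
#' adjustCutoff(cut, prof, 0.05)
#' @export
adjustCutoff <- function(cutoff, profile, stringencyOffset) {
  stopifnot(is(cutoff, "CutoffResult"), is(profile, "RankedProfile"))
  if (!is.numeric(stringencyOffset) || length(stringencyOffset) != 1L ||
      is.na(stringencyOffset) ||
      stringencyOffset <= -1 || stringencyOffset >= 1)
    stopKneecut("validation_error",
                "stringency offset must lie strictly between -1 and 1")
  if (length(profile) != cutoff@n)
    stopKneecut("validation_error",
                "cutoff was computed from a profile of different size")
  n <- cutoff@n
  newRank <- as.integer(min(max(
    round(cutoff@referenceRank + stringencyOffset * n), 1), n))
  new("CutoffResult",
      rank = newRank, id = profile@ids[newRank],
      value = profile@values[newRank], distance = cutoff@distances[newRank],
      maxDistance = cutoff@maxDistance,
      shortlistSize = as.integer(n - newRank), tieCount = cutoff@tieCount,
      n = n, chord = cutoff@chord, distances = cutoff@distances,
      referenceRank = cutoff@referenceRank,
      stringencyOffset = stringencyOffset)
}
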