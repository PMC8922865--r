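#' @name kneecut-accessors
#' @title Accessors for kneecut result objects
#'
#' @description Slot accessors for [RankedProfile-class], [Chord-class],
#' [CutoffResult-class] and [StabilityTable-class] objects. Use these rather
#' than `@` access.
#'
#' @param x a kneecut object.
#' @return `recordIds` and `recordValues` return vectors aligned with ranks
#'   `1..n`; `ranks` returns the integer sequence `1..n`; `chordSlope`,
#'   `chordIntercept`, `cutoffRank`, `cutoffId`, `cutoffValue`,
#'   `maxDistance`, `shortlistSize`, `tieCount` and `referenceRank` return
#'   scalars; `distances` returns the per-rank perpendicular distances;
#'   `stabilitySteps` returns the per-step data.frame of a sweep.
#'
#' @examples
#' prof <- rankProfile(c("a", "b", "c", "d", "e"), c(0, 0, 0, 0, 10))
#' cut <- findCutoff(prof)
#' cutoffRank(cut)
#' shortlistSize(cut)
NULL

#' @rdname kneecut-accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname kneecut-accessors
#' @export
setGeneric("recordValues", function(x) standardGeneric("recordValues"))

#' @rdname kneecut-accessors
#' @export
setGeneric("ranks", function(x) standardGeneric("ranks"))

#' @rdname kneecut-accessors
#' @export
setGeneric("chordSlope", function(x) standardGeneric("chordSlope"))

#' @rdname kneecut-accessors
#' @export
setGeneric("chordIntercept", function(x) standardGeneric("chordIntercept"))

#' @rdname kneecut-accessors
#' @export
setGeneric("cutoffRank", function(x) standardGeneric("cutoffRank"))

#' @rdname kneecut-accessors
#' @export
setGeneric("cutoffId", function(x) standardGeneric("cutoffId"))

#' @rdname kneecut-accessors
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname kneecut-accessors
#' @export
setGeneric("maxDistance", function(x) standardGeneric("maxDistance"))

#' @rdname kneecut-accessors
#' @export
setGeneric("shortlistSize", function(x) standardGeneric("shortlistSize"))

#' @rdname kneecut-accessors
#' @export
setGeneric("tieCount", function(x) standardGeneric("tieCount"))

#' @rdname kneecut-accessors
#' @export
setGeneric("referenceRank", function(x) standardGeneric("referenceRank"))

#' @rdname kneecut-accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname kneecut-accessors
#' @export
setGeneric("stabilitySteps", function(x) standardGeneric("stabilitySteps"))
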