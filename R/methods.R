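# Accessors, show() and coercion methods.

#' @rdname kneecut-accessors
#' @aliases recordIds,RankedProfile-method
setMethod("recordIds", "RankedProfile", function(x) x@ids)

#' @rdname kneecut-accessors
#' @aliases recordValues,RankedProfile-method
setMethod("recordValues", "RankedProfile", function(x) x@values)

#' @rdname kneecut-accessors
#' @aliases ranks,RankedProfile-method
setMethod("ranks", "RankedProfile", function(x) seq_along(x@values))

#' Number of records in a RankedProfile
#' @param x a [RankedProfile-class].
#' @return integer record count.
#' @export
setMethod("length", "RankedProfile", function(x) length(x@values))

#' @rdname kneecut-accessors
#' @aliases chordSlope,Chord-method
setMethod("chordSlope", "Chord", function(x) x@slope)

#' @rdname kneecut-accessors
#' @aliases chordIntercept,Chord-method
setMethod("chordIntercept", "Chord", function(x) x@intercept)

#' @rdname kneecut-accessors
#' @aliases chordSlope,CutoffResult-method
setMethod("chordSlope", "CutoffResult", function(x) x@chord@slope)

#' @rdname kneecut-accessors
#' @aliases chordIntercept,CutoffResult-method
setMethod("chordIntercept", "CutoffResult", function(x) x@chord@intercept)

#' @rdname kneecut-accessors
#' @aliases cutoffRank,CutoffResult-method
setMethod("cutoffRank", "CutoffResult", function(x) x@rank)

#' @rdname kneecut-accessors
#' @aliases cutoffId,CutoffResult-method
setMethod("cutoffId", "CutoffResult", function(x) x@id)

#' @rdname kneecut-accessors
#' @aliases cutoffValue,CutoffResult-method
setMethod("cutoffValue", "CutoffResult", function(x) x@value)

#' @rdname kneecut-accessors
#' @aliases maxDistance,CutoffResult-method
setMethod("maxDistance", "CutoffResult", function(x) x@maxDistance)

#' @rdname kneecut-accessors
#' @aliases shortlistSize,CutoffResult-method
setMethod("shortlistSize", "CutoffResult", function(x) x@shortlistSize)

#' @rdname kneecut-accessors
#' @aliases tieCount,CutoffResult-method
setMethod("tieCount", "CutoffResult", function(x) x@tieCount)

#' @rdname kneecut-accessors
#' @aliases referenceRank,CutoffResult-method
setMethod("referenceRank", "CutoffResult", function(x) x@referenceRank)

#' @rdname kneecut-accessors
#' @aliases distances,CutoffResult-method
setMethod("distances", "CutoffResult", function(x) x@distances)

#' @rdname kneecut-accessors
#' @aliases stabilitySteps,StabilityTable-method
setMethod("stabilitySteps", "StabilityTable", function(x) x@steps)

setMethod("show", "RankedProfile", function(object) {
  n <- length(object@values)
  cat(sprintf("RankedProfile with %d records\n", n))
  cat(sprintf("  value range: [%g, %g]\n",
              object@values[1L], object@values[n]))
  cat(sprintf("  zero-valued records: %d\n", sum(object@values == 0)))
})

setMethod("show", "Chord", function(object) {
  cat(sprintf("Chord: y = %g x %s %g\n", object@slope,
              if (object@intercept < 0) "-" else "+",
              abs(object@intercept)))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf("CutoffResult on %d records\n", object@n))
  cat(sprintf("  cutoff rank: %d (%s, value %g)\n",
              object@rank, object@id, object@value))
  cat(sprintf("  max perpendicular distance: %g\n", object@maxDistance))
  cat(sprintf("  shortlist size (ranks > cutoff): %d\n",
              object@shortlistSize))
  if (object@tieCount > 1L)
    cat(sprintf("  note: %d ranks tied for the maximum distance\n",
                object@tieCount))
  if (object@rank != object@referenceRank)
    cat(sprintf("  stringency offset %+g applied (reference rank %d)\n",
                object@stringencyOffset, object@referenceRank))
})

setMethod("show", "StabilityTable", function(object) {
  cat(sprintf("StabilityTable: %d steps, increment %d\n",
              nrow(object@steps), object@increment))
  cat(sprintf("  full-data shortlist size: %d\n", object@fullShortlistSize))
  cat(sprintf("  shortlist stable up to %.1f%% of records removed\n",
              100 * object@maxStableFraction))
})

#' Coerce a RankedProfile to a data.frame
#'
#' @param x a [RankedProfile-class].
#' @param row.names,optional,... passed through for signature compatibility.
#' @return data.frame with columns `rank`, `id`, `value`.
#' @export
as.data.frame.RankedProfile <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(rank = seq_along(x@values), id = x@ids, value = x@values,
             stringsAsFactors = FALSE)
}

#' Coerce a StabilityTable to its per-step data.frame
#'
#' @param x a [StabilityTable-class].
#' @param row.names,optional,... passed through for signature compatibility.
#' @return the per-step data.frame.
#' @export
as.data.frame.StabilityTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  x@steps
}
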