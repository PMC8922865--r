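#' Perpendicular from a ranked point to the chord, step by step
#'
#' For a point `(R, V)` of the ranked curve and a chord `y = m x + b`, the
#' line through the point perpendicular to the chord is
#' `y = (-1/m) x + bC` with `bC = V - (-1/m) R`. Equating the two lines gives
#' the foot of the perpendicular on the chord:
#' `yFoot = (b + bC m^2) / (1 + m^2)` and `xFoot = (yFoot - b) / m`.
#'
#' This stepwise construction is exposed mainly as a transparent reference;
#' production code uses the algebraically equivalent residual form (see
#' [segmentLengthClosed()]).
#'
#' @param R rank (x coordinate) of the curve point; vectorized.
#' @param V value (y coordinate) of the curve point; vectorized.
#' @param chord a [Chord-class] with nonzero slope.
#' @return a list with elements `x`, `y` (the curve point), `perpIntercept`
#'   (`bC`), and `footX`, `footY` (the foot on the chord).
#'
#' @details A horizontal chord (`m = 0`) makes the perpendicular slope `-1/m`
#' undefined; a `kneecut_degenerate_error` is raised.
#'
#' @examples
#' ch <- new("Chord", slope = 2, intercept = 0)
#' perpendicularGeometry(3, 4, ch)   # bC = 5.5, foot at (2.2, 4.4)
#' @export
perpendicularGeometry <- function(R, V, chord) {
  stopifnot(is(chord, "Chord"))
  m <- chord@slope
  b <- chord@intercept
  if (m == 0)
    stopKneecut("degenerate_error",
                "horizontal chord: perpendicular slope -1/m is undefined")
  bC <- V - (-1 / m) * R
  yFoot <- (b + bC * m^2) / (1 + m^2)
  xFoot <- (yFoot - b) / m
  list(x = R, y = V, perpIntercept = bC, footX = xFoot, footY = yFoot)
}

#' Perpendicular segment length via the explicit foot construction
#'
#' Length of the segment from the curve point `(R, V)` to the foot of its
#' perpendicular on the chord, computed with the Pythagorean theorem from the
#' coordinates returned by [perpendicularGeometry()].
#'
#' @inheritParams perpendicularGeometry
#' @return non-negative distance(s), vectorized over `R` and `V`.
#' @examples
#' ch <- new("Chord", slope = 2, intercept = 0)
#' segmentLengthStepwise(3, 4, ch)   # sqrt(0.8)
#' @export
segmentLengthStepwise <- function(R, V, chord) {
  g <- perpendicularGeometry(R, V, chord)
  sqrt((g$footX - g$x)^2 + (g$footY - g$y)^2)
}

#' Perpendicular segment length, closed form
#'
#' Single-expression distance from the curve point `(R, V)` to the chord
#' `y = m x + b`:
#' \deqn{D = \sqrt{\frac{(Vm - bm - Rm^2)^2 + (b + mR - V)^2}{(1+m^2)^2}}}
#' which simplifies to `|V - mR - b| / sqrt(1 + m^2)`, the standard
#' point-to-line distance. Both forms are evaluated here exactly as written
#' so the simplification can be machine-verified; the simplified residual
#' form is the production path used by [distanceProfile()].
#'
#' @inheritParams perpendicularGeometry
#' @param simplified logical; if `TRUE` (default) evaluate the residual form,
#'   otherwise the unsimplified closed form above.
#' @return non-negative distance(s), vectorized over `R` and `V`.
#' @examples
#' ch <- new("Chord", slope = 2, intercept = 0)
#' segmentLengthClosed(3, 4, ch)
#' segmentLengthClosed(3, 4, ch, simplified = FALSE)
#' @export
segmentLengthClosed <- function(R, V, chord, simplified = TRUE) {
  stopifnot(is(chord, "Chord"))
  m <- chord@slope
  b <- chord@intercept
  if (simplified)
    return(abs(V - m * R - b) / sqrt(1 + m * m))
  sqrt(((V * m - b * m - R * m^2)^2 + (b + m * R - V)^2) / (1 + m^2)^2)
}
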