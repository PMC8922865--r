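#' Fit the chord through the first and last ranked points
#'
#' The chord is the straight line `y = m x + b` through `(1, V_min)` and
#' `(N, V_max)` of the ranked curve, so `m = (V_max - V_min) / (N - 1)` and
#' `b = V_min - m`. For a profile whose minimum value is 0 the intercept
#' equals `-m`, i.e. the line has the form `y = m x - m`.
#'
#' @param profile a [RankedProfile-class].
#' @return a [Chord-class].
#'
#' @details A flat profile (all values equal) has a horizontal chord; no
#' bending point exists and the perpendicular construction degenerates, so a
#' `kneecut_degenerate_error` is raised rather than returning a cutoff.
#'
#' @examples
#' prof <- rankProfile(c("a", "b", "c"), c(0, 1, 10))
#' fitChord(prof)   # y = 5x - 5
#' @export
fitChord <- function(profile) {
  stopifnot(is(profile, "RankedProfile"))
  v <- profile@values
  n <- length(v)
  if (v[n] == v[1L])
    stopKneecut("degenerate_error",
                "flat profile: all values are equal, no bending point exists")
  m <- (v[n] - v[1L]) / (n - 1)
  new("Chord", slope = m, intercept = v[1L] - m)
}

# Perpendicular distance from points (R, V) to the chord, simplified form
# |V - m R - b| / sqrt(1 + m^2). Algebraically identical to the stepwise
# perpendicular-foot construction and to its closed form; numerically the
# most stable of the three. Vectorized over R and V.
.chordDistance <- function(R, V, chord) {
  m <- chord@slope
  abs(V - m * R - chord@intercept) / sqrt(1 + m * m)
}
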