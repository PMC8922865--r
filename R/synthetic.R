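#' Generate a synthetic biphasic ranked dataset with a known knee
#'
#' Produces an id/value table whose noiseless ranked curve is biphasic: a
#' long first phase of values growing slowly with rank, then a short second
#' phase growing rapidly, with a convex junction exactly at `kneeRank`. Two
#' phase families are available: piecewise linear (slopes `s1 < s2`) and
#' piecewise exponential (per-rank rates `r1 < r2`), the simplest shapes
#' matching the biphasic description while admitting exact ground truth.
#'
#' Defaults emulate the scale of a genome-wide consensus expression table:
#' 16,353 records with the knee placed at rank 15,778, so the ground-truth
#' shortlist holds 575 records (about 3.5\% of the data).
#'
#' Identifiers are zero-padded so lexicographic order equals construction
#' order; with noiseless ties (e.g. a flat `s1 = 0` first phase) the
#' canonical tie-break of [rankProfile()] therefore preserves construction
#' ranks. Optional Gaussian noise (`noiseSd`, additive, in value units) is
#' applied to the values *before* ranking — ranking is part of the method
#' under test — and perturbed values are clamped at 0, consistent with
#' non-negative abundance data.
#'
#' @param n total record count.
#' @param kneeRank ground-truth junction rank, in `[3, n - 1]`.
#' @param model `"linear"` or `"exponential"`.
#' @param s1,s2 linear-phase slopes per rank, `0 <= s1 < s2`.
#' @param r1,r2 exponential-phase rates per rank, `0 < r1 < r2` (used when
#'   `model = "exponential"`).
#' @param noiseSd standard deviation of additive Gaussian noise, value
#'   units; 0 for a noiseless profile.
#' @param seed optional integer seed; generation is reproducible for a fixed
#'   seed, and the caller's RNG state is restored on exit.
#' @param prefix identifier prefix.
#' @return data.frame with columns `id` and `value`, in construction order
#'   (pass to [rankProfile()] to rank).
#' @examples
#' generateBiphasic(n = 5, kneeRank = 4, s1 = 0, s2 = 10)  # values 0,0,0,0,10
#' @export
generateBiphasic <- function(n = 16353L, kneeRank = 15778L,
                             model = c("linear", "exponential"),
                             s1 = 0.01, s2 = 1, r1 = 5e-4, r2 = 5e-3,
                             noiseSd = 0, seed = NULL, prefix = "g") {
  model <- match.arg(model)
  n <- as.integer(n)
  kneeRank <- as.integer(kneeRank)
  if (is.na(n) || n < 4L)
    stopKneecut("validation_error", "n must be at least 4")
  if (is.na(kneeRank) || kneeRank < 3L || kneeRank > n - 1L)
    stopKneecut("validation_error", "kneeRank must lie in [3, n - 1]")
  if (!is.numeric(noiseSd) || noiseSd < 0)
    stopKneecut("validation_error", "noiseSd must be non-negative")

  i <- seq_len(n)
  if (model == "linear") {
    if (!(s1 >= 0 && s2 > s1))
      stopKneecut("validation_error", "need 0 <= s1 < s2")
    v <- ifelse(i <= kneeRank, s1 * (i - 1),
                s1 * (kneeRank - 1) + s2 * (i - kneeRank))
  } else {
    if (!(r1 > 0 && r2 > r1))
      stopKneecut("validation_error", "need 0 < r1 < r2")
    # phase 1 grows as exp(r1 * rank) - 1; phase 2 continues
    # multiplicatively at the faster rate r2, which keeps the junction
    # convex for any r2 > r1
    vk <- expm1(r1 * (kneeRank - 1))
    v <- ifelse(i <= kneeRank, expm1(r1 * (i - 1)),
                (vk + 1) * exp(r2 * (i - kneeRank)) - 1)
  }

  if (noiseSd > 0) {
    if (!is.null(seed)) {
      if (!exists(".Random.seed", envir = globalenv()))
        set.seed(NULL)
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
      set.seed(as.integer(seed))
    }
    v <- pmax(0, v + stats::rnorm(n, sd = noiseSd))
  }

  data.frame(id = sprintf("%s%0*d", prefix, nchar(as.character(n)), i),
             value = v, stringsAsFactors = FALSE)
}

#' Degenerate fixtures for edge-case behavior
#'
#' Small id/value tables covering the degenerate inputs a cutoff tool must
#' handle deliberately. Expected behavior:
#' \describe{
#'   \item{`flat`}{all values equal: [fitChord()] and [findCutoff()] raise a
#'     degenerate-profile error — a flat curve has no bending point.}
#'   \item{`all_zero`}{all values 0: same degenerate-profile error.}
#'   \item{`line`}{values exactly on a straight line: every distance is 0,
#'     all N ranks tie, [findCutoff()] returns rank N (largest-rank tie
#'     rule) with an empty shortlist and `tieCount = N`.}
#'   \item{`two_records`}{fewer than 3 records: [rankProfile()] raises a
#'     size error.}
#'   \item{`single_spike`}{one non-zero value among zeros: a valid profile;
#'     the cutoff lands at rank N - 1 and the spike alone is shortlisted.}
#'   \item{`massive_ties`}{many repeated values: valid; ties are broken by
#'     identifier so the ranking is still canonical.}
#' }
#'
#' @return named list of data.frames with columns `id`, `value`.
#' @examples
#' names(degenerateFixtures())
#' @export
degenerateFixtures <- function() {
  mk <- function(values, prefix = "v")
    data.frame(id = sprintf("%s%02d", prefix, seq_along(values)),
               value = values, stringsAsFactors = FALSE)
  list(
    flat = mk(rep(1, 10)),
    all_zero = mk(rep(0, 10)),
    line = mk(0:9),
    two_records = mk(c(1, 2)),
    single_spike = mk(c(rep(0, 9), 10)),
    massive_ties = mk(rep(c(0, 1, 5), times = c(20, 20, 2)))
  )
}
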