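#' Plot a ranked profile with its chord and cutoff
#'
#' Draws the ranked value curve, the chord connecting its first and last
#' points, and — when a cutoff is supplied — a red vertical line at the
#' cutoff rank separating the low-value background from the shortlist.
#'
#' @param profile a [RankedProfile-class].
#' @param cutoff optional [CutoffResult-class] computed from `profile`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotRankedProfile <- function(profile, cutoff = NULL,
                              main = "Ranked value distribution", ...) {
  r <- ranks(profile)
  v <- recordValues(profile)
  graphics::plot(r, v, type = "l", lwd = 2, xlab = "Rank", ylab = "Value",
                 main = main, ...)
  graphics::segments(r[1L], v[1L], r[length(r)], v[length(v)],
                     col = "grey40", lty = 2)
  if (!is.null(cutoff)) {
    graphics::abline(v = cutoffRank(cutoff), col = "red", lwd = 2)
    graphics::mtext(sprintf("cutoff rank %d, shortlist %d",
                            cutoffRank(cutoff), shortlistSize(cutoff)),
                    side = 3, line = 0.2, cex = 0.8)
  }
  invisible(NULL)
}

#' Plot shortlist stability across a truncation sweep
#'
#' Shortlist size, as percent of the full-data shortlist, against the
#' fraction of lowest-value records removed.
#'
#' @param stability a [StabilityTable-class].
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotStability <- function(stability,
                          main = "Shortlist stability under truncation",
                          ...) {
  st <- stabilitySteps(stability)
  graphics::plot(100 * st$removed_fraction, st$shortlist_percent_of_full,
                 type = "b", pch = 19, xlab = "Records removed (%)",
                 ylab = "Shortlist size (% of full data)", main = main, ...)
  graphics::abline(h = 100, col = "grey60", lty = 3)
  invisible(NULL)
}
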