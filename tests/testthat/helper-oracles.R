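# Independent oracles and small fixture builders, used to cross-check the
# package's production paths.

# Distance of (R, V) to the line y = m x + b via the explicit
# perpendicular-foot construction, written out step by step and
# independently of the package's implementation.
oracleFootDistance <- function(R, V, m, b) {
  stopifnot(m != 0)
  bC <- V - (-1 / m) * R                 # intercept of the perpendicular
  yF <- (b + bC * m^2) / (1 + m^2)       # foot ordinate
  xF <- (yF - b) / m                     # foot abscissa
  sqrt((xF - R)^2 + (yF - V)^2)          # Pythagoras
}

# Brute-force cutoff: evaluate the foot distance at every rank of a value
# vector (already sorted ascending) and take the argmax, largest rank on
# exact ties.
oracleCutoffRank <- function(values) {
  n <- length(values)
  m <- (values[n] - values[1]) / (n - 1)
  b <- values[1] - m
  d <- vapply(seq_len(n), function(r) oracleFootDistance(r, values[r], m, b),
              numeric(1))
  max(which(d == max(d)))
}

# Convex two-segment polyline with junction at rank k.
twoSegmentValues <- function(n, k, s1, s2) {
  i <- seq_len(n)
  ifelse(i <= k, s1 * (i - 1), s1 * (k - 1) + s2 * (i - k))
}

padIds <- function(n, prefix = "g") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

microProfile <- function() {
  rankProfile(paste0("g", 1:5), c(0, 0, 0, 0, 10))
}

writeTempTable <- function(df, ext = ".tsv", sep = "\t") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
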