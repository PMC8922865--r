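test_that("the micro example yields cutoff rank 4 and a shortlist of 1", {
  prof <- microProfile()
  cut <- findCutoff(prof)
  expect_identical(cutoffRank(cut), 4L)
  expect_identical(cutoffId(cut), "g4")
  expect_identical(shortlistSize(cut), 1L)
  expect_equal(maxDistance(cut), oracleFootDistance(4, 0, 2.5, -2.5))
  short <- extractShortlist(prof, cut)
  expect_identical(short$id, "g5")
  expect_identical(short$rank, 5L)
})

test_that("cutoff lands on the junction of convex two-segment profiles", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(10:2000, 1)
    k <- sample(3:(n - 1), 1)
    s1 <- runif(1, 0, 1)
    s2 <- s1 + runif(1, 0.5, 5)
    prof <- rankProfile(padIds(n), twoSegmentValues(n, k, s1, s2))
    expect_identical(cutoffRank(findCutoff(prof)), as.integer(k))
  }
})

test_that("cutoff agrees with per-rank brute force on irregular profiles", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:400, 1)
    vals <- sort(runif(n, 0, 100))
    if (vals[n] == vals[1]) next
    prof <- rankProfile(padIds(n), vals)
    expect_identical(cutoffRank(findCutoff(prof)),
                     as.integer(oracleCutoffRank(recordValues(prof))))
  }
})

test_that("exact distance ties resolve to the largest rank", {
  # straight line: every distance is exactly 0, all N ranks tie
  prof <- rankProfile(padIds(10), as.numeric(0:9))
  cut <- findCutoff(prof)
  expect_identical(cutoffRank(cut), 10L)
  expect_identical(tieCount(cut), 10L)
  expect_identical(shortlistSize(cut), 0L)
  expect_identical(nrow(extractShortlist(prof, cut)), 0L)
})

test_that("the cutoff is invariant under positive affine value maps", {
  set.seed(29)
  for (i in 1:30) {
    n <- sample(10:1000, 1)
    vals <- sort(runif(n, 0, 50)^2)
    if (vals[n] == vals[1]) next
    prof <- rankProfile(padIds(n), vals)
    ref <- findCutoff(prof)
    a <- runif(1, 0.01, 100)
    c0 <- runif(1, 0, 100)
    mapped <- rankProfile(padIds(n), a * vals + c0)
    got <- findCutoff(mapped)
    expect_identical(cutoffRank(got), cutoffRank(ref))
    expect_identical(cutoffId(got), cutoffId(ref))
  }
})

test_that("shortlist is strictly above the cutoff and conserves counts", {
  prof <- rankProfile(padIds(200), twoSegmentValues(200, 150, 0.05, 2))
  cut <- findCutoff(prof)
  short <- extractShortlist(prof, cut)
  expect_identical(nrow(short), shortlistSize(cut))
  expect_identical(shortlistSize(cut) + cutoffRank(cut), 200L)
  expect_true(all(short$rank > cutoffRank(cut)))
  expect_false(cutoffId(cut) %in% short$id)
  expect_identical(short$rank, seq(200L, cutoffRank(cut) + 1L))  # descending
})

test_that("low-tail control list excludes zeros and respects size", {
  prof <- rankProfile(paste0("g", 1:6), c(0, 0, 1, 2, 3, 9))
  ctl <- lowTailControlList(prof, 2)
  expect_identical(ctl$value, c(1, 2))
  expect_identical(ctl$rank, 3:4)
  all4 <- lowTailControlList(prof, 4)
  expect_identical(nrow(all4), 4L)
  expect_error(lowTailControlList(prof, 5), class = "kneecut_size_error")

  # shortlist and equal-size control list never overlap when the cutoff
  # rank is at least the control size
  cut <- findCutoff(prof)
  short <- extractShortlist(prof, cut)
  if (nrow(short) > 0 && cutoffRank(cut) >= nrow(short)) {
    ctl2 <- lowTailControlList(prof, nrow(short))
    expect_length(intersect(short$id, ctl2$id), 0)
  }
})

test_that("stringency offsets shift, clamp, and keep the reference rank", {
  prof <- rankProfile(padIds(100), twoSegmentValues(100, 90, 0, 1))
  cut <- findCutoff(prof)
  expect_identical(cutoffRank(cut), 90L)

  same <- adjustCutoff(cut, prof, 0)
  expect_identical(cutoffRank(same), 90L)
  expect_identical(shortlistSize(same), shortlistSize(cut))

  up <- adjustCutoff(cut, prof, 0.05)
  expect_identical(cutoffRank(up), 95L)
  expect_identical(referenceRank(up), 90L)
  expect_identical(shortlistSize(up), 5L)

  down <- adjustCutoff(cut, prof, -0.1)
  expect_identical(cutoffRank(down), 80L)

  clamped <- adjustCutoff(adjustCutoff(cut, prof, 0.08), prof, 0.15)
  expect_identical(cutoffRank(clamped), 100L)
  expect_identical(shortlistSize(clamped), 0L)

  expect_error(adjustCutoff(cut, prof, 1), class = "kneecut_validation_error")
  expect_error(adjustCutoff(cut, prof, -1.2),
               class = "kneecut_validation_error")
})

test_that("flat profiles have no cutoff", {
  prof <- rankProfile(padIds(10), rep(3, 10))
  expect_error(findCutoff(prof), class = "kneecut_degenerate_error")
})
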