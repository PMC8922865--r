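test_that("the generator reproduces the tiny construction example", {
  d <- generateBiphasic(n = 5, kneeRank = 4, s1 = 0, s2 = 10, noiseSd = 0)
  expect_identical(d$value, c(0, 0, 0, 0, 10))
  expect_identical(d$id, paste0("g", 1:5))
})

test_that("noiseless profiles are non-decreasing and convex at the knee", {
  for (model in c("linear", "exponential")) {
    d <- generateBiphasic(n = 500, kneeRank = 460, model = model)
    v <- d$value
    expect_true(all(diff(v) >= 0))
    k <- 460
    secondDiff <- (v[k + 1] - v[k]) - (v[k] - v[k - 1])
    expect_gte(secondDiff, 0)
  }
})

test_that("find_cutoff recovers the knee of noiseless generated profiles", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(50:20000, 1)
    k <- sample(seq(max(3, floor(0.5 * n)), n - 1), 1)
    s1 <- runif(1, 0, 0.5)
    s2 <- s1 + runif(1, 0.2, 4)
    d <- generateBiphasic(n = n, kneeRank = k, s1 = s1, s2 = s2)
    expect_identical(cutoffRank(findCutoff(rankProfile(d))), as.integer(k))
  }
})

test_that("generation is reproducible for a fixed seed", {
  a <- generateBiphasic(n = 100, kneeRank = 90, noiseSd = 2, seed = 99)
  b <- generateBiphasic(n = 100, kneeRank = 90, noiseSd = 2, seed = 99)
  expect_identical(a, b)
  c <- generateBiphasic(n = 100, kneeRank = 90, noiseSd = 2, seed = 100)
  expect_false(identical(a, c))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(generateBiphasic(n = 50, kneeRank = 40, noiseSd = 1, seed = 7))
  expect_identical(runif(1), before)
})

test_that("noisy values stay non-negative and ranking absorbs the noise", {
  d <- generateBiphasic(n = 2000, kneeRank = 1900, s1 = 0.001, s2 = 1,
                        noiseSd = 5, seed = 3)
  expect_true(all(d$value >= 0))
  expect_gt(sum(d$value == 0), 0)  # clamping visibly active at this sd
  expect_s4_class(rankProfile(d), "RankedProfile")
})

test_that("noisy knee recovery stays within the characterized bands", {
  # regression baseline measured on this generator: at additive noise of
  # 1% of the phase-2 amplitude the recovered cutoff stays within 1% of n
  # of the true knee; at 5% noise it stays within 3% of n (the bend
  # flattens and shifts down-rank once re-ranked noise smooths it).
  n <- 5000; k <- 4825; amp2 <- 1 * (n - k)
  recover <- function(rel, i) {
    d <- generateBiphasic(n = n, kneeRank = k, s1 = 0.01, s2 = 1,
                          noiseSd = rel * amp2, seed = 1000 + i)
    cutoffRank(findCutoff(rankProfile(d)))
  }
  dev1 <- abs(vapply(1:100, function(i) recover(0.01, i), numeric(1)) - k)
  expect_gte(mean(dev1 <= 0.01 * n), 0.95)
  dev5 <- abs(vapply(1:100, function(i) recover(0.05, i), numeric(1)) - k)
  expect_gte(mean(dev5 <= 0.03 * n), 0.95)
})

test_that("invalid generator specs are rejected", {
  expect_error(generateBiphasic(n = 3, kneeRank = 2),
               class = "kneecut_validation_error")
  expect_error(generateBiphasic(n = 100, kneeRank = 100),
               class = "kneecut_validation_error")
  expect_error(generateBiphasic(n = 100, kneeRank = 90, s1 = 2, s2 = 1),
               class = "kneecut_validation_error")
  expect_error(generateBiphasic(n = 100, kneeRank = 90, noiseSd = -1),
               class = "kneecut_validation_error")
  expect_error(generateBiphasic(n = 100, kneeRank = 90,
                                model = "exponential", r1 = 0.1, r2 = 0.1),
               class = "kneecut_validation_error")
})

test_that("degenerate fixtures behave as documented", {
  fx <- degenerateFixtures()
  expect_true(all(c("flat", "all_zero", "line", "two_records",
                    "single_spike", "massive_ties") %in% names(fx)))

  expect_error(findCutoff(rankProfile(fx$flat)),
               class = "kneecut_degenerate_error")
  expect_error(findCutoff(rankProfile(fx$all_zero)),
               class = "kneecut_degenerate_error")
  expect_error(rankProfile(fx$two_records), class = "kneecut_size_error")

  lineCut <- findCutoff(rankProfile(fx$line))
  expect_identical(cutoffRank(lineCut), nrow(fx$line))
  expect_identical(tieCount(lineCut), nrow(fx$line))
  expect_identical(shortlistSize(lineCut), 0L)

  spike <- rankProfile(fx$single_spike)
  spikeCut <- findCutoff(spike)
  expect_identical(cutoffRank(spikeCut), length(spike) - 1L)
  expect_identical(extractShortlist(spike, spikeCut)$value, 10)

  ties <- rankProfile(fx$massive_ties)
  expect_s4_class(findCutoff(ties), "CutoffResult")
})
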