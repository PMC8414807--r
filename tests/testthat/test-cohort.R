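test_that("generation is bit-identical for a fixed spec and seed, and seed-sensitive", {
  spec <- defaultCohortSpec(n = 100L, seed = 31L)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  attr(c1, "provenance") <- attr(c2, "provenance") <- NULL
  expect_identical(c1, c2)
  c3 <- generateCohort(defaultCohortSpec(n = 100L, seed = 32L))
  expect_false(isTRUE(all.equal(c1$ds, c3$ds)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  a <- runif(1)
  set.seed(77)
  invisible(generateCohort(defaultCohortSpec(n = 10L, seed = 5L)))
  expect_identical(runif(1), a)
})

test_that("the default spec encodes the published marginals", {
  spec <- defaultCohortSpec()
  m <- spec@marginals
  expect_equal(m$male, 0.7036)
  expect_equal(unname(m$tcad["right"]), 187 / 253)
  expect_equal(unname(m$vessel["LAD"]), 205 / 253)
  expect_equal(m$lvefMean, 57.7)
  expect_equal(m$lvmMean, 148.56)
  expect_equal(sum(m$dsBinProbs), 1)
  expect_equal(m$dsBinProbs, c(0.051, 0.518, 0.415, 0.016))
})

test_that("a large cohort recovers the marginal distributions within CLT bands", {
  coh <- generateCohort(defaultCohortSpec(n = 10000L, seed = 8L))
  n <- nrow(coh)
  binSe <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(coh$gender == "male") - 0.7036), 3 * binSe(0.7036))
  expect_lt(abs(mean(coh$tcad == "right") - 187 / 253), 3 * binSe(0.7391))
  expect_lt(abs(mean(coh$stenosis_location == "LAD") - 205 / 253),
    3 * binSe(0.8103))
  expect_lt(abs(mean(coh$lvef) - 57.7), 3 * 19.3 / sqrt(n))
  expect_lt(abs(mean(coh$bmi) - 23.6), 3 * 5.3 / sqrt(n))
  expect_lt(abs(mean(coh$lvm) - 148.56), 3 * 25.6 / sqrt(n))
  # DS bin occupancy
  expect_lt(abs(mean(coh$ds >= 50 & coh$ds < 70) - 0.518), 3 * binSe(0.518))
  expect_lt(abs(mean(coh$ds >= 90) - 0.016), 3 * binSe(0.016))
  expect_true(all(coh$ds >= 30 & coh$ds <= 100))
})

test_that("male count at n = 253 stays inside the binomial band around 178", {
  coh <- generateCohort(defaultCohortSpec(n = 253L, seed = 9L))
  sd3 <- 3 * sqrt(253 * 0.7036 * (1 - 0.7036))
  expect_lt(abs(sum(coh$gender == "male") - 178), sd3)
})

test_that("physiological truncation holds and clips are recorded in provenance", {
  coh <- generateCohort(defaultCohortSpec(n = 5000L, seed = 10L))
  expect_true(all(coh$av > 0))
  expect_true(all(coh$lvef >= 5 & coh$lvef <= 90))
  expect_true(all(coh$ffr > 0.5 & coh$ffr <= 1))
  prov <- attr(coh, "provenance")
  expect_named(prov$clips, names(ffrscore:::.CLIPS))
  expect_gt(prov$clips$lvef, 0)  # LVEF 57.7 +/- 19.3 clips at [5, 90] sometimes
  expect_identical(prov$seed, 10L)
})

test_that("the latent label model is monotone in the total score", {
  coh <- generateCohort(defaultCohortSpec(n = 8000L, seed = 11L))
  s <- scoreCohort(coh, ffrScoringForm())$results$total
  low <- lowFfrLabels(coh$ffr)
  expect_gt(mean(low[s > stats::median(s)]), mean(low[s < stats::median(s)]))
  # continuous FFR is consistent with its binary label
  expect_true(all(coh$ffr[low] <= 0.8))
  expect_true(all(coh$ffr[!low] > 0.8))
})

test_that("slope zero removes all signal: AUC near 0.5", {
  spec <- defaultCohortSpec(n = 4000L, seed = 12L)
  spec@ffrModel <- list(intercept = 0, slope = 0)
  coh <- generateCohort(spec)
  s <- scoreCohort(coh, ffrScoringForm())$results$total
  a <- rocAuc(s, lowFfrLabels(coh$ffr))$auc
  expect_lt(abs(a - 0.5), 0.03)
})

test_that("mean total score at n = 253 covers the published 6.7-point mean", {
  inBand <- vapply(1:20, function(seed) {
    coh <- generateCohort(defaultCohortSpec(n = 253L, seed = seed))
    m <- scoreCohort(coh, ffrScoringForm())$mean
    abs(m - 6.7) <= 0.8
  }, logical(1))
  expect_gte(mean(inBand), 0.9)
})

test_that("calibration rejects unattainable or invalid targets", {
  spec <- defaultCohortSpec()
  expect_error(calibrateFfrModel(spec, targetAuc = 0.4), "targetAuc")
  expect_error(calibrateFfrModel(spec, targetPrevalence = 1.2),
    "targetPrevalence")
  expect_error(calibrateFfrModel(spec, targetAuc = 0.999, n = 2000L),
    "calibration failed")
})

test_that("calibration reaches the requested operating point", {
  spec <- calibrateFfrModel(defaultCohortSpec(), targetAuc = 0.75,
    targetPrevalence = 0.3, n = 6000L, seed = 21L)
  check <- defaultCohortSpec(n = 6000L, seed = 22L)
  check@ffrModel <- spec@ffrModel
  coh <- generateCohort(check)
  s <- scoreCohort(coh, ffrScoringForm())$results$total
  low <- lowFfrLabels(coh$ffr)
  expect_lt(abs(rocAuc(s, low)$auc - 0.75), 0.03)
  expect_lt(abs(mean(low) - 0.3), 0.03)
})
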