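test_that("form derivation reproduces the published 10-point distribution", {
  gw <- propagateWeights(ffrHierarchy())
  form <- deriveScoringForm(gw, rankFactors(gw, 7))
  it <- formItems(form)
  pts <- stats::setNames(it$points, it$factor)
  expect_equal(pts[["gender"]], 1.4)
  expect_equal(pts[["ls"]], 1.8)
  expect_equal(pts[["ds"]], 2.4)
  expect_equal(pts[["tcad"]], 1.5)
  expect_equal(pts[["lvef"]], 1.2)
  expect_equal(pts[["lvm"]], 0.7)  # 0.6 + the 0.1 rounding residual
  expect_equal(pts[["bmi"]], 1.0)
  expect_equal(sum(it$points), 10)
  expect_equal(formTotalPoints(form), 10)
  expect_equal(formCutoff(form), 6.2)
})

test_that("equal weights split the total evenly with no residual", {
  h <- hierarchy("t", c(only = 1),
    list(only = c(a = 0.2, b = 0.2, c = 0.2, d = 0.2, e = 0.2)))
  preds <- data.frame(factor = letters[1:5], field = letters[1:5],
    op = "ge", value = "1", stringsAsFactors = FALSE)
  form <- deriveScoringForm(propagateWeights(h), letters[1:5],
    totalPoints = 10, cutoff = 5, predicates = preds)
  expect_equal(formItems(form)$points, rep(2, 5))
})

test_that("derivation validates its inputs", {
  gw <- propagateWeights(ffrHierarchy())
  expect_error(deriveScoringForm(gw, c("ds", "nosuch")), "unknown factor")
  expect_error(deriveScoringForm(gw, "ds", totalPoints = 0), "> 0")
  expect_error(deriveScoringForm(gw, c("ds", "age")), "no predicate")
})

test_that("an all-positive patient scores the full total and is classified low-FFR", {
  form <- ffrScoringForm()
  res <- scorePatient(allPositivePatient(), form)
  expect_equal(res$total, 10)
  expect_true(res$predictedLowFfr)
})

test_that("a single met predicate awards only that item's points", {
  form <- ffrScoringForm()
  p <- list(gender = "female", stenosis_location = "RCA", ds = 62,
    tcad = "left", lvef = 60, lvm = 140, bmi = 22)
  res <- scorePatient(p, form)
  expect_equal(res$total, 2.4)
  expect_equal(unname(res$awarded[res$awarded > 0]), 2.4)
  expect_false(res$predictedLowFfr)
})

test_that("the decision cutoff is inclusive at exactly 6.2 points", {
  form <- ffrScoringForm()
  # LAD + right dominant + LVEF + LVM + BMI = 1.8 + 1.5 + 1.2 + 0.7 + 1.0 = 6.2
  p <- list(gender = "female", stenosis_location = "LAD", ds = 55,
    tcad = "right", lvef = 50, lvm = 150, bmi = 25)
  res <- scorePatient(p, form)
  expect_equal(res$total, 6.2)
  expect_true(res$predictedLowFfr)
})

test_that("numeric predicate boundaries are inclusive as printed", {
  form <- ffrScoringForm()
  base <- allPositivePatient()
  base$ds <- 60; base$lvef <- 58; base$lvm <- 148; base$bmi <- 23.5
  expect_equal(scorePatient(base, form)$total, 10)
})

test_that("flipping one predicate from unmet to met never decreases the total", {
  form <- ffrScoringForm()
  it <- formItems(form)
  metValue <- list(gender = "male", ls = "LAD", ds = 65, tcad = "right",
    lvef = 50, lvm = 150, bmi = 25)
  set.seed(3)
  for (rep in 1:20) {
    p <- randomPatient()
    t0 <- scorePatient(p, form)$total
    for (i in seq_len(nrow(it))) {
      q <- p
      q[[it$field[i]]] <- metValue[[it$factor[i]]]
      expect_gte(scorePatient(q, form)$total, t0)
    }
  }
})

test_that("classification is invariant to item ordering", {
  form <- ffrScoringForm()
  set.seed(4)
  shuffled <- form
  shuffled@items <- form@items[sample(nrow(form@items)), ]
  for (rep in 1:10) {
    p <- randomPatient()
    expect_equal(scorePatient(p, shuffled)$total, scorePatient(p, form)$total)
  }
})

test_that("missing-data policy: strict errors name the field, zero mode logs", {
  form <- ffrScoringForm()
  p <- allPositivePatient()
  p$lvef <- NA
  expect_error(scorePatient(p, form), "lvef")
  expect_message(res <- scorePatient(p, form, missing = "zero"), "zero-points")
  expect_equal(res$total, 10 - 1.2)
})

test_that("cohort scoring summarizes totals with the documented conventions", {
  form <- ffrScoringForm()
  one <- as.data.frame(allPositivePatient(), stringsAsFactors = FALSE)
  sc1 <- scoreCohort(one, form)
  expect_equal(sc1$mean, 10)
  expect_equal(sc1$sd, 0)  # single record: SD 0 by convention
  two <- rbind(one, data.frame(gender = "female", stenosis_location = "RCA",
    ds = 62, tcad = "left", lvef = 60, lvm = 140, bmi = 22))
  sc2 <- scoreCohort(two, form)
  expect_equal(sc2$mean, (10 + 2.4) / 2)
  expect_equal(sc2$results$total, c(10, 2.4))
  expect_error(scoreCohort(data.frame(), form), "non-empty")
})

test_that("vectorized cohort scoring agrees with patient-by-patient scoring", {
  form <- ffrScoringForm()
  set.seed(5)
  cohort <- do.call(rbind, lapply(1:25, function(i)
    as.data.frame(randomPatient(), stringsAsFactors = FALSE)))
  sc <- scoreCohort(cohort, form)
  single <- vapply(seq_len(nrow(cohort)), function(i)
    scorePatient(cohort[i, ], form)$total, numeric(1))
  expect_equal(sc$results$total, single)
})

test_that("scoring forms round-trip through JSON losslessly", {
  form <- ffrScoringForm()
  path <- withr::local_tempfile(fileext = ".json")
  writeScoringForm(form, path)
  back <- readScoringForm(path)
  expect_equal(formItems(back), formItems(form))
  expect_equal(formTotalPoints(back), formTotalPoints(form))
  expect_equal(formCutoff(back), formCutoff(form))
})
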