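test_that("AUC hits the trivial limits", {
  expect_equal(suppressWarnings(  # pROC flags the degenerate AUC == 1 CI
    rocAuc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0.5)
})

test_that("rank AUC equals exhaustive pairwise concordance on the 6-point toy set", {
  score <- c(3, 2, 2, 1, 2, 0)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(rocAuc(score, truth)$auc, bruteForceAuc(score, truth))
  expect_equal(bruteForceAuc(score, truth), 8 / 9)
})

test_that("rank AUC equals the pairwise oracle on random tied data", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(6:20, 1)
    score <- sample(0:6, n, replace = TRUE)
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    expect_equal(rocAuc(score, truth)$auc, bruteForceAuc(score, truth),
      tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  score <- rnorm(40)
  truth <- runif(40) < plogis(score)
  a0 <- rocAuc(score, truth)$auc
  expect_equal(rocAuc(exp(score), truth)$auc, a0)
  expect_equal(rocAuc(qlogis(plogis(score)) * 100 + 3, truth)$auc, a0,
    tolerance = 1e-12)
})

test_that("rank AUC equals the trapezoidal ROC integral on tie-free data", {
  set.seed(14)
  score <- rnorm(60)
  truth <- runif(60) < plogis(2 * score)
  rp <- rocPoints(score, truth)
  fpr <- 1 - rp$specificity
  trap <- -sum(diff(fpr) * (rp$sensitivity[-1] + rp$sensitivity[-nrow(rp)]) / 2)
  expect_equal(rocAuc(score, truth)$auc, trap, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC cross-check and single-class input errors", {
  set.seed(15)
  score <- c(rnorm(20, 1), rnorm(20))
  truth <- rep(c(TRUE, FALSE), each = 20)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
    levels = c(FALSE, TRUE), direction = "<")))
  expect_equal(rocAuc(score, truth)$auc, ref, tolerance = 1e-12)
  expect_error(rocAuc(score, rep(TRUE, 40)), "both classes")
})

test_that("DeLong and bootstrap CIs bracket the AUC", {
  set.seed(16)
  score <- c(rnorm(30, 1.2), rnorm(30))
  truth <- rep(c(TRUE, FALSE), each = 30)
  r <- rocAuc(score, truth)
  expect_lt(r$ciLower, r$auc)
  expect_gt(r$ciUpper, r$auc)
  set.seed(16)
  rb <- rocAuc(score, truth, ciMethod = "bootstrap")
  expect_lt(rb$ciLower, rb$auc)
  expect_gt(rb$ciUpper, rb$auc)
})

test_that("Youden cutoff selection matches an exhaustive threshold scan", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    score <- round(runif(n, 0, 10), 1)
    truth <- runif(n) < plogis(score - 5)
    if (!any(truth) || all(truth)) next
    if (min(score[truth]) > max(score[!truth])) next  # separated case below
    expect_equal(selectCutoff(score, truth), bruteForceYouden(score, truth))
  }
})

test_that("cutoff conventions: separation midpoint, ties toward sensitivity, degenerate data", {
  expect_equal(selectCutoff(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
    (5 + 2) / 2)
  # thresholds 2 and 5 tie on J = 0.5: pick the lower (higher sensitivity)
  expect_equal(selectCutoff(c(2, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 2)
  # degenerate single-threshold data: that threshold
  expect_equal(selectCutoff(c(2, 2, 2), c(TRUE, FALSE, TRUE)), 2)
})

test_that("confusion metrics reproduce hand-computed rates", {
  score <- c(5, 5, 5, 3, 3, 3)
  truth <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  m <- confusionMetrics(score, truth, 4)
  expect_equal(m$counts, list(tp = 2L, fp = 1L, tn = 3L, fn = 0L))
  expect_equal(m$sensitivity$value, 1)
  expect_equal(m$specificity$value, 0.75)
  expect_equal(m$ppv$value, 2 / 3)
  expect_equal(m$npv$value, 1)
  expect_length(m$undefined, 0)
  expect_true(m$sensitivity$ciLower <= 1 & m$sensitivity$ciUpper >= 1)
})

test_that("degenerate all-positive prediction flags NPV as undefined", {
  m <- confusionMetrics(c(9, 9, 9), c(TRUE, TRUE, FALSE), 1)
  expect_equal(m$specificity$value, 0)
  expect_true(is.na(m$npv$value))
  expect_identical(m$undefined, "npv")
})

test_that("published sensitivity, specificity and PPV imply the published NPV", {
  imp <- impliedPrevalenceNpv(0.943, 0.762, 0.789)
  expect_equal(round(imp$prevalence, 3), 0.486)
  expect_equal(round(imp$npv, 3), 0.934)
})

test_that("DS-alone baseline is a continuous comparator score", {
  cohort <- data.frame(ds = c(70, 50, 65, 40), ffr = c(0.6, 0.9, 0.7, 0.95))
  b <- dsAloneBaseline(cohort)
  expect_equal(b$score, cohort$ds)
  expect_identical(b$truth, c(TRUE, FALSE, TRUE, FALSE))
  # label exactly determined by DS >= 60 gives perfect discrimination
  expect_equal(suppressWarnings(rocAuc(b$score, b$truth))$auc, 1)
  cohort$ds[2] <- NA
  expect_error(dsAloneBaseline(cohort), "present for all")
})

test_that("low-FFR labels use the inclusive 0.80 threshold", {
  expect_identical(lowFfrLabels(c(0.8, 0.801, 0.5)), c(TRUE, FALSE, TRUE))
  expect_error(lowFfrLabels(c(0.7, NA)), "missing")
})
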