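#' Low-FFR truth labels from measured FFR
#'
#' @param ffr numeric vector of measured FFR values in (0, 1].
#' @return logical vector, TRUE iff FFR <= 0.80 (hemodynamically
#'   significant stenosis).
#' @export
lowFfrLabels <- function(ffr) {
  if (any(is.na(ffr)))
    stop("measured FFR missing for some records; labels undefined")
  ffr <= 0.80
}

.checkBothClasses <- function(truth) {
  if (!any(truth) || all(truth))
    stop("both classes must be present to compute ROC metrics")
}

#' ROC curve and AUC with 95% confidence interval
#'
#' The AUC is computed as the Mann-Whitney concordance probability
#' P(score_pos > score_neg) + 0.5 P(score_pos = score_neg) via the rank
#' formulation (midranks, so ties count one half). The confidence interval
#' is DeLong's by default (via \pkg{pROC}) or a seeded stratified
#' bootstrap. ROC points use the convention: predicted positive iff
#' score >= threshold, thresholds at the observed score values plus a +Inf
#' sentinel.
#'
#' @param score numeric risk scores (higher = more likely low FFR).
#' @param truth logical low-FFR labels.
#' @param ciMethod `"delong"` (default) or `"bootstrap"` (stratified,
#'   2000 replicates, seeded and deterministic).
#' @return list with `auc`, `ciLower`, `ciUpper`, `ciMethod`, and
#'   `rocPoints` (data.frame threshold, sensitivity, specificity).
#' @examples
#' rocAuc(c(3, 2, 2, 1, 2, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
rocAuc <- function(score, truth, ciMethod = c("delong", "bootstrap")) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(length(score) == length(truth), !anyNA(score), !anyNA(truth))
  .checkBothClasses(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  r <- rank(score)  # midranks handle ties as half-concordance
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  rocObj <- pROC::roc(response = truth, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- if (ciMethod == "delong") {
    as.numeric(pROC::ci.auc(rocObj, method = "delong"))
  } else {
    # stratified bootstrap; draws from the caller's RNG stream, so wrap in
    # set.seed() for a reproducible interval
    as.numeric(pROC::ci.auc(rocObj, method = "bootstrap", boot.n = 2000,
      boot.stratified = TRUE))
  }
  list(auc = auc, ciLower = ci[1], ciUpper = ci[3], ciMethod = ciMethod,
    rocPoints = rocPoints(score, truth))
}

#' Empirical ROC points
#'
#' @inheritParams rocAuc
#' @return data.frame with one row per threshold (observed score values
#'   plus +Inf), columns `threshold`, `sensitivity`, `specificity`.
#' @export
rocPoints <- function(score, truth) {
  thresholds <- c(sort(unique(score)), Inf)
  sp <- sort(score[truth])
  sn <- sort(score[!truth])
  # findInterval with left.open counts values strictly below each threshold
  belowPos <- findInterval(thresholds, sp, left.open = TRUE)
  belowNeg <- findInterval(thresholds, sn, left.open = TRUE)
  data.frame(
    threshold = thresholds,
    sensitivity = (length(sp) - belowPos) / length(sp),
    specificity = belowNeg / length(sn)
  )
}

#' Select a decision cutoff
#'
#' Default criterion: maximize the Youden index J = sensitivity +
#' specificity - 1 over candidate thresholds (the observed score values);
#' ties are resolved toward higher sensitivity, i.e. the lowest tied
#' threshold. When the classes are perfectly separated, the midpoint of the
#' separating gap is returned by convention.
#'
#' @inheritParams rocAuc
#' @param criterion currently `"youden"`.
#' @return the selected cutoff (predicted positive iff score >= cutoff).
#' @export
selectCutoff <- function(score, truth, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  stopifnot(length(score) == length(truth))
  .checkBothClasses(truth)
  rp <- rocPoints(score, truth)
  cand <- rp[is.finite(rp$threshold), ]
  j <- cand$sensitivity + cand$specificity - 1
  best <- which(j == max(j))
  # lower thresholds have higher sensitivity; take the lowest tied one
  cutoff <- min(cand$threshold[best])
  if (min(score[truth]) > max(score[!truth]))
    cutoff <- (min(score[truth]) + max(score[!truth])) / 2
  cutoff
}

.wilsonCi <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  # prop.test without continuity correction is the Wilson score interval
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, conf.level = conf, correct = FALSE)$conf.int))
}

#' Confusion-matrix metrics at a cutoff
#'
#' Classifies `score >= cutoff` as predicted low-FFR and reports
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP) and NPV
#' TN/(TN+FN) with 95% Wilson score confidence intervals. A metric whose
#' denominator is zero is reported as NA with its name in `undefined`.
#'
#' @inheritParams rocAuc
#' @param cutoff decision threshold (inclusive).
#' @return list with `counts` (tp, fp, tn, fn), `sensitivity`,
#'   `specificity`, `ppv`, `npv` (each a list value/ciLower/ciUpper),
#'   `prevalence`, and `undefined` (character vector).
#' @export
confusionMetrics <- function(score, truth, cutoff) {
  stopifnot(length(score) == length(truth))
  .checkBothClasses(truth)
  pred <- score >= cutoff
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth)
  metric <- function(num, den) {
    if (den == 0) return(list(value = NA_real_, ciLower = NA_real_,
      ciUpper = NA_real_))
    ci <- .wilsonCi(num, den)
    list(value = num / den, ciLower = ci[1], ciUpper = ci[2])
  }
  out <- list(
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = metric(tp, tp + fn),
    specificity = metric(tn, tn + fp),
    ppv = metric(tp, tp + fp),
    npv = metric(tn, tn + fn),
    prevalence = (tp + fn) / length(truth)
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")],
    function(m) is.na(m$value), logical(1))))
  out
}

#' Prevalence and NPV implied by sensitivity, specificity and PPV
#'
#' Under a single confusion matrix, PPV = sens*p / (sens*p +
#' (1-spec)*(1-p)) determines the prevalence p, which with sensitivity and
#' specificity determines the NPV. Useful as a coherence check on reported
#' diagnostic metrics.
#'
#' @param sensitivity,specificity,ppv proportions in (0, 1).
#' @return list with `prevalence` and `npv`.
#' @examples
#' impliedPrevalenceNpv(0.943, 0.762, 0.789)  # prevalence ~0.486, NPV ~0.934
#' @export
impliedPrevalenceNpv <- function(sensitivity, specificity, ppv) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0,
    specificity < 1, ppv > 0, ppv < 1)
  f <- 1 - specificity
  prevalence <- ppv * f / (sensitivity * (1 - ppv) + ppv * f)
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  list(prevalence = prevalence, npv = npv)
}

#' Diameter-stenosis-alone baseline scores
#'
#' The conventional comparator: the continuous DS percentage itself as the
#' risk score, enabling a like-for-like ROC comparison with the scoring
#' form.
#'
#' @param cohort data.frame with columns `ds` and `ffr` (ffr non-missing).
#' @return data.frame with columns `score` (DS %) and `truth`
#'   (FFR <= 0.8).
#' @export
dsAloneBaseline <- function(cohort) {
  if (!"ds" %in% names(cohort) || anyNA(cohort$ds))
    stop("diameter stenosis (ds) must be present for all records")
  data.frame(score = cohort$ds, truth = lowFfrLabels(cohort$ffr))
}

#' End-to-end evaluation of a scoring form on a labelled cohort
#'
#' Scores the cohort, computes ROC/AUC with CI for the form and for the
#' DS-alone baseline, selects (or takes) a cutoff, and reports
#' confusion-matrix metrics at that cutoff.
#'
#' @param cohort data.frame of patient records with measured `ffr`.
#' @param form a [ScoringForm-class]; default the reference form.
#' @param cutoff decision threshold; default the form's own cutoff. Pass
#'   `NULL` to re-derive it by the Youden criterion.
#' @param ciMethod CI method for the AUC, see [rocAuc()].
#' @return list of class `ffrEvaluation`: `auc` (form), `dsAuc`
#'   (baseline), `cutoff`, `metrics` (see [confusionMetrics()]), `n`, and
#'   `meanScore`/`sdScore`.
#' @export
evaluateCohort <- function(cohort, form = ffrScoringForm(), cutoff = formCutoff(form),
                           ciMethod = "delong") {
  sc <- scoreCohort(cohort, form)
  truth <- lowFfrLabels(cohort$ffr)
  score <- sc$results$total
  if (is.null(cutoff)) cutoff <- selectCutoff(score, truth)
  ds <- dsAloneBaseline(cohort)
  out <- list(
    auc = rocAuc(score, truth, ciMethod = ciMethod),
    dsAuc = rocAuc(ds$score, ds$truth, ciMethod = ciMethod),
    cutoff = cutoff,
    metrics = confusionMetrics(score, truth, cutoff),
    n = nrow(cohort),
    meanScore = sc$mean,
    sdScore = sc$sd
  )
  class(out) <- "ffrEvaluation"
  out
}

#' @export
print.ffrEvaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d records (prevalence of low FFR: %.3f)\n",
    x$n, x$metrics$prevalence))
  cat(sprintf("  scoring form AUC: %.3f (95%% CI %.3f-%.3f)\n",
    x$auc$auc, x$auc$ciLower, x$auc$ciUpper))
  cat(sprintf("  DS-alone AUC:     %.3f (95%% CI %.3f-%.3f)\n",
    x$dsAuc$auc, x$dsAuc$ciLower, x$dsAuc$ciUpper))
  cat(sprintf("  cutoff >= %.1f points: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f\n",
    x$cutoff, x$metrics$sensitivity$value, x$metrics$specificity$value,
    x$metrics$ppv$value, x$metrics$npv$value))
  cat(sprintf("  mean total score: %.1f +/- %.1f points\n", x$meanScore,
    x$sdScore))
  invisible(x)
}
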