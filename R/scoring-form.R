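#' Default score-item predicates for the FFR form
#'
#' The binary predicates attached to each scored factor: male gender, LAD
#' stenosis location, diameter stenosis >= 60%, right-dominant coronary
#' distribution, LVEF <= 58%, LVM >= 148 g, BMI >= 23.5 kg/m2. All
#' numeric comparisons are inclusive. Thresholds are configuration, not
#' hard-coded: pass a modified copy to [deriveScoringForm()] to change them
#' (e.g. a DS >= 50% variant of the angiographic criterion).
#'
#' @return data.frame with columns `factor`, `field`, `op`, `value`.
#' @export
ffrPredicates <- function() {
  data.frame(
    factor = c("gender", "ls", "ds", "tcad", "lvef", "lvm", "bmi"),
    field = c("gender", "stenosis_location", "ds", "tcad", "lvef", "lvm", "bmi"),
    op = c("eq", "eq", "ge", "eq", "le", "ge", "ge"),
    value = c("male", "LAD", "60", "right", "58", "148", "23.5"),
    stringsAsFactors = FALSE
  )
}

#' Derive a point-based scoring form from global weights
#'
#' Normalizes the global weights of the selected factors to `totalPoints`,
#' rounds each item to one decimal, and assigns any rounding residual to the
#' smallest-weight item so the printed total is exact. Predicates come from
#' `predicates` (default [ffrPredicates()]).
#'
#' @param weights a [GlobalWeightTable-class].
#' @param selected character vector of factor names to include (must be in
#'   the table and in `predicates`).
#' @param totalPoints total points on the form (> 0), default 10.
#' @param cutoff inclusive decision threshold in points; default 6.2, the
#'   reference form's critical value. Use [selectCutoff()] to re-derive one
#'   from scored data.
#' @param predicates data.frame of predicates as in [ffrPredicates()].
#'
#' @return a [ScoringForm-class].
#' @examples
#' gw <- propagateWeights(ffrHierarchy())
#' deriveScoringForm(gw, rankFactors(gw, 7))
#' @export
deriveScoringForm <- function(weights, selected, totalPoints = 10,
                              cutoff = 6.2, predicates = ffrPredicates()) {
  stopifnot(is(weights, "GlobalWeightTable"))
  if (totalPoints <= 0) stop("totalPoints must be > 0")
  tb <- weights@table
  unknown <- setdiff(selected, tb$factor)
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  noPred <- setdiff(selected, predicates$factor)
  if (length(noPred))
    stop("no predicate configured for factor(s): ",
      paste(noPred, collapse = ", "))
  w <- stats::setNames(tb$globalWeight, tb$factor)[selected]
  raw <- w / sum(w) * totalPoints
  pts <- round(raw, 1)
  # work in tenths of a point to keep the residual arithmetic exact
  residual <- round(totalPoints * 10) - sum(round(pts * 10))
  if (residual != 0) {
    smallest <- selected[order(w, selected)][1]
    pts[smallest] <- (round(pts[smallest] * 10) + residual) / 10
  }
  items <- predicates[match(selected, predicates$factor), ]
  items$points <- unname(pts[selected])
  rownames(items) <- NULL
  new("ScoringForm", items = items, totalPoints = totalPoints,
    cutoff = cutoff)
}

#' Reference 10-point FFR scoring form
#'
#' Convenience constructor: the top seven global-weight factors of the
#' built-in hierarchy (DS, LS, TCAD, gender, LVEF, BMI, LVM) normalized to
#' 10 points with the one-decimal rounding/residual rule and the >= 6.2
#' point decision cutoff. Item values: male gender 1.4, LAD stenosis 1.8,
#' DS >= 60% 2.4, right dominant 1.5, LVEF <= 58% 1.2, LVM >= 148 g 0.7,
#' BMI >= 23.5 1.0.
#'
#' @return a [ScoringForm-class].
#' @export
ffrScoringForm <- function() {
  gw <- propagateWeights(ffrHierarchy())
  deriveScoringForm(gw, rankFactors(gw, 7L))
}

#' Accessors for ScoringForm
#'
#' @param x a [ScoringForm-class].
#' @return `formItems()` the item data.frame; `formTotalPoints()` and
#'   `formCutoff()` the scalars.
#' @export
formItems <- function(x) x@items

#' @rdname formItems
#' @export
formTotalPoints <- function(x) x@totalPoints

#' @rdname formItems
#' @export
formCutoff <- function(x) x@cutoff

setMethod("show", "ScoringForm", function(object) {
  cat(sprintf("ScoringForm: %g points total, predict low FFR when score >= %g\n",
    object@totalPoints, object@cutoff))
  it <- object@items
  opSym <- c(eq = "=", ge = ">=", le = "<=")
  for (i in seq_len(nrow(it)))
    cat(sprintf("  %-8s %s %s %s : %.1f\n", it$factor[i], it$field[i],
      opSym[[it$op[i]]], it$value[i], it$points[i]))
})

.evalPredicate <- function(value, op, target) {
  if (op == "eq") return(identical(tolower(as.character(value)),
    tolower(as.character(target))))
  x <- suppressWarnings(as.numeric(value))
  t0 <- as.numeric(target)
  if (is.na(x)) stop("non-numeric value where a numeric comparison is required")
  switch(op, ge = x >= t0, le = x <= t0)
}

#' Score one patient against a form
#'
#' Awards each item's points iff its predicate holds; the total is their
#' sum and the patient is predicted low-FFR iff total >= cutoff
#' (inclusive).
#'
#' @param p a single patient: one-row data.frame or named list with the
#'   fields the form's items reference (gender, stenosis_location, ds,
#'   tcad, lvef, lvm, bmi for the reference form).
#' @param form a [ScoringForm-class].
#' @param missing missing-data policy: `"error"` (default) raises an error
#'   naming the missing field; `"zero"` awards 0 points for items whose
#'   field is absent or NA (each use is logged with a message).
#' @return list with `awarded` (named numeric per item), `total`, and
#'   `predictedLowFfr`.
#' @examples
#' p <- list(gender = "male", stenosis_location = "LAD", ds = 65,
#'   tcad = "right", lvef = 50, lvm = 150, bmi = 25)
#' scorePatient(p, ffrScoringForm())
#' @export
scorePatient <- function(p, form, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  stopifnot(is(form, "ScoringForm"))
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- as.list(p)
  }
  it <- form@items
  awarded <- numeric(nrow(it))
  names(awarded) <- it$factor
  for (i in seq_len(nrow(it))) {
    f <- it$field[i]
    v <- p[[f]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      if (missing == "error")
        stop(sprintf("missing required field '%s' for score item '%s'", f,
          it$factor[i]))
      message(sprintf("missing field '%s': awarding 0 points (zero-points policy)", f))
      next
    }
    if (.evalPredicate(v, it$op[i], it$value[i])) awarded[i] <- it$points[i]
  }
  total <- sum(awarded)
  list(awarded = awarded, total = total,
    predictedLowFfr = total >= form@cutoff)
}

#' Score a whole cohort
#'
#' Applies [scorePatient()] row-wise and summarizes the totals.
#'
#' @param cohort data.frame of patient records (see [readCohortCsv()] for
#'   the schema).
#' @param form a [ScoringForm-class].
#' @param missing missing-data policy passed to [scorePatient()].
#' @return list with `results` (data.frame: one column of awarded points
#'   per item, plus `total` and `predictedLowFfr`), `mean` and `sd` of the
#'   totals. With a single patient the sample SD is reported as 0 by
#'   convention.
#' @export
scoreCohort <- function(cohort, form, missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data.frame")
  it <- form@items
  awarded <- matrix(0, nrow(cohort), nrow(it),
    dimnames = list(NULL, it$factor))
  for (i in seq_len(nrow(it))) {
    f <- it$field[i]
    col <- cohort[[f]]
    if (is.null(col)) col <- rep(NA, nrow(cohort))
    miss <- is.na(col)
    if (any(miss)) {
      if (missing == "error")
        stop(sprintf("missing required field '%s' for score item '%s' (row %s)",
          f, it$factor[i], paste(utils::head(which(miss), 5), collapse = ", ")))
      message(sprintf("field '%s' missing in %d record(s): awarding 0 points (zero-points policy)",
        f, sum(miss)))
    }
    met <- switch(it$op[i],
      eq = tolower(as.character(col)) == tolower(it$value[i]),
      ge = as.numeric(col) >= as.numeric(it$value[i]),
      le = as.numeric(col) <= as.numeric(it$value[i]))
    met[is.na(met)] <- FALSE
    awarded[met, i] <- it$points[i]
  }
  results <- as.data.frame(awarded)
  results$total <- rowSums(awarded)
  results$predictedLowFfr <- results$total >= form@cutoff
  s <- if (nrow(results) > 1) stats::sd(results$total) else 0
  list(results = results, mean = mean(results$total), sd = s)
}
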