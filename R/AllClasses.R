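#' @import methods
NULL

.RECIPROCITY_TOL <- 1e-9
.WEIGHT_SUM_TOL <- 1e-6

#' Pairwise importance-degree matrix
#'
#' A square positive reciprocal matrix of pairwise importance degrees on the
#' Saaty scale: entry \eqn{A_{ij}} states how much more important factor
#' \eqn{i} is than factor \eqn{j}, from 1 (equally important) to 9 (extremely
#' important), with \eqn{A_{ji} = 1/A_{ij}}.
#'
#' @slot entries numeric matrix of importance degrees (dimensionless).
#' @slot labels character vector of factor names, one per row/column.
#' @slot provenance list of construction metadata (e.g. the odds-ratio
#'   mapping strategy used).
#'
#' @seealso [comparisonMatrix()], [matrixFromOddsRatios()],
#'   [principalWeights()], [consistencyReport()]
#' @export
setClass("ComparisonMatrix",
  representation(
    entries = "matrix",
    labels = "character",
    provenance = "list"
  ),
  prototype(provenance = list())
)

setValidity("ComparisonMatrix", function(object) {
  A <- object@entries
  msgs <- character()
  if (!is.numeric(A) || nrow(A) != ncol(A))
    return("entries must be a square numeric matrix")
  n <- nrow(A)
  if (n < 2) msgs <- c(msgs, "matrix order must be at least 2")
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must match the matrix order")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "labels must be unique")
  if (any(!is.finite(A)) || any(A <= 0))
    msgs <- c(msgs, "all entries must be finite and > 0")
  else {
    if (any(abs(diag(A) - 1) > .RECIPROCITY_TOL))
      msgs <- c(msgs, "diagonal entries must equal 1")
    if (any(abs(A * t(A) - 1) > .RECIPROCITY_TOL))
      msgs <- c(msgs, "reciprocity violated: entries[i,j] * entries[j,i] must equal 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Principal-eigenvector weighting result
#'
#' Normalized weights (the principal right eigenvector scaled to sum 1) and
#' the maximum characteristic root (dominant eigenvalue, MCR) of an
#' importance-degree matrix.
#'
#' @slot weights named numeric vector of positive weights summing to 1.
#' @slot mcr maximum characteristic root; at least the matrix order for any
#'   positive reciprocal matrix, with equality iff the matrix is consistent.
#' @slot iterations number of power iterations used.
#'
#' @seealso [principalWeights()]
#' @export
setClass("EigenResult",
  representation(weights = "numeric", mcr = "numeric", iterations = "integer")
)

setValidity("EigenResult", function(object) {
  msgs <- character()
  if (any(object@weights <= 0)) msgs <- c(msgs, "weights must be strictly positive")
  if (abs(sum(object@weights) - 1) > .RECIPROCITY_TOL)
    msgs <- c(msgs, "weights must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Consistency diagnostics for an importance-degree matrix
#'
#' The consistency index CI = (MCR - n) / (n - 1) and random consistency
#' ratio RCR = CI / K, where K is the order-dependent random-consistency
#' constant. RCR <= 0.1 indicates acceptable consistency.
#'
#' @slot n matrix order (NA for an aggregated whole-hierarchy report).
#' @slot mcr maximum characteristic root (NA for aggregated reports).
#' @slot ci consistency index.
#' @slot k random-consistency constant used.
#' @slot rcr random consistency ratio.
#' @slot acceptable logical, TRUE iff rcr <= 0.1.
#'
#' @seealso [consistencyReport()], [consistencyIndex()],
#'   [randomConsistencyRatio()], [totalConsistency()]
#' @export
setClass("ConsistencyReport",
  representation(
    n = "numeric", mcr = "numeric", ci = "numeric",
    k = "numeric", rcr = "numeric", acceptable = "logical"
  )
)

#' Three-layer factor hierarchy
#'
#' A target / intermediate (criteria) / variable (factors) hierarchy with
#' local weights on each layer: criterion weights sum to 1, and factor
#' weights sum to 1 within each criterion.
#'
#' @slot target name of the target (what is being predicted).
#' @slot criteria data.frame with columns `criterion`, `weight`.
#' @slot factors data.frame with columns `criterion`, `factor`, `weight`.
#'
#' @seealso [hierarchy()], [ffrHierarchy()], [propagateWeights()]
#' @export
setClass("Hierarchy",
  representation(target = "character", criteria = "data.frame",
    factors = "data.frame")
)

setValidity("Hierarchy", function(object) {
  msgs <- character()
  cr <- object@criteria
  fa <- object@factors
  if (!all(c("criterion", "weight") %in% names(cr)))
    return("criteria must have columns 'criterion' and 'weight'")
  if (!all(c("criterion", "factor", "weight") %in% names(fa)))
    return("factors must have columns 'criterion', 'factor' and 'weight'")
  if (anyDuplicated(cr$criterion)) msgs <- c(msgs, "criterion names must be unique")
  if (anyDuplicated(fa$factor)) msgs <- c(msgs, "factor names must be unique")
  if (any(cr$weight <= 0) || any(fa$weight <= 0))
    msgs <- c(msgs, "all local weights must be > 0")
  if (abs(sum(cr$weight) - 1) > .WEIGHT_SUM_TOL)
    msgs <- c(msgs, "criterion weights must sum to 1")
  orphan <- setdiff(fa$criterion, cr$criterion)
  if (length(orphan))
    msgs <- c(msgs, paste0("factors assigned to unknown criterion: ",
      paste(orphan, collapse = ", ")))
  for (c0 in unique(fa$criterion)) {
    s <- sum(fa$weight[fa$criterion == c0])
    if (abs(s - 1) > .WEIGHT_SUM_TOL)
      msgs <- c(msgs, sprintf("factor weights under criterion '%s' sum to %.6f, not 1", c0, s))
  }
  if (length(msgs)) msgs else TRUE
})

#' Global (propagated) factor weights with ranks
#'
#' Global weight of a factor = its criterion's local weight times its own
#' local weight within that criterion; ranks are 1 = largest global weight,
#' ties broken lexicographically by factor name.
#'
#' @slot table data.frame with columns `factor`, `criterion`,
#'   `criterionWeight`, `factorWeight`, `globalWeight`, `rank`.
#'
#' @seealso [propagateWeights()], [rankFactors()]
#' @export
setClass("GlobalWeightTable", representation(table = "data.frame"))

setValidity("GlobalWeightTable", function(object) {
  tb <- object@table
  need <- c("factor", "criterion", "criterionWeight", "factorWeight",
    "globalWeight", "rank")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (abs(sum(tb$globalWeight) - 1) > .WEIGHT_SUM_TOL)
    msgs <- c(msgs, "global weights must sum to 1")
  if (!setequal(tb$rank, seq_len(nrow(tb))))
    msgs <- c(msgs, "ranks must be a permutation of 1..#factors")
  if (length(msgs)) msgs else TRUE
})

#' Point-based clinical scoring form
#'
#' A list of binary score items (a predicate on one patient variable and a
#' point value at one-decimal granularity), a fixed total, and an inclusive
#' decision cutoff: a patient whose summed points reach the cutoff is
#' predicted to have low FFR (<= 0.8).
#'
#' @slot items data.frame with columns `factor`, `field`, `op` (one of
#'   "eq", "ge", "le"), `value` (character; numeric threshold or category
#'   label), `points`.
#' @slot totalPoints total points available on the form.
#' @slot cutoff inclusive decision threshold in points.
#'
#' @seealso [deriveScoringForm()], [ffrScoringForm()], [scorePatient()]
#' @export
setClass("ScoringForm",
  representation(items = "data.frame", totalPoints = "numeric",
    cutoff = "numeric")
)

setValidity("ScoringForm", function(object) {
  it <- object@items
  need <- c("factor", "field", "op", "value", "points")
  if (!all(need %in% names(it)))
    return(paste("items must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (any(!it$op %in% c("eq", "ge", "le")))
    msgs <- c(msgs, "item op must be one of 'eq', 'ge', 'le'")
  if (any(it$points < 0)) msgs <- c(msgs, "item points must be >= 0")
  if (abs(sum(round(it$points * 10)) - round(object@totalPoints * 10)) > 0)
    msgs <- c(msgs, "item points must sum to totalPoints at one-decimal granularity")
  if (object@cutoff <= 0 || object@cutoff > object@totalPoints)
    msgs <- c(msgs, "cutoff must lie in (0, totalPoints]")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic cohort specification
#'
#' Marginal distribution parameters for each patient variable plus a latent
#' logistic FFR label model: P(FFR <= 0.8 | total score s) =
#' plogis(intercept + slope * s), with the continuous FFR value synthesized
#' consistently with the binary label.
#'
#' @slot n cohort size.
#' @slot seed RNG seed (recorded in cohort provenance).
#' @slot marginals named list of per-variable distribution parameters.
#' @slot ffrModel list with elements `intercept` and `slope`.
#'
#' @seealso [defaultCohortSpec()], [generateCohort()], [calibrateFfrModel()]
#' @export
setClass("CohortSpec",
  representation(n = "integer", seed = "integer", marginals = "list",
    ffrModel = "list")
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@n < 1) msgs <- c(msgs, "n must be >= 1")
  m <- object@marginals
  probs <- c(m$male, m$cc, m$tcad, m$vessel, m$dsBinProbs)
  if (any(probs < 0 | probs > 1)) msgs <- c(msgs, "probabilities must be in [0, 1]")
  for (nm in c("tcad", "vessel", "dsBinProbs"))
    if (abs(sum(m[[nm]]) - 1) > 1e-6)
      msgs <- c(msgs, sprintf("%s category probabilities must sum to 1", nm))
  sds <- vapply(m[grepl("Sd$", names(m))], identity, numeric(1))
  if (any(sds < 0)) msgs <- c(msgs, "all SDs must be >= 0")
  if (!all(c("intercept", "slope") %in% names(object@ffrModel)))
    msgs <- c(msgs, "ffrModel must contain 'intercept' and 'slope'")
  if (length(msgs)) msgs else TRUE
})
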