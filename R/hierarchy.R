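#' Construct a three-layer factor hierarchy
#'
#' @param target name of the target layer (what is predicted).
#' @param criteria named numeric vector of intermediate-layer local weights
#'   (must sum to 1).
#' @param factors named list, one element per criterion, each a named
#'   numeric vector of variable-layer local weights (each summing to 1).
#'
#' @return a validated [Hierarchy-class].
#' @examples
#' h <- hierarchy("low FFR",
#'   criteria = c(clinical = 0.6, imaging = 0.4),
#'   factors = list(clinical = c(age = 0.3, gender = 0.7),
#'                  imaging = c(ds = 1)))
#' propagateWeights(h)
#' @export
hierarchy <- function(target, criteria, factors) {
  cr <- data.frame(criterion = names(criteria), weight = unname(criteria),
    stringsAsFactors = FALSE)
  fa <- do.call(rbind, lapply(names(factors), function(c0) {
    f <- factors[[c0]]
    data.frame(criterion = c0, factor = names(f), weight = unname(f),
      stringsAsFactors = FALSE)
  }))
  rownames(fa) <- NULL
  new("Hierarchy", target = target, criteria = cr, factors = fa)
}

setMethod("show", "Hierarchy", function(object) {
  cat(sprintf("Hierarchy: target '%s'\n", object@target))
  for (i in seq_len(nrow(object@criteria))) {
    c0 <- object@criteria$criterion[i]
    f <- object@factors[object@factors$criterion == c0, ]
    cat(sprintf("  %s (%.3f): %s\n", c0, object@criteria$weight[i],
      paste(sprintf("%s=%.3f", f$factor, f$weight), collapse = ", ")))
  }
})

#' Reference FFR risk-factor hierarchy
#'
#' The built-in three-layer hierarchy for predicting low fractional flow
#' reserve (FFR <= 0.8): target "predicting FFR"; intermediate layer
#' clinical statistics (0.32), coronary angiography (0.51) and cardiac
#' ultrasound (0.17); variable layer of 13 published independent risk
#' factors with their eigenvector local weights (e.g. DS 0.387 under
#' coronary angiography, gender 0.35 under clinical statistics).
#'
#' @return a [Hierarchy-class].
#' @seealso [propagateWeights()], [ffrScoringForm()]
#' @export
ffrHierarchy <- function() {
  hierarchy(
    target = "predicting FFR",
    criteria = c(
      `clinical statistics` = 0.32,
      `coronary angiography` = 0.51,
      `cardiac ultrasound` = 0.17
    ),
    factors = list(
      `clinical statistics` = c(gender = 0.35, age = 0.1, hr = 0.093,
        sp = 0.11, dp = 0.091, bmi = 0.256),
      `coronary angiography` = c(ls = 0.288, ds = 0.387, tcad = 0.242,
        cc = 0.083),
      `cardiac ultrasound` = c(av = 0.13, lvef = 0.59, lvm = 0.28)
    )
  )
}

#' Propagate local weights to global weights
#'
#' The global weight of factor f under criterion c is the product
#' localweight(c) * localweight(f | c); propagation preserves normalization,
#' so the global weights sum to 1. Ranks are assigned by descending global
#' weight, ties broken lexicographically by factor name.
#'
#' @param h a [Hierarchy-class].
#' @return a [GlobalWeightTable-class].
#' @examples
#' propagateWeights(ffrHierarchy())
#' @export
propagateWeights <- function(h) {
  stopifnot(is(h, "Hierarchy"))
  validObject(h)
  fa <- h@factors
  cw <- stats::setNames(h@criteria$weight, h@criteria$criterion)
  tb <- data.frame(
    factor = fa$factor,
    criterion = fa$criterion,
    criterionWeight = unname(cw[fa$criterion]),
    factorWeight = fa$weight,
    stringsAsFactors = FALSE
  )
  tb$globalWeight <- tb$criterionWeight * tb$factorWeight
  ord <- order(-tb$globalWeight, tb$factor)
  tb$rank <- NA_integer_
  tb$rank[ord] <- seq_len(nrow(tb))
  new("GlobalWeightTable", table = tb)
}

#' Accessor: global-weight table as a data.frame
#'
#' @param x a [GlobalWeightTable-class].
#' @return data.frame with factor, criterion, local weights, global weight
#'   and rank, ordered by rank.
#' @export
globalWeights <- function(x) {
  tb <- x@table
  tb[order(tb$rank), , drop = FALSE]
}

setMethod("show", "GlobalWeightTable", function(object) {
  cat("GlobalWeightTable\n")
  tb <- globalWeights(object)
  tb$globalWeight <- round(tb$globalWeight, 5)
  print(tb, row.names = FALSE)
})

#' Top-ranked factors by global weight
#'
#' @param table a [GlobalWeightTable-class].
#' @param topK how many factors to return, between 1 and the number of
#'   factors.
#' @return character vector of factor names in descending global-weight
#'   order (ties lexicographic).
#' @examples
#' rankFactors(propagateWeights(ffrHierarchy()), 7)
#' @export
rankFactors <- function(table, topK) {
  stopifnot(is(table, "GlobalWeightTable"))
  tb <- table@table
  if (topK < 1 || topK > nrow(tb))
    stop(sprintf("topK must be between 1 and %d", nrow(tb)))
  tb <- tb[order(tb$rank), ]
  tb$factor[seq_len(topK)]
}

#' Whole-hierarchy consistency
#'
#' Aggregates per-criterion consistency reports into a total report using
#' the criterion weights: total CI = sum_j w_j CI_j, total K = sum_j w_j
#' K_j, total RCR = total CI / total K, acceptable when <= 0.1.
#'
#' @param h a [Hierarchy-class].
#' @param reports named list of [ConsistencyReport-class], one per
#'   criterion of `h` (names must match criterion names).
#' @return a [ConsistencyReport-class] with `n` and `mcr` set to NA (they
#'   have no aggregate meaning).
#' @export
totalConsistency <- function(h, reports) {
  stopifnot(is(h, "Hierarchy"))
  validObject(h)
  cr <- h@criteria
  missing <- setdiff(cr$criterion, names(reports))
  if (length(missing))
    stop("missing consistency report for criterion: ",
      paste(missing, collapse = ", "))
  ci <- 0
  k <- 0
  for (i in seq_len(nrow(cr))) {
    rep_i <- reports[[cr$criterion[i]]]
    stopifnot(is(rep_i, "ConsistencyReport"))
    ci <- ci + cr$weight[i] * rep_i@ci
    k <- k + cr$weight[i] * rep_i@k
  }
  rcr <- ci / k
  new("ConsistencyReport", n = NA_real_, mcr = NA_real_, ci = ci, k = k,
    rcr = rcr, acceptable = rcr <= 0.1)
}
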