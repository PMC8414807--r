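#' Random-consistency constants
#'
#' The order-dependent constants K used in the random consistency ratio
#' RCR = CI / K: 0.58, 0.96, 1.12 and 1.24 for matrix orders 3-6. K is not
#' defined for orders below 3 (a 2x2 reciprocal matrix is always
#' consistent).
#'
#' @return named numeric vector, names are matrix orders.
#' @export
kConstants <- function() {
  c(`3` = 0.58, `4` = 0.96, `5` = 1.12, `6` = 1.24)
}

#' Consistency index
#'
#' CI = (MCR - n) / (n - 1), where MCR is the maximum characteristic root
#' and n the matrix order. CI = 0 means complete consistency; values close
#' to 0 indicate satisfactory consistency of the importance degrees. For an
#' exact MCR of a positive reciprocal matrix CI >= 0; a negative CI can only
#' arise from a rounded input MCR and is flagged with a warning.
#'
#' @param mcr maximum characteristic root.
#' @param n matrix order, >= 2.
#' @return the consistency index (full precision; round to 3 decimals for
#'   reporting).
#' @examples
#' consistencyIndex(6.11, 6)   # 0.022
#' consistencyIndex(4.043, 4)  # 0.01433...
#' @export
consistencyIndex <- function(mcr, n) {
  if (!is.finite(mcr)) stop("mcr must be finite")
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("matrix order n must be an integer >= 2")
  ci <- (mcr - n) / (n - 1)
  if (ci < 0)
    warning("negative consistency index: the supplied MCR is below the matrix order, ",
      "which can only arise from rounding of the input")
  ci
}

#' Random consistency ratio
#'
#' RCR = CI / K(n). RCR <= 0.1 indicates good consistency of the odds
#' ratios once converted into importance degrees; otherwise the
#' importance-degree matrix should be re-adjusted.
#'
#' @param ci consistency index.
#' @param n matrix order; must be present in the K lookup (built in for
#'   3-6) unless `k` overrides it.
#' @param k optional K constant override for orders outside the built-in
#'   table.
#' @return list with elements `rcr`, `k` and `acceptable` (`rcr <= 0.1`).
#' @examples
#' randomConsistencyRatio(0.022, 6)  # 0.01774..., acceptable
#' @export
randomConsistencyRatio <- function(ci, n, k = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n <= 2)
    stop("the random-consistency constant K is not defined for matrix order <= 2")
  if (is.null(k)) {
    kc <- kConstants()
    key <- as.character(n)
    if (!key %in% names(kc))
      stop(sprintf("no built-in K constant for matrix order %d; supply k explicitly", n))
    k <- unname(kc[key])
  }
  if (!is.finite(k) || k <= 0) stop("k must be finite and > 0")
  rcr <- ci / k
  list(rcr = rcr, k = k, acceptable = rcr <= 0.1)
}

#' Full consistency diagnostics for a comparison matrix
#'
#' Computes the principal-eigenvector MCR, consistency index and random
#' consistency ratio of an importance-degree matrix in one step.
#'
#' @param matrix a [ComparisonMatrix-class] of order >= 3 (K is undefined
#'   below 3).
#' @param k optional K override, passed to [randomConsistencyRatio()].
#' @return a [ConsistencyReport-class].
#' @examples
#' cm <- comparisonMatrix(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)))
#' consistencyReport(cm)
#' @export
consistencyReport <- function(matrix, k = NULL) {
  eg <- principalWeights(matrix)
  n <- length(eg@weights)
  ci <- consistencyIndex(eg@mcr, n)
  rc <- randomConsistencyRatio(ci, n, k = k)
  new("ConsistencyReport", n = as.numeric(n), mcr = eg@mcr, ci = ci,
    k = rc$k, rcr = rc$rcr, acceptable = rc$acceptable)
}

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport\n")
  cat(sprintf("  n = %s   MCR = %s\n",
    format(object@n), format(round(object@mcr, 4))))
  # CI reported to 3 decimals, RCR to 4, matching conventional reporting
  cat(sprintf("  CI = %.3f   K = %.3f   RCR = %.4f   %s\n",
    object@ci, object@k, object@rcr,
    if (object@acceptable) "acceptable (RCR <= 0.1)" else "NOT acceptable (RCR > 0.1)"))
})

#' Convert a ConsistencyReport to a list
#'
#' @param x a [ConsistencyReport-class].
#' @return plain list with fields n, mcr, ci, k, rcr, acceptable (for JSON
#'   serialization).
#' @export
asConsistencyList <- function(x) {
  list(n = x@n, mcr = x@mcr, ci = x@ci, k = x@k, rcr = x@rcr,
    acceptable = x@acceptable)
}
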