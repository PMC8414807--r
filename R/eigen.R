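#' Principal-eigenvector weights of an importance-degree matrix
#'
#' Solves for the normalized principal right eigenvector (the factor
#' weights) and the maximum characteristic root (MCR, the dominant
#' eigenvalue) of a positive reciprocal matrix by power iteration. For a
#' positive matrix the Perron-Frobenius theorem guarantees a unique positive
#' dominant eigenvector, so the iteration is deterministic for a given
#' matrix.
#'
#' @param matrix a [ComparisonMatrix-class].
#' @param tol convergence tolerance on the max absolute change of the
#'   normalized weight vector between iterations.
#' @param maxIterations iteration cap; exceeding it raises an error.
#'
#' @return an [EigenResult-class] with slots `weights` (named, summing to 1)
#'   and `mcr`.
#' @examples
#' cm <- comparisonMatrix(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)))
#' principalWeights(cm)
#' @export
principalWeights <- function(matrix, tol = 1e-12, maxIterations = 10000L) {
  stopifnot(is(matrix, "ComparisonMatrix"))
  validObject(matrix)
  A <- matrix@entries
  n <- nrow(A)
  w <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(maxIterations)) {
    v <- as.vector(A %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol) {
      w <- v
      converged <- TRUE
      break
    }
    w <- v
  }
  if (!converged)
    stop(sprintf("power iteration did not converge within %d iterations", maxIterations))
  # with sum(w) == 1, the Rayleigh quotient reduces to sum(A w)
  mcr <- sum(A %*% w)
  names(w) <- matrix@labels
  new("EigenResult", weights = w, mcr = mcr, iterations = it)
}

#' Accessors for EigenResult
#'
#' @param x an [EigenResult-class].
#' @return `eigenWeights()` the named weight vector; `mcr()` the maximum
#'   characteristic root.
#' @export
eigenWeights <- function(x) x@weights

#' @rdname eigenWeights
#' @export
mcr <- function(x) x@mcr

setMethod("show", "EigenResult", function(object) {
  cat(sprintf("EigenResult: MCR = %.6f (%d iterations)\n", object@mcr,
    object@iterations))
  print(round(object@weights, 4))
})
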