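#' Construct an importance-degree matrix
#'
#' Builds a validated [ComparisonMatrix-class] from a square positive
#' reciprocal matrix of Saaty-scale importance degrees.
#'
#' @param entries square numeric matrix; positive, unit diagonal,
#'   reciprocal (`entries[i,j] * entries[j,i] == 1`).
#' @param labels character vector of factor names; defaults to the matrix
#'   dimnames or `F1..Fn`.
#' @param strict if TRUE, warn when entries fall outside the strict Saaty
#'   set \{1..9\} and their reciprocals. Near-consistent reconstructed
#'   matrices routinely carry non-integer degrees, so this is a warning,
#'   never an error.
#' @param provenance optional list of construction metadata.
#'
#' @return a [ComparisonMatrix-class] object.
#' @examples
#' cm <- comparisonMatrix(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)),
#'   labels = c("DS", "LS", "TCAD"))
#' principalWeights(cm)
#' @export
comparisonMatrix <- function(entries, labels = NULL, strict = FALSE,
                             provenance = list()) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop("entries must be a square matrix")
  if (is.null(labels)) {
    labels <- rownames(entries)
    if (is.null(labels)) labels <- paste0("F", seq_len(nrow(entries)))
  }
  dimnames(entries) <- list(labels, labels)
  obj <- new("ComparisonMatrix", entries = entries, labels = labels,
    provenance = provenance)
  if (strict) {
    saaty <- c(1:9, 1 / (2:9))
    off <- entries[row(entries) != col(entries)]
    if (any(vapply(off, function(x) min(abs(x - saaty)) > 1e-9, logical(1))))
      warning("matrix contains entries outside the strict Saaty scale {1..9, 1/2..1/9}")
  }
  obj
}

#' @describeIn comparisonMatrix matrix order (number of factors).
#' @param x,object a `ComparisonMatrix`.
#' @export
setMethod("length", "ComparisonMatrix", function(x) nrow(x@entries))

#' Accessors for ComparisonMatrix
#'
#' @param x a [ComparisonMatrix-class].
#' @return `cmEntries()` the numeric matrix; `cmLabels()` the factor names.
#' @export
cmEntries <- function(x) x@entries

#' @rdname cmEntries
#' @export
cmLabels <- function(x) x@labels

setMethod("show", "ComparisonMatrix", function(object) {
  cat(sprintf("ComparisonMatrix of order %d\n", nrow(object@entries)))
  print(round(object@entries, 4))
  if (length(object@provenance))
    cat("provenance:", paste(names(object@provenance),
      unlist(object@provenance), sep = "=", collapse = ", "), "\n")
})

#' Build an importance-degree matrix from odds ratios
#'
#' Converts per-factor odds ratios (for low FFR, taken from published
#' multivariable analyses) into a pairwise importance-degree matrix. The
#' degree for factors i, j with \eqn{OR_i \ge OR_j} is a monotone map of the
#' ratio \eqn{r = OR_i / OR_j}, clamped to the Saaty range \[1, 9\]; the
#' opposite cell holds the reciprocal.
#'
#' Mapping strategies:
#' \describe{
#'   \item{`ratio` (default)}{`round(r)` clamped to \[1, 9\]. Equal odds
#'     ratios give degree 1 ("equally important").}
#'   \item{`log`}{`round(1 + 2 * log(r))` clamped to \[1, 9\]; compresses
#'     large odds-ratio ratios onto the scale.}
#' }
#'
#' @param oddsRatios named numeric vector of odds ratios, all finite and > 0.
#' @param mapping `"ratio"` or `"log"`.
#' @return a [ComparisonMatrix-class]; the mapping is recorded in its
#'   provenance.
#' @examples
#' matrixFromOddsRatios(c(DS = 3.2, LS = 1.0, gender = 1.6))
#' @export
matrixFromOddsRatios <- function(oddsRatios, mapping = c("ratio", "log")) {
  mapping <- match.arg(mapping)
  or <- oddsRatios
  if (length(or) < 2)
    stop("at least two factors are required to build a comparison matrix")
  if (any(!is.finite(or)) || any(or <= 0))
    stop("all odds ratios must be finite and > 0")
  if (is.null(names(or))) names(or) <- paste0("F", seq_along(or))
  n <- length(or)
  degree <- function(r) {  # r >= 1
    d <- switch(mapping,
      ratio = round(r),
      log = round(1 + 2 * log(r)))
    min(9, max(1, d))
  }
  A <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (or[i] >= or[j]) {
        d <- degree(or[i] / or[j])
        A[i, j] <- d
        A[j, i] <- 1 / d
      } else {
        d <- degree(or[j] / or[i])
        A[j, i] <- d
        A[i, j] <- 1 / d
      }
    }
  }
  comparisonMatrix(A, labels = names(or),
    provenance = list(source = "odds_ratios", mapping = mapping))
}
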