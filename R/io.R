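.SCHEMA_VERSION <- 1L

.COHORT_COLUMNS <- c("gender", "age", "bmi", "hr", "sp", "dp", "cc", "av",
  "tcad", "lvef", "lvm", "stenosis_location", "ds", "ffr")
.COHORT_NUMERIC <- c("age", "bmi", "hr", "sp", "dp", "av", "lvef", "lvm",
  "ds", "ffr")

#' Read a patient cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row naming the
#' patient-record fields (case-insensitive): gender, age, bmi, hr, sp, dp,
#' cc, av, tcad, lvef, lvm, stenosis_location, ds, and optionally ffr.
#' Missing values are empty cells; `ffr` may be absent or partially
#' missing (records without it can still be scored, not evaluated).
#'
#' Range checks: ds and lvef in \[0, 100\], ffr in (0, 1\]. Violations and
#' unparseable numeric cells raise errors naming the offending row.
#'
#' @param path CSV file path.
#' @return data.frame of typed patient records.
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  unknown <- setdiff(names(df), .COHORT_COLUMNS)
  if (length(unknown))
    stop("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "))
  required <- setdiff(.COHORT_COLUMNS, "ffr")
  absent <- setdiff(required, names(df))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  toNum <- function(col, nm) {
    col[col == ""] <- NA
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad))
      stop(sprintf("unparseable %s value '%s' at row %d", nm, col[bad[1]], bad[1]))
    out
  }
  for (nm in intersect(.COHORT_NUMERIC, names(df))) df[[nm]] <- toNum(df[[nm]], nm)
  checkRange <- function(nm, lo, hi, loOpen = FALSE) {
    x <- df[[nm]]
    bad <- which(!is.na(x) & ((if (loOpen) x <= lo else x < lo) | x > hi))
    if (length(bad))
      stop(sprintf("%s value %g out of range %s%g, %g] at row %d", nm,
        x[bad[1]], if (loOpen) "(" else "[", lo, hi, bad[1]))
  }
  checkRange("ds", 0, 100)
  checkRange("lvef", 0, 100)
  if ("ffr" %in% names(df)) checkRange("ffr", 0, 1, loOpen = TRUE)
  if ("cc" %in% names(df)) {
    cc <- tolower(df$cc)
    cc[cc == ""] <- NA
    df$cc <- cc %in% c("true", "1", "present", "yes")
    df$cc[is.na(cc)] <- NA
  }
  df
}

#' Write a patient cohort to CSV
#'
#' @param cohort data.frame of patient records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
    na = "")
  invisible(path)
}

.readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a hierarchy configuration (YAML or JSON)
#'
#' Expected structure: `target`, and `criteria`, a list of
#' `{name, weight, factors: [{name, weight}, ...]}`. The packaged
#' reference configuration is at
#' `system.file("extdata", "ffr_hierarchy.yaml", package = "ffrscore")`.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return a [Hierarchy-class].
#' @export
readHierarchy <- function(path) {
  doc <- .readConfigFile(path)
  if (is.null(doc$target) || is.null(doc$criteria))
    stop("hierarchy config must contain 'target' and 'criteria'")
  crit <- stats::setNames(
    vapply(doc$criteria, function(x) as.numeric(x$weight), numeric(1)),
    vapply(doc$criteria, function(x) as.character(x$name), character(1)))
  factors <- lapply(doc$criteria, function(x) {
    stats::setNames(
      vapply(x$factors, function(f) as.numeric(f$weight), numeric(1)),
      vapply(x$factors, function(f) as.character(f$name), character(1)))
  })
  names(factors) <- names(crit)
  hierarchy(doc$target, crit, factors)
}

.parseOneMatrix <- function(doc) {
  labels <- as.character(doc$labels)
  if (!is.null(doc$matrix)) {
    n <- length(labels)
    entries <- matrix(as.numeric(unlist(doc$matrix)), nrow = n, byrow = TRUE)
    comparisonMatrix(entries, labels = labels,
      provenance = list(source = "explicit"))
  } else if (!is.null(doc$odds_ratios)) {
    or <- unlist(doc$odds_ratios)
    if (length(labels)) or <- stats::setNames(as.numeric(or), labels)
    mapping <- if (is.null(doc$mapping)) "ratio" else doc$mapping
    matrixFromOddsRatios(or, mapping = mapping)
  } else {
    stop("comparison config must contain either 'matrix' or 'odds_ratios'")
  }
}

#' Read importance-degree matrices (YAML or JSON)
#'
#' A document holds either a single matrix (`labels` plus row-major
#' `matrix`, or `odds_ratios` plus optional `mapping`) or a list of such
#' blocks under `matrices`, each with a `name`.
#'
#' @param path file path.
#' @return a named list of [ComparisonMatrix-class] objects (single
#'   matrices get name "matrix").
#' @export
readComparisonConfig <- function(path) {
  doc <- .readConfigFile(path)
  if (!is.null(doc$matrices)) {
    out <- lapply(doc$matrices, .parseOneMatrix)
    names(out) <- vapply(doc$matrices, function(x)
      as.character(x$name %||% "matrix"), character(1))
    out
  } else {
    list(matrix = .parseOneMatrix(doc))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scoring form as JSON
#'
#' The JSON document round-trips losslessly:
#' `{schema_version, items: [{factor, field, op, value, points}], total_points, cutoff}`.
#'
#' @param form a [ScoringForm-class].
#' @param path file path.
#' @return `writeScoringForm()` the path invisibly; `readScoringForm()` the
#'   form.
#' @export
writeScoringForm <- function(form, path) {
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    items = form@items,
    total_points = form@totalPoints,
    cutoff = form@cutoff
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}

#' @rdname writeScoringForm
#' @export
readScoringForm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(doc$items, stringsAsFactors = FALSE)
  items$value <- as.character(items$value)
  items$points <- as.numeric(items$points)
  new("ScoringForm", items = items,
    totalPoints = as.numeric(doc$total_points),
    cutoff = as.numeric(doc$cutoff))
}

#' Write global weights to CSV or JSON
#'
#' @param gwt a [GlobalWeightTable-class].
#' @param path output path; format chosen by extension (.csv or .json).
#' @return the path, invisibly.
#' @export
writeGlobalWeights <- function(gwt, path) {
  tb <- globalWeights(gwt)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(schema_version = .SCHEMA_VERSION, weights = tb),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report an evaluation result from [evaluateCohort()].
#' @param path output path.
#' @param rocCsv optional path for a CSV export of the ROC points.
#' @return the path, invisibly.
#' @export
writeEvaluationReport <- function(report, path, rocCsv = NULL) {
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    n = report$n,
    auc = report$auc[c("auc", "ciLower", "ciUpper", "ciMethod")],
    ds_auc = report$dsAuc[c("auc", "ciLower", "ciUpper", "ciMethod")],
    cutoff = report$cutoff,
    metrics = report$metrics,
    mean_score = report$meanScore,
    sd_score = report$sdScore
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(rocCsv))
    utils::write.csv(report$auc$rocPoints, rocCsv, row.names = FALSE)
  invisible(path)
}
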