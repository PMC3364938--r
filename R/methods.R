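## Accessors and show() methods for the result classes.

#' @rdname result-accessors
#' @export
setMethod("pValue", "RelativeDistanceResult",
          function(x) min(x@ksP, x@areaP))
#' @rdname result-accessors
#' @export
setMethod("pValue", "AbsoluteDistanceResult", function(x) x@p)
#' @rdname result-accessors
#' @export
setMethod("pValue", "ProjectionResult", function(x) x@p)
#' @rdname result-accessors
#' @export
setMethod("pValue", "JaccardResult", function(x) x@p)

#' @rdname result-accessors
#' @export
setMethod("testStatistic", "RelativeDistanceResult",
          function(x) x@correlation)
#' @rdname result-accessors
#' @export
setMethod("testStatistic", "AbsoluteDistanceResult",
          function(x) x@meanScaledDistance)
#' @rdname result-accessors
#' @export
setMethod("testStatistic", "ProjectionResult", function(x) x@nHits)
#' @rdname result-accessors
#' @export
setMethod("testStatistic", "JaccardResult", function(x) x@jaccard)

#' @rdname result-accessors
#' @export
setMethod("direction", "RelativeDistanceResult", function(x) x@direction)
#' @rdname result-accessors
#' @export
setMethod("direction", "AbsoluteDistanceResult", function(x) x@direction)
#' @rdname result-accessors
#' @export
setMethod("direction", "ProjectionResult", function(x) x@direction)
#' @rdname result-accessors
#' @export
setMethod("direction", "JaccardResult", function(x) x@direction)

#' @rdname result-accessors
#' @export
setMethod("sampleSize", "RelativeDistanceResult", function(x) x@nQuery)
#' @rdname result-accessors
#' @export
setMethod("sampleSize", "AbsoluteDistanceResult", function(x) x@nQuery)
#' @rdname result-accessors
#' @export
setMethod("sampleSize", "ProjectionResult", function(x) x@nQuery)
#' @rdname result-accessors
#' @export
setMethod("sampleSize", "JaccardResult", function(x) x@nPerm)

fmtP <- function(p) format.pval(p, digits = 3, eps = 1e-16)

setMethod("show", "RelativeDistanceResult", function(object) {
  cat("Relative distance test [", object@scope, "]\n", sep = "")
  cat("  n query points: ", object@nQuery,
      if (object@nDropped > 0L)
        paste0(" (", object@nDropped, " dropped outside reference span)"),
      "\n", sep = "")
  cat("  KS statistic: ", signif(object@ksStatistic, 4),
      "  p = ", fmtP(object@ksP), "\n", sep = "")
  cat("  ECDF area S: ", signif(object@areaS, 4),
      "  permutation p = ", fmtP(object@areaP), "\n", sep = "")
  cat("  correlation (4S): ", signif(object@correlation, 4),
      "  direction: ", object@direction, "\n", sep = "")
})

setMethod("show", "AbsoluteDistanceResult", function(object) {
  cat("Absolute distance test [", object@scope, "]\n", sep = "")
  cat("  n query points: ", object@nQuery, "\n", sep = "")
  cat("  mean scaled distance: ", signif(object@meanScaledDistance, 4),
      " (permutation mean ", signif(object@permMean, 4), ")\n", sep = "")
  cat("  p = ", fmtP(object@p), " (", object@nPerm, " permutations)",
      "  direction: ", object@direction, "\n", sep = "")
})

setMethod("show", "ProjectionResult", function(object) {
  cat("Projection test [", object@scope, "]\n", sep = "")
  cat("  ", object@nHits, " of ", object@nQuery,
      " query points in reference intervals (coverage ",
      signif(object@coverageP, 4), ")\n", sep = "")
  cat("  binomial p = ", fmtP(object@p),
      "  direction: ", object@direction, "\n", sep = "")
  if (object@lowInformation)
    cat("  note: coverage near 0 or 1; test unlikely to be informative\n")
})

setMethod("show", "JaccardResult", function(object) {
  cat("Jaccard test [", object@scope, "]\n", sep = "")
  cat("  Jaccard statistic: ", signif(object@jaccard, 6), "\n", sep = "")
  cat("  p = ", fmtP(object@p), " (", object@nPerm, " permutations)",
      "  direction: ", object@direction, "\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
  cat("Association run configuration\n")
  cat("  query:     ", object@query, " (", object@queryFormat, ")\n", sep = "")
  cat("  reference: ", object@reference, " (", object@referenceFormat, ")\n",
      sep = "")
  cat("  genome:    ", object@genome, "\n", sep = "")
  if (!is.null(object@mask)) cat("  mask:      ", object@mask, "\n", sep = "")
  cat("  tests: ", paste(object@tests, collapse = ", "),
      "  (nPerm = ", object@nPerm, ", seed = ", object@seed, ")\n", sep = "")
  cat("  both directions: ", object@bothDirections,
      ", alpha = ", object@alpha, "\n", sep = "")
})

setMethod("show", "AssociationReport", function(object) {
  cat("AssociationReport:", length(object@results), "direction(s)\n")
  for (dir in names(object@results)) {
    scopes <- names(object@results[[dir]])
    cat("  ", dir, ": ", length(scopes), " scope(s) [",
        paste(utils::head(scopes, 5), collapse = ", "),
        if (length(scopes) > 5) ", ...", "]\n", sep = "")
  }
  if (nrow(object@skipped))
    cat("  skipped:", nrow(object@skipped), "scope/test combination(s)\n")
  cat("Use reportTable() for a flat summary.\n")
})

#' Extract one result from a report
#'
#' @param report an \linkS4class{AssociationReport}.
#' @param test one of \code{"relative"}, \code{"absolute"},
#'   \code{"projection"}, \code{"jaccard"}.
#' @param scope chromosome name or \code{"genome"} (default).
#' @param direction \code{"query_vs_reference"} (default) or
#'   \code{"reference_vs_query"}.
#' @return the stored result object, or NULL if that scope/test was skipped.
#' @export
getResult <- function(report, test, scope = "genome",
                      direction = "query_vs_reference") {
  stopifnot(is(report, "AssociationReport"))
  report@results[[direction]][[scope]][[test]]
}
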