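#' @title Accessor generics for association-test results
#'
#' @description Every test in the package returns an S4 result object; these
#' generics give uniform access to the primary statistic, p-value, direction
#' call and sample size.
#'
#' @param x a result object
#' (\linkS4class{RelativeDistanceResult},
#' \linkS4class{AbsoluteDistanceResult},
#' \linkS4class{ProjectionResult} or \linkS4class{JaccardResult}).
#'
#' @return \code{pValue}: the test's p-value (for the relative-distance test,
#' the smaller of the KS and ECDF-area p-values). \code{testStatistic}: the
#' primary statistic. \code{direction}: one of \code{"closer"},
#' \code{"farther"}, \code{"overlapping"}, \code{"nonoverlapping"} or
#' \code{"none"}. \code{sampleSize}: the number of query points (or
#' permutations for the Jaccard test, see the class documentation).
#'
#' @name result-accessors
#' @aliases pValue testStatistic direction sampleSize
#' @examples
#' res <- projectionTest(
#'   GenomicRanges::GRanges("chrA", IRanges::IRanges(c(10, 500), width = 1)),
#'   GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 400),
#'     seqlengths = c(chrA = 1000)))
#' pValue(res)
#' direction(res)
NULL

#' @rdname result-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname result-accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))

#' @rdname result-accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname result-accessors
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))
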