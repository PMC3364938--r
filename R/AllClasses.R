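## S4 classes for test results, run configuration and the nested report.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Result of the relative-distance test
#'
#' Holds the two inference routes on the relative distances \eqn{d_i}: the
#' one-sample Kolmogorov-Smirnov test of \eqn{2 d_i} against Uniform(0,1),
#' and the permutation test on the signed area \eqn{S} between the empirical
#' CDF of the \eqn{d_i} and the uniform-null straight line, together with
#' the rescaled correlation-like measure \eqn{4S = 1 - 4\,\mathrm{mean}(d)}.
#'
#' @slot nQuery number of query points used.
#' @slot nDropped query points discarded by \code{edgeMode = "drop"}.
#' @slot ksStatistic,ksP Kolmogorov-Smirnov statistic and two-sided
#'   asymptotic p-value.
#' @slot areaS signed ECDF-area statistic \eqn{S \in [-1/4, 1/4]}; positive
#'   means query points sit closer to references than expected.
#' @slot areaP permutation p-value for \eqn{|S|} (add-one corrected).
#' @slot correlation \eqn{4S \in [-1, 1]}: 1 when every query point
#'   coincides with a reference point, -1 when every query point falls in
#'   the middle of its reference gap, 0 in expectation under independence.
#' @slot direction \code{"closer"}, \code{"farther"} or \code{"none"}
#'   (significance at the reporting alpha required for a non-"none" call).
#' @slot scope chromosome name or \code{"genome"}.
#'
#' @seealso [relativeDistanceTest()]
#' @export
setClass("RelativeDistanceResult",
  representation(
    nQuery = "integer", nDropped = "integer",
    ksStatistic = "numeric", ksP = "numeric",
    areaS = "numeric", areaP = "numeric",
    correlation = "numeric", direction = "character",
    scope = "character"))

setValidity("RelativeDistanceResult", function(object) {
  msg <- NULL
  if (object@nQuery < 1L) msg <- c(msg, "nQuery must be >= 1")
  if (abs(object@correlation) > 1 + 1e-12)
    msg <- c(msg, "correlation must lie in [-1, 1]")
  for (s in c("ksP", "areaP")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must lie in [0, 1]"))
  }
  if (!object@direction %in% c("closer", "farther", "none"))
    msg <- c(msg, "invalid direction")
  if (is.null(msg)) TRUE else msg
})

#' Result of the scaled absolute minimal-distance test
#'
#' The statistic is the mean over query points of the distance to the
#' nearest reference point, scaled by the expected inter-reference gap for
#' the chromosome; the lower it is, the closer together the two sets tend
#' to be.  Significance is assessed by redrawing the query points uniformly
#' along each chromosome.
#'
#' @slot nQuery number of query points.
#' @slot meanScaledDistance observed mean scaled distance.
#' @slot p two-sided permutation p-value (doubled one-tail, add-one
#'   corrected, hence always > 0).
#' @slot direction \code{"closer"} when the observed mean is below the
#'   permutation median, \code{"farther"} when above, \code{"none"} on a tie.
#' @slot permMean mean of the permuted statistics (used as the null
#'   reference line in plots).
#' @slot nPerm number of permutations.
#' @slot scope chromosome name or \code{"genome"}.
#'
#' @seealso [absoluteDistanceTest()]
#' @export
setClass("AbsoluteDistanceResult",
  representation(
    nQuery = "integer", meanScaledDistance = "numeric",
    p = "numeric", direction = "character",
    permMean = "numeric", nPerm = "integer", scope = "character"))

setValidity("AbsoluteDistanceResult", function(object) {
  msg <- NULL
  if (object@meanScaledDistance < 0)
    msg <- c(msg, "meanScaledDistance must be >= 0")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (!object@direction %in% c("closer", "farther", "none"))
    msg <- c(msg, "invalid direction")
  if (is.null(msg)) TRUE else msg
})

#' Result of the projection (binomial) test
#'
#' Under independence, the probability that a query point falls inside a
#' reference interval equals the fraction of the chromosome covered by the
#' (merged) reference; the hit count is then binomial and an exact
#' two-sided binomial test is applied.
#'
#' @slot nQuery number of query points.
#' @slot nHits query points inside reference intervals.
#' @slot coverageP reference coverage fraction (the binomial success
#'   probability).
#' @slot p exact two-sided binomial p-value (minimum-likelihood convention).
#' @slot direction \code{"overlapping"} if \code{nHits} exceeds its
#'   expectation, \code{"nonoverlapping"} if below, \code{"none"} if equal.
#' @slot lowInformation TRUE when coverage is below 1\% or above 99\%, where
#'   the test carries little information.
#' @slot scope chromosome name or \code{"genome"}.
#'
#' @seealso [projectionTest()]
#' @export
setClass("ProjectionResult",
  representation(
    nQuery = "integer", nHits = "integer", coverageP = "numeric",
    p = "numeric", direction = "character", lowInformation = "logical",
    scope = "character"))

setValidity("ProjectionResult", function(object) {
  msg <- NULL
  if (object@nHits < 0L || object@nHits > object@nQuery)
    msg <- c(msg, "nHits must lie in [0, nQuery]")
  if (object@coverageP < 0 || object@coverageP > 1)
    msg <- c(msg, "coverageP must lie in [0, 1]")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (!object@direction %in% c("overlapping", "nonoverlapping", "none"))
    msg <- c(msg, "invalid direction")
  if (is.null(msg)) TRUE else msg
})

#' Result of the Jaccard overlap test
#'
#' The Jaccard statistic is the number of base pairs in the intersection of
#' the two (merged) interval sets divided by the base pairs in their union;
#' its null distribution is obtained by spacing-preserving randomization of
#' the query (circular rotation by default).
#'
#' @slot jaccard observed Jaccard statistic in [0, 1].
#' @slot p two-sided permutation p-value (add-one corrected).
#' @slot direction \code{"overlapping"} if the observed statistic is above
#'   the permutation median, \code{"nonoverlapping"} if below, else
#'   \code{"none"}.
#' @slot nPerm number of permutations.
#' @slot scope chromosome name or \code{"genome"}.
#'
#' @seealso [jaccardTest()], [jaccardStatistic()]
#' @export
setClass("JaccardResult",
  representation(
    jaccard = "numeric", p = "numeric", direction = "character",
    nPerm = "integer", scope = "character"))

setValidity("JaccardResult", function(object) {
  msg <- NULL
  if (object@jaccard < 0 || object@jaccard > 1)
    msg <- c(msg, "jaccard must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (!object@direction %in% c("overlapping", "nonoverlapping", "none"))
    msg <- c(msg, "invalid direction")
  if (is.null(msg)) TRUE else msg
})

#' Declarative run configuration
#'
#' Describes one full analysis: input paths and formats, the tests to run,
#' permutation counts, the master seed, edge/scaling conventions and output
#' location.  Usually built by [readRunConfig()] from an INI-style file so
#' the configuration can be archived for reproducibility, or directly with
#' [runConfig()].
#'
#' @slot query,reference input paths.
#' @slot queryFormat,referenceFormat \code{"bed"} or \code{"gff"}.
#' @slot genome path to a two-column chromosome-sizes file.
#' @slot mask optional BED path restricting the comparison to a subset.
#' @slot tests subset of \code{c("relative","absolute","projection","jaccard")}.
#' @slot nPerm permutations per test (>= 100).
#' @slot seed nonnegative integer master seed.
#' @slot edgeMode \code{"circular"} or \code{"drop"} (relative distances).
#' @slot gapScaling \code{"n+1"} or \code{"n"} (absolute-distance scaling).
#' @slot jaccardMode \code{"rotation"} or \code{"gap-shuffle"}.
#' @slot bothDirections run with the roles swapped as well (recommended:
#'   spatial association is asymmetric).
#' @slot alpha reporting significance level for direction calls.
#' @slot outDir output directory.
#' @slot skipUnknown tolerate records on chromosomes absent from the genome.
#'
#' @seealso [runCorrelation()]
#' @export
setClass("RunConfig",
  representation(
    query = "character", queryFormat = "character",
    reference = "character", referenceFormat = "character",
    genome = "character", mask = "characterOrNULL",
    tests = "character", nPerm = "integer", seed = "integer",
    edgeMode = "character", gapScaling = "character",
    jaccardMode = "character", bothDirections = "logical",
    alpha = "numeric", outDir = "character", skipUnknown = "logical"))

setValidity("RunConfig", function(object) {
  msg <- NULL
  bad <- setdiff(object@tests,
                 c("relative", "absolute", "projection", "jaccard"))
  if (length(bad)) msg <- c(msg, paste("unknown tests:", paste(bad, collapse = ", ")))
  if (length(object@tests) == 0L) msg <- c(msg, "no tests requested")
  if (object@nPerm < 100L) msg <- c(msg, "nPerm must be >= 100")
  if (object@seed < 0L) msg <- c(msg, "seed must be a nonnegative integer")
  if (!object@edgeMode %in% c("circular", "drop"))
    msg <- c(msg, "edgeMode must be 'circular' or 'drop'")
  if (!object@gapScaling %in% c("n+1", "n"))
    msg <- c(msg, "gapScaling must be 'n+1' or 'n'")
  if (!object@jaccardMode %in% c("rotation", "gap-shuffle"))
    msg <- c(msg, "jaccardMode must be 'rotation' or 'gap-shuffle'")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Nested report of a full association run
#'
#' Per direction (\code{query_vs_reference} and, when requested,
#' \code{reference_vs_query}), per scope (each chromosome plus the pooled
#' \code{"genome"}), one result object per requested test.  Chromosomes
#' that could not be tested are recorded with reasons rather than erroring.
#'
#' @slot results nested list: direction -> scope -> test -> result object.
#' @slot skipped data.frame with columns direction, scope, test, reason.
#' @slot meta run metadata (configuration echo, package version, seed).
#' @slot distances retained relative/absolute distance vectors per
#'   direction and scope, for plotting.
#'
#' @seealso [runCorrelation()], [correlateFeatures()], [reportTable()],
#'   [writeReport()]
#' @export
setClass("AssociationReport",
  representation(results = "list", skipped = "data.frame",
                 meta = "list", distances = "list"))
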