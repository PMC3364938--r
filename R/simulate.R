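## Synthetic feature-set generator.
##
## Produces query/reference GRanges pairs with a known spatial
## relationship, so calibration, power and asymmetry experiments run with
## no external data.  Counts are split across chromosomes in proportion to
## length; interval lengths default to 1 bp (pointwise) so that midpoint
## reduction is a no-op in baseline experiments.
##
## Relationship-specific defaults are the package's stated experimental
## world (see the methods vignette for the power analyses behind them):
##  * spike_in: 1 chromosome of 1 Mb, 1000 references, 2000 queries,
##    fraction 0.1 at offsets 75-100 bp among background offsets
##    10-10000 bp -- a dense-reference regime in which a fixed-offset
##    subpopulation is diluted in relative terms but detectable in
##    absolute terms.
##  * asymmetric: 30 sparse queries each within 40 bp of a member of a
##    10000-point dense reference -- association detectable only with the
##    sparse set as query.

#' Default simulation genome: four chromosomes of 1 Mb
#' @param nChrom number of chromosomes.
#' @param chromLength length of each chromosome in bp.
#' @return a Seqinfo.
#' @export
defaultGenome <- function(nChrom = 4L, chromLength = 1e6) {
  GenomeInfoDb::Seqinfo(paste0("chr", seq_len(nChrom)),
                        rep(as.integer(chromLength), nChrom))
}

#' Simulate a query/reference feature-set pair with a known relationship
#'
#' @param relationship one of \code{"independent"} (both sets uniform),
#'   \code{"coincident"} (query midpoints equal reference midpoints),
#'   \code{"fixed_offset"} (each query exactly \code{offset} bp from a
#'   reference midpoint, random sign), \code{"attraction"} (query displaced
#'   from references by two-sided exponential noise of scale
#'   \code{scale}), \code{"repulsion"} (query uniform within the middle
#'   third of inter-reference gaps), \code{"spike_in"} (fraction
#'   \code{fraction} of queries at offsets in \code{offsetRange} from a
#'   reference, the rest at offsets in \code{backgroundRange}), or
#'   \code{"asymmetric"} (a sparse query set of size \code{sparseN} near
#'   members of a dense reference of size \code{denseN}).
#' @param genome a Seqinfo; defaults depend on the relationship (see
#'   Details in the source; \code{spike_in} uses one 1 Mb chromosome,
#'   everything else [defaultGenome()]).
#' @param nQuery,nReference set sizes (relationship-specific defaults).
#' @param queryLength,referenceLength interval lengths in bp (default 1:
#'   pointwise features).
#' @param offset fixed offset in bp for \code{fixed_offset}; also the
#'   maximal anchor offset for \code{asymmetric} (default 40).
#' @param scale Laplace-like displacement scale for \code{attraction}.
#' @param fraction spiked fraction for \code{spike_in}.
#' @param offsetRange,backgroundRange offset windows (bp) for
#'   \code{spike_in}.
#' @param sparseN,denseN set sizes for \code{asymmetric}.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with elements \code{query} (GRanges), \code{reference}
#'   (GRanges) and \code{truth} (the generating relationship and
#'   parameters, for test assertions).
#' @examples
#' sim <- simulateFeatureSets("coincident", nQuery = 50, seed = 1)
#' relativeDistanceTest(sim$query, sim$reference, nPerm = 100, seed = 1)
#' @export
simulateFeatureSets <- function(relationship = c("independent", "coincident",
                                                 "fixed_offset", "attraction",
                                                 "repulsion", "spike_in",
                                                 "asymmetric"),
                                genome = NULL,
                                nQuery = NULL, nReference = NULL,
                                queryLength = 1L, referenceLength = 1L,
                                offset = NULL, scale = 100,
                                fraction = 0.1,
                                offsetRange = c(75, 100),
                                backgroundRange = c(10, 10000),
                                sparseN = 30L, denseN = 10000L,
                                seed = NULL) {
  relationship <- match.arg(relationship)
  if (is.null(genome))
    genome <- if (relationship == "spike_in") defaultGenome(1L)
              else defaultGenome()
  if (is.null(nReference))
    nReference <- switch(relationship, spike_in = 1000L, asymmetric = denseN,
                         200L)
  if (is.null(nQuery))
    nQuery <- switch(relationship, spike_in = 2000L, asymmetric = sparseN,
                     200L)
  if (is.null(offset))
    offset <- if (relationship == "asymmetric") 40 else 500
  lens <- GenomeInfoDb::seqlengths(genome)
  if (relationship == "fixed_offset" && offset >= min(lens))
    stop("offset must be smaller than every chromosome length")
  if (max(queryLength, referenceLength) > min(lens))
    stop("interval length exceeds chromosome length")
  withSeed(seed, {
    refPos <- uniformPositions(nReference, lens)
    qPos <- switch(relationship,
      independent = uniformPositions(nQuery, lens),
      coincident = resamplePositions(refPos, nQuery),
      fixed_offset = offsetPositions(refPos, nQuery, lens,
                                     function(n) rep(offset, n)),
      attraction = offsetPositions(refPos, nQuery, lens,
                                   function(n) stats::rexp(n, 1 / scale)),
      repulsion = repulsionPositions(refPos, nQuery, lens),
      spike_in = spikeInPositions(refPos, nQuery, lens, fraction,
                                  offsetRange, backgroundRange),
      asymmetric = offsetPositions(refPos, nQuery, lens,
                                   function(n) stats::runif(n, 0, offset)))
    list(query = positionsToGRanges(qPos, genome, queryLength),
         reference = positionsToGRanges(refPos, genome, referenceLength),
         truth = list(relationship = relationship, nQuery = nQuery,
                      nReference = nReference, offset = offset,
                      scale = scale, fraction = fraction,
                      offsetRange = offsetRange,
                      backgroundRange = backgroundRange, seed = seed))
  })
}

## n uniform 0-based positions split across chromosomes in proportion to
## length; returns a named list of sorted vectors.
uniformPositions <- function(n, lens) {
  chrom <- sample(names(lens), n, replace = TRUE,
                  prob = as.numeric(lens) / sum(as.numeric(lens)))
  pos <- floor(stats::runif(n) * as.numeric(lens[chrom]))
  f <- factor(chrom, levels = names(lens))
  lapply(split(as.numeric(pos), f), sort)
}

## Cyclic recycling (not resampling) so that whenever nQuery >= nReference
## every reference midpoint reappears in the query: the coincident
## relationship is then exactly symmetric under role reversal.
resamplePositions <- function(refPos, nQuery) {
  nr <- lengths(refPos)
  take <- distributeCounts(nQuery, nr)
  Map(function(p, k) {
    if (k == 0L || length(p) == 0L) return(numeric(0))
    sort(rep_len(p, k))
  }, refPos, take)
}

## Split n among chromosomes proportionally to weights (largest remainder).
distributeCounts <- function(n, weights) {
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## Place query points at |offsetFun| bp (random sign) from resampled
## reference anchors, wrapping circularly to stay on the chromosome.
offsetPositions <- function(refPos, nQuery, lens, offsetFun) {
  nr <- lengths(refPos)
  take <- distributeCounts(nQuery, nr)
  out <- Map(function(p, k, L) {
    if (k == 0L || length(p) == 0L) return(numeric(0))
    anchors <- sample(p, k, replace = TRUE)
    disp <- sample(c(-1, 1), k, replace = TRUE) * offsetFun(k)
    sort(floor(anchors + disp) %% L)
  }, refPos, take, as.list(as.numeric(lens)))
  out
}

## Query uniform within the middle third of circular inter-reference gaps
## (gap chosen with probability proportional to its length).
repulsionPositions <- function(refPos, nQuery, lens) {
  nr <- lengths(refPos)
  take <- distributeCounts(nQuery, nr)
  out <- Map(function(p, k, L) {
    if (k == 0L || length(p) == 0L) return(numeric(0))
    gapStart <- p
    gapLen <- if (length(p) == 1L) L else c(diff(p), L - p[length(p)] + p[1L])
    gi <- sample.int(length(gapLen), k, replace = TRUE, prob = gapLen)
    u <- stats::runif(k, 1 / 3, 2 / 3)
    sort(floor(gapStart[gi] + u * gapLen[gi]) %% L)
  }, refPos, take, as.list(as.numeric(lens)))
  out
}

spikeInPositions <- function(refPos, nQuery, lens, fraction,
                             offsetRange, backgroundRange) {
  nr <- lengths(refPos)
  take <- distributeCounts(nQuery, nr)
  out <- Map(function(p, k, L) {
    if (k == 0L || length(p) == 0L) return(numeric(0))
    ns <- round(fraction * k)
    anchors <- sample(p, k, replace = TRUE)
    off <- c(stats::runif(ns, offsetRange[1L], offsetRange[2L]),
             stats::runif(k - ns, backgroundRange[1L], backgroundRange[2L]))
    disp <- sample(c(-1, 1), k, replace = TRUE) * off
    sort(floor(anchors + disp) %% L)
  }, refPos, take, as.list(as.numeric(lens)))
  out
}

## Positions (0-based midpoints) -> GRanges of the requested width, clipped
## to the chromosome.
positionsToGRanges <- function(pos, genome, width) {
  lens <- GenomeInfoDb::seqlengths(genome)
  chroms <- rep(names(pos), lengths(pos))
  p <- unlist(pos, use.names = FALSE)
  if (length(p) == 0L) return(GenomicRanges::GRanges(seqinfo = genome))
  ## width-w interval whose covered-base midpoint (round-down rule) is p
  start1 <- pmax(1, p + 1 - floor((width - 1) / 2))
  end1 <- pmin(as.numeric(lens[chroms]), start1 + width - 1)
  start1 <- pmax(1, pmin(start1, end1 - width + 1))
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(start1, end1),
                               seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a simulated dataset to disk
#'
#' Writes \code{query.bed}, \code{reference.bed}, \code{genome.sizes} and
#' \code{truth.json} under \code{dir}.
#'
#' @param sim result of [simulateFeatureSets()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatures(sim$query, file.path(dir, "query.bed"))
  writeFeatures(sim$reference, file.path(dir, "reference.bed"))
  writeChromSizes(GenomeInfoDb::seqinfo(sim$query),
                  file.path(dir, "genome.sizes"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
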