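## Projection (binomial) test and Jaccard overlap test.
##
## Projection: under independence a query point lands inside a reference
## interval with probability equal to the reference coverage fraction, so
## the hit count is binomial; an exact two-sided binomial test (minimum
## likelihood convention, as in stats::binom.test) gives the p-value.
##
## Jaccard: base pairs in the intersection over base pairs in the union of
## the merged sets.  The null preserves the query's internal spacing: each
## permutation applies an independent uniform circular rotation per
## chromosome (default), or randomly permutes the circular inter-interval
## gaps and applies a uniform phase ("gap-shuffle").

#' Projection test: query points in reference intervals
#'
#' @param query GRanges; intervals are reduced to midpoints.
#' @param reference GRanges of intervals (merged internally).
#' @param chrom single chromosome name, or NULL for the whole genome
#'   (hit counts and coverage are summed over chromosomes before the
#'   single binomial test).
#' @return a \linkS4class{ProjectionResult}, or NULL (with a warning) when
#'   there are no query points in scope.  The result carries a
#'   low-information flag when the reference coverage is below 1\% or
#'   above 99\%.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrA", 1000)
#' q <- GenomicRanges::GRanges("chrA", IRanges::IRanges(c(100, 600), width = 1),
#'   seqinfo = si)
#' r <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 500), seqinfo = si)
#' projectionTest(q, r)
#' @export
projectionTest <- function(query, reference, chrom = NULL) {
  ref <- normalizeFeatures(reference)
  mid <- featureMidpoints(query)
  if (!is.null(chrom)) {
    lens <- GenomeInfoDb::seqlengths(query)
    if (!chrom %in% names(lens)) stop("unknown chromosome '", chrom, "'")
    mid <- mid[GenomicRanges::seqnames(mid) == chrom]
    ref <- ref[GenomicRanges::seqnames(ref) == chrom]
    total <- as.numeric(lens[[chrom]])
  } else {
    total <- sum(as.numeric(GenomeInfoDb::seqlengths(query)))
  }
  nq <- length(mid)
  if (nq == 0L) {
    warning("no query points in scope; skipping projection test")
    return(NULL)
  }
  hits <- sum(GenomicRanges::countOverlaps(mid, ref,
                                           ignore.strand = TRUE) > 0L)
  covP <- sum(GenomicRanges::width(ref)) / total
  ## degenerate coverages: the hit count is deterministic under the null
  p <- if (covP == 0) as.numeric(hits == 0)
       else if (covP == 1) as.numeric(hits == nq)
       else stats::binom.test(hits, nq, p = covP)$p.value
  expct <- nq * covP
  dir <- if (hits > expct) "overlapping"
         else if (hits < expct) "nonoverlapping" else "none"
  new("ProjectionResult",
      nQuery = as.integer(nq), nHits = as.integer(hits),
      coverageP = covP, p = p, direction = dir,
      lowInformation = covP < 0.01 || covP > 0.99,
      scope = if (is.null(chrom)) "genome" else chrom)
}

#' Jaccard statistic of two interval sets
#'
#' Base pairs in the intersection divided by base pairs in the union of
#' the merged sets over the scope; symmetric in its arguments; defined as
#' 0 (with a warning) when both sets are empty on the scope.
#'
#' @param query,reference GRanges (merged internally).
#' @param chrom single chromosome name, or NULL for the whole genome.
#' @return a fraction in [0, 1].
#' @export
jaccardStatistic <- function(query, reference, chrom = NULL) {
  q <- normalizeFeatures(query)
  r <- normalizeFeatures(reference)
  if (!is.null(chrom)) {
    q <- q[GenomicRanges::seqnames(q) == chrom]
    r <- r[GenomicRanges::seqnames(r) == chrom]
  }
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(q, r, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(
    GenomicRanges::union(q, r, ignore.strand = TRUE)))
  if (uni == 0) {
    warning("both interval sets empty on scope; Jaccard statistic set to 0")
    return(0)
  }
  inter / uni
}

#' Jaccard test with spacing-preserving permutation
#'
#' The observed statistic is compared with \code{nPerm} permuted values in
#' which the query set is relocated on each chromosome without changing
#' interval lengths or (for rotation) inter-interval gaps.  Two-sided
#' add-one-corrected p-value; direction is \code{"overlapping"} when the
#' observed statistic exceeds the permutation median.
#'
#' @param query,reference GRanges with seqlengths (merged internally).
#' @param chrom single chromosome name, or NULL for the whole genome
#'   (per-chromosome intersections/unions are summed into one statistic;
#'   permutations still act independently per chromosome).
#' @param nPerm number of permutations (>= 100).
#' @param seed optional integer seed.
#' @param mode \code{"rotation"} (circular shift, the only transformation
#'   preserving all spacings exactly) or \code{"gap-shuffle"} (random
#'   permutation of the circular gaps plus a uniform phase).
#' @return a \linkS4class{JaccardResult}, or NULL (with a warning) when
#'   the query is empty on the scope.
#' @export
jaccardTest <- function(query, reference, chrom = NULL, nPerm = 1000L,
                        seed = NULL, mode = c("rotation", "gap-shuffle")) {
  mode <- match.arg(mode)
  if (nPerm < 100L) stop("nPerm must be >= 100")
  q <- normalizeFeatures(query)
  r <- normalizeFeatures(reference)
  lens <- GenomeInfoDb::seqlengths(q)
  chroms <- if (is.null(chrom)) names(lens) else chrom
  qiv <- intervalsByChrom(q, chroms)
  riv <- intervalsByChrom(r, chroms)
  if (sum(vapply(qiv, function(x) length(x$start), integer(1))) == 0L) {
    warning("query empty on scope; skipping Jaccard test")
    return(NULL)
  }
  ## observed statistic via the same sweep kernel as the permutations
  ## (asserted equal to the GRanges intersect/union route in the tests)
  obs <- observedJaccard(qiv, riv, chroms)
  perm <- withSeed(seed,
    permutedJaccard(qiv, riv, lens, chroms, nPerm, mode))
  tails <- permPvalues(obs, perm)
  med <- stats::median(perm)
  dir <- if (obs > med) "overlapping"
         else if (obs < med) "nonoverlapping" else "none"
  new("JaccardResult",
      jaccard = obs, p = tails$p, direction = dir,
      nPerm = as.integer(nPerm),
      scope = if (is.null(chrom)) "genome" else chrom)
}

## ---- numeric kernels (0-based half-open, disjoint sorted intervals) ----

intervalsByChrom <- function(gr, chroms) {
  sn <- as.character(GenomicRanges::seqnames(gr))
  out <- lapply(chroms, function(ch) {
    i <- sn == ch
    list(start = GenomicRanges::start(gr)[i] - 1,
         end = as.numeric(GenomicRanges::end(gr)[i]))
  })
  names(out) <- chroms
  out
}

## Cumulative covered bp of a disjoint sorted set below position x (0-based).
## Returns a function F usable on vectors.
coverageCumFun <- function(rs, re) {
  if (length(rs) == 0L) return(function(x) numeric(length(x)))
  cumBefore <- c(0, cumsum(re - rs))
  function(x) {
    idx <- findInterval(x, rs)
    ifelse(idx == 0L, 0,
           cumBefore[pmax(idx, 1L)] +
             pmax(0, pmin(x, re[pmax(idx, 1L)]) - rs[pmax(idx, 1L)]))
  }
}

## Intersection bp between a fixed set (via its F) and intervals given as
## 0-based starts `a` (possibly wrapping) with widths `w` on a ring of
## length L.
wrappedIntersection <- function(a, w, FR, FL, L) {
  b <- a + w
  noWrap <- b <= L
  out <- numeric(length(a))
  out[noWrap] <- FR(b[noWrap]) - FR(a[noWrap])
  if (any(!noWrap))
    out[!noWrap] <- (FL - FR(a[!noWrap])) + FR(b[!noWrap] - L)
  sum(out)
}

## All rotation permutations at once: intersection bp for every shift, one
## flattened findInterval pass instead of a per-permutation loop.
rotationIntersections <- function(qs, w, FR, FL, L, shifts) {
  nq <- length(qs)
  a <- (rep(qs, times = length(shifts)) +
          rep(shifts, each = nq)) %% L
  b <- a + rep(w, times = length(shifts))
  v <- numeric(length(a))
  noWrap <- b <= L
  v[noWrap] <- FR(b[noWrap]) - FR(a[noWrap])
  if (any(!noWrap))
    v[!noWrap] <- (FL - FR(a[!noWrap])) + FR(b[!noWrap] - L)
  colSums(matrix(v, nrow = nq))
}

## Explicit circular rotation of disjoint intervals; wrapping intervals are
## split in two.  Used by tests and kept as the reference implementation
## for the fast path above.
rotateIntervals <- function(start, end, chromLength, shift) {
  if (length(start) == 0L)
    return(list(start = numeric(0), end = numeric(0)))
  w <- end - start
  a <- (start + shift) %% chromLength
  b <- a + w
  wrap <- b > chromLength
  ns <- c(a[!wrap], a[wrap], rep(0, sum(wrap)))
  ne <- c(b[!wrap], rep(chromLength, sum(wrap)), b[wrap] - chromLength)
  o <- order(ns)
  list(start = ns[o], end = ne[o])
}

## nPerm permuted genome-scope Jaccard values.  Intersections are summed
## across chromosomes; each chromosome gets an independent shift (and, for
## gap-shuffle, gap permutation) per iteration.
permutedJaccard <- function(qiv, riv, lens, chroms, nPerm, mode) {
  interM <- matrix(0, nrow = nPerm, ncol = length(chroms))
  bpQ <- 0; bpR <- 0
  for (j in seq_along(chroms)) {
    ch <- chroms[j]
    qs <- qiv[[ch]]$start; qe <- qiv[[ch]]$end
    rs <- riv[[ch]]$start; re <- riv[[ch]]$end
    bpQ <- bpQ + sum(qe - qs); bpR <- bpR + sum(re - rs)
    if (length(qs) == 0L || length(rs) == 0L) next
    L <- as.numeric(lens[[ch]])
    FR <- coverageCumFun(rs, re)
    FL <- FR(L)
    w <- qe - qs
    shifts <- floor(stats::runif(nPerm) * L)
    if (mode == "rotation") {
      interM[, j] <- rotationIntersections(qs, w, FR, FL, L, shifts)
    } else {
      gaps <- circularGaps(qs, qe, L)
      for (i in seq_len(nPerm)) {
        a <- gapShuffleStarts(w, gaps, shifts[i], L)
        interM[i, j] <- wrappedIntersection(a, w, FR, FL, L)
      }
    }
  }
  inter <- rowSums(interM)
  uni <- bpQ + bpR - inter
  ifelse(uni == 0, 0, inter / uni)
}

observedJaccard <- function(qiv, riv, chroms) {
  inter <- 0; bpQ <- 0; bpR <- 0
  for (ch in chroms) {
    qs <- qiv[[ch]]$start; qe <- qiv[[ch]]$end
    rs <- riv[[ch]]$start; re <- riv[[ch]]$end
    bpQ <- bpQ + sum(qe - qs); bpR <- bpR + sum(re - rs)
    if (length(qs) == 0L || length(rs) == 0L) next
    FR <- coverageCumFun(rs, re)
    inter <- inter + sum(FR(qe) - FR(qs))
  }
  uni <- bpQ + bpR - inter
  if (uni == 0) {
    warning("both interval sets empty on scope; Jaccard statistic set to 0")
    return(0)
  }
  inter / uni
}

## Circular gaps following each interval (last gap wraps around the origin).
circularGaps <- function(qs, qe, L) {
  n <- length(qs)
  if (n == 1L) return(L - (qe - qs))
  c(qs[-1L] - qe[-n], L - qe[n] + qs[1L])
}

## Interval starts after permuting the circular gaps and applying a phase;
## interval length order is preserved.
gapShuffleStarts <- function(w, gaps, phase, L) {
  g <- sample(gaps)
  (phase + c(0, cumsum(w[-length(w)] + g[-length(g)]))) %% L
}
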