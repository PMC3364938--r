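## Relative distance test.
##
## For each query point q with flanking reference points k_left <= q <
## k_right, the raw ratio is r = (q - k_left) / (k_right - k_left) and the
## relative distance is d = min(r, 1 - r), which is Uniform(0, 1/2) when
## query and reference are independent.  Uniformity is tested two ways:
## the one-sample Kolmogorov-Smirnov test, and a permutation test on the
## signed area S between the empirical CDF of the d_i and the straight
## line that is the uniform-null CDF.  4S rescales the area into a
## correlation-like measure in [-1, 1].

#' Relative distances of query points within flanking reference gaps
#'
#' Low-level kernel on numeric positions (0-based bp on one chromosome).
#' Reference positions are deduplicated (identical reference points would
#' create zero-width gaps).  With \code{edgeMode = "circular"} (default)
#' the chromosome is closed into a ring, so the last reference also flanks
#' query points lying before the first reference and every query point is
#' used; with \code{edgeMode = "drop"}, query points outside
#' \code{[first_ref, last_ref)} are excluded and their count is returned in
#' the \code{"nDropped"} attribute.
#'
#' @param query numeric vector of query positions in \code{[0, chromLength)}.
#' @param reference numeric vector of reference positions (>= 1 distinct
#'   point for circular mode, >= 2 for drop mode).
#' @param chromLength chromosome length in bp.
#' @param edgeMode \code{"circular"} or \code{"drop"}.
#' @return numeric vector of distances in [0, 1/2] with attribute
#'   \code{nDropped}; \code{NULL} (with a warning) when the reference has
#'   too few points, signalling that the chromosome should be skipped.
#' @examples
#' relativeDistances(c(125, 150), c(100, 200), 1000)   # 0.25, 0.5
#' relativeDistances(0, c(100, 900), 1000)             # circular: 0.5
#' @export
relativeDistances <- function(query, reference, chromLength,
                              edgeMode = c("circular", "drop")) {
  edgeMode <- match.arg(edgeMode)
  refs <- sort(unique(reference))
  m <- length(refs)
  need <- if (edgeMode == "circular") 1L else 2L
  if (m < need || length(query) == 0L) {
    warning("too few reference points on chromosome; skipping")
    return(NULL)
  }
  L <- chromLength
  if (edgeMode == "circular") {
    idx <- findInterval(query, refs)
    li <- ifelse(idx == 0L, m, idx)
    ri <- li %% m + 1L
    off <- (query - refs[li]) %% L
    gap <- (refs[ri] - refs[li]) %% L
    gap[gap == 0] <- L                 # single reference point: gap is the ring
    r <- off / gap
    nDropped <- 0L
  } else {
    keep <- query >= refs[1L] & query < refs[m]
    nDropped <- sum(!keep)
    q2 <- query[keep]
    if (length(q2) == 0L) {
      warning("no query points between the outermost references; skipping")
      return(NULL)
    }
    idx <- findInterval(q2, refs)
    r <- (q2 - refs[idx]) / (refs[idx + 1L] - refs[idx])
    r[q2 == refs[idx]] <- 0            # coincident points
  }
  d <- pmin(r, 1 - r)
  attr(d, "nDropped") <- as.integer(nDropped)
  d
}

#' Kolmogorov-Smirnov test of relative distances against the uniform null
#'
#' One-sample KS test of \eqn{2 d_i} against Uniform(0, 1) (equivalently,
#' of the \eqn{d_i} against Uniform(0, 1/2)); two-sided, asymptotic
#' p-value.
#'
#' @param d numeric vector of relative distances in [0, 1/2].
#' @return list with elements \code{statistic} and \code{p.value}.
#' @export
ksUniformTest <- function(d) {
  if (length(d) == 0L) stop("empty distance vector")
  if (any(d < 0 | d > 0.5)) stop("relative distances outside [0, 1/2]")
  ks <- suppressWarnings(stats::ks.test(2 * d, "punif", exact = FALSE))
  list(statistic = unname(ks$statistic), p.value = ks$p.value)
}

#' Signed area between the ECDF of relative distances and the uniform null
#'
#' \eqn{S = \int_0^{1/2} (\mathrm{ECDF}(x) - 2x)\,dx}, computed exactly
#' from the sorted sample (piecewise-constant ECDF against the straight
#' line).  Positive S means the distances pile up near 0 (query attracted
#' to reference); negative S means they pile up near 1/2 (avoidance).
#'
#' @param d numeric vector of relative distances in [0, 1/2].
#' @return the signed area, in [-1/4, 1/4].
#' @examples
#' ecdfArea(rep(0, 5))     #  1/4
#' ecdfArea(rep(0.5, 5))   # -1/4
#' @export
ecdfArea <- function(d) {
  if (length(d) == 0L) stop("empty distance vector")
  if (any(d < 0 | d > 0.5)) stop("relative distances outside [0, 1/2]")
  n <- length(d)
  x <- c(sort(d), 0.5)
  ## ECDF is i/n on [x_i, x_{i+1}); integrate stepwise, subtract int 2x dx
  steps <- diff(x)
  sum((seq_len(n) / n) * steps) - 0.25
}

#' Permutation p-value for the ECDF-area statistic
#'
#' Draws \code{nQuery} values from the ideal Uniform(0, 1/2) distribution
#' \code{nPerm} times, recomputes the area each time, and returns the
#' two-sided add-one-corrected p-value
#' \eqn{(1 + \#\{|S_{perm}| \ge |S_{obs}|\}) / (nPerm + 1)}.
#'
#' @param areaObs observed area from [ecdfArea()].
#' @param nQuery number of query points behind the observation.
#' @param nPerm number of Monte-Carlo draws (>= 100).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return the permutation p-value.
#' @export
areaPermutationTest <- function(areaObs, nQuery, nPerm = 1000L, seed = NULL) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  withSeed(seed, {
    ## S for a uniform sample reduces to 1/4 - mean(d); see ecdfArea()
    means <- rowMeans(matrix(stats::runif(nPerm * nQuery, 0, 0.5),
                             nrow = nPerm))
    sPerm <- 0.25 - means
    (1 + sum(abs(sPerm) >= abs(areaObs))) / (nPerm + 1)
  })
}

#' Correlation-like measure derived from the ECDF area
#'
#' \eqn{4S = 1 - 4\,\mathrm{mean}(d)}: equals 1 when every query point
#' coincides with a reference point, -1 when every query point falls in
#' the middle of its reference gap, and 0 in expectation when the two sets
#' are independent.
#'
#' @param d numeric vector of relative distances in [0, 1/2].
#' @return a value in [-1, 1].
#' @export
correlationMeasure <- function(d) {
  if (length(d) == 0L) stop("empty distance vector")
  1 - 4 * mean(d)
}

## Direction call shared by the relative-distance wrappers.
relativeDirection <- function(correlation, ksP, areaP, alpha) {
  if (min(ksP, areaP) >= alpha || correlation == 0) "none"
  else if (correlation > 0) "closer"
  else "farther"
}

#' Relative distance test on GRanges feature sets
#'
#' High-level wrapper: reduces both sets to midpoints, computes relative
#' distances per chromosome (pooling them when \code{chrom} is NULL), and
#' runs the KS and ECDF-area tests.
#'
#' @param query,reference GRanges with seqlengths; intervals are reduced to
#'   midpoints.
#' @param chrom single chromosome name, or NULL to pool the whole genome.
#' @param nPerm permutations for the area test.
#' @param seed optional integer seed.
#' @param edgeMode passed to [relativeDistances()].
#' @param alpha reporting significance level for the direction call.
#' @return a \linkS4class{RelativeDistanceResult}, or NULL (with a warning)
#'   if no chromosome had enough data.
#' @export
relativeDistanceTest <- function(query, reference, chrom = NULL,
                                 nPerm = 1000L, seed = NULL,
                                 edgeMode = c("circular", "drop"),
                                 alpha = 0.05) {
  edgeMode <- match.arg(edgeMode)
  d <- pooledRelativeDistances(query, reference, chrom, edgeMode)
  if (is.null(d)) return(NULL)
  buildRelativeResult(d, nPerm, seed, alpha,
                      scope = if (is.null(chrom)) "genome" else chrom)
}

## Pool per-chromosome relative distances; NULL if nothing testable.
pooledRelativeDistances <- function(query, reference, chrom, edgeMode) {
  qp <- midpointPositions(query)
  rp <- midpointPositions(reference)
  lens <- GenomeInfoDb::seqlengths(query)
  chroms <- if (is.null(chrom)) names(qp) else chrom
  need <- if (edgeMode == "circular") 1L else 2L
  out <- list(); nDropped <- 0L
  for (ch in chroms) {
    if (length(qp[[ch]]) == 0L || length(unique(rp[[ch]])) < need) next
    di <- suppressWarnings(
      relativeDistances(qp[[ch]], rp[[ch]], lens[[ch]], edgeMode))
    if (is.null(di) || length(di) == 0L) next
    nDropped <- nDropped + attr(di, "nDropped")
    out[[ch]] <- as.numeric(di)
  }
  if (length(out) == 0L) {
    warning("no chromosome with enough query/reference points")
    return(NULL)
  }
  d <- unlist(out, use.names = FALSE)
  attr(d, "nDropped") <- nDropped
  d
}

buildRelativeResult <- function(d, nPerm, seed, alpha, scope) {
  ks <- ksUniformTest(d)
  S <- ecdfArea(d)
  areaP <- areaPermutationTest(S, length(d), nPerm, seed)
  corr <- correlationMeasure(d)
  new("RelativeDistanceResult",
      nQuery = length(d),
      nDropped = attr(d, "nDropped") %||% 0L,
      ksStatistic = ks$statistic, ksP = ks$p.value,
      areaS = S, areaP = areaP, correlation = corr,
      direction = relativeDirection(corr, ks$p.value, areaP, alpha),
      scope = scope)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
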