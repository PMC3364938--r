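## Independent brute-force oracles used to check the interval sweeps and
## closed forms.  All operate on 0-based half-open numeric intervals or
## 0-based point positions, and deliberately avoid the package's own
## code paths.

## Per-base membership vector of length L for intervals [start, end).
oracleMembership <- function(start, end, L) {
  v <- logical(L)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) v[(start[i] + 1):end[i]] <- TRUE
  }
  v
}

oracleJaccard <- function(qs, qe, rs, re, L) {
  q <- oracleMembership(qs, qe, L)
  r <- oracleMembership(rs, re, L)
  u <- sum(q | r)
  if (u == 0) 0 else sum(q & r) / u
}

oracleCoverage <- function(start, end, L) mean(oracleMembership(start, end, L))

## Minimal |q - k| by direct enumeration.
oracleMinDist <- function(q, refs) {
  vapply(q, function(x) min(abs(x - refs)), numeric(1))
}

## Relative distances by explicit flanking-point search (one query point
## at a time, modular arithmetic done longhand for the circular case).
oracleRelDist <- function(q, refs, L, circular = TRUE) {
  refs <- sort(unique(refs))
  m <- length(refs)
  out <- numeric(0)
  for (x in q) {
    left <- refs[refs <= x]
    right <- refs[refs > x]
    if (circular) {
      kl <- if (length(left)) max(left) else max(refs) - L
      kr <- if (length(right)) min(right) else min(refs) + L
      gap <- kr - kl
      if (gap == 0 || m == 1) { kl <- refs[1]; gap <- L }
      r <- ((x - kl) %% L) / gap
    } else {
      if (!length(left) || x >= refs[m]) next
      kl <- max(left)
      kr <- min(refs[refs > kl])
      if (x == kl) r <- 0 else r <- (x - kl) / (kr - kl)
    }
    out <- c(out, min(r, 1 - r))
  }
  out
}

## Two-sided binomial p by full enumeration (minimum-likelihood rule).
oracleBinomTwoSided <- function(k, n, p) {
  dens <- dbinom(0:n, n, p)
  sum(dens[dens <= dens[k + 1] * (1 + 1e-7)])
}

## Exact average scaled minimal distance over every base of a chromosome.
oracleExpectedScaledMin <- function(refs, L, nPlusOne = TRUE) {
  g <- if (nPlusOne) L / (length(refs) + 1) else L / length(refs)
  mean(oracleMinDist(0:(L - 1), refs)) / g
}

## Shorthand for a GRanges on a single test chromosome.
gr1 <- function(start1, end1, L = 1000, chrom = "chrA") {
  GenomicRanges::GRanges(rep(chrom, length(start1)),
                         IRanges::IRanges(start1, end1),
                         seqinfo = GenomeInfoDb::Seqinfo(chrom, L))
}

## GRanges of width-1 features at 0-based positions.
grPoints <- function(pos0, L = 1000, chrom = "chrA") {
  gr1(pos0 + 1, pos0 + 1, L, chrom)
}

## Random disjoint 0-based interval set on [0, L): returns list(start, end).
randomIntervalSet <- function(L, maxN = 20, maxLen = 500) {
  n <- sample.int(maxN, 1)
  s <- sort(sample.int(L, n)) - 1
  e <- pmin(L, s + sample.int(maxLen, n, replace = TRUE))
  ir <- IRanges::reduce(IRanges::IRanges(s + 1, e))
  list(start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
}
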