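test_that("relative distances match hand-computed flanking-gap ratios", {
  expect_equal(as.numeric(relativeDistances(150, c(100, 200), 1000)), 0.5)
  expect_equal(as.numeric(relativeDistances(125, c(100, 200), 1000)), 0.25)
  expect_equal(as.numeric(relativeDistances(100, c(100, 200), 1000)), 0)
  # circular closure: the wrap gap 900 -> 100 has length 200
  expect_equal(as.numeric(relativeDistances(0, c(100, 900), 1000)), 0.5)
  # a single reference on a ring: gap is the whole chromosome
  expect_equal(as.numeric(relativeDistances(c(500, 750), 250, 1000)),
               c(0.25, 0.5))
})

test_that("drop mode excludes points outside the reference span", {
  d <- relativeDistances(c(50, 125, 150, 250), c(100, 200), 1000, "drop")
  expect_equal(as.numeric(d), c(0.25, 0.5))
  expect_identical(attr(d, "nDropped"), 2L)
  expect_warning(relativeDistances(50, 100, 1000, "drop"), "too few")
})

test_that("relative distances agree with the brute-force flanking oracle", {
  set.seed(21)
  for (i in 1:50) {
    L <- sample(500:5000, 1)
    refs <- sort(sample.int(L, sample(2:20, 1))) - 1
    q <- sort(sample.int(L, 30, replace = TRUE)) - 1
    expect_equal(as.numeric(relativeDistances(q, refs, L)),
                 oracleRelDist(q, refs, L, circular = TRUE))
    dd <- suppressWarnings(relativeDistances(q, refs, L, "drop"))
    if (!is.null(dd))
      expect_equal(as.numeric(dd), oracleRelDist(q, refs, L, circular = FALSE))
  }
})

test_that("every relative distance lies in [0, 1/2] (circular and drop)", {
  set.seed(22)
  for (i in 1:200) {
    L <- sample(100:100000, 1)
    refs <- sample.int(L, sample(1:50, 1)) - 1
    q <- sample.int(L, sample(1:50, 1), replace = TRUE) - 1
    d <- relativeDistances(q, refs, L)
    expect_true(all(d >= 0 & d <= 0.5))
  }
})

test_that("circular distances are invariant under coordinate rotation", {
  set.seed(23)
  L <- 10000
  refs <- sample.int(L, 15) - 1
  q <- sample.int(L, 40) - 1
  d0 <- sort(as.numeric(relativeDistances(q, refs, L)))
  for (shift in sample.int(L, 5)) {
    d1 <- sort(as.numeric(relativeDistances((q + shift) %% L,
                                            (refs + shift) %% L, L)))
    expect_equal(d1, d0)
  }
})

test_that("drop mode equals circular mode when references span the chromosome", {
  set.seed(24)
  L <- 10000
  refs <- c(0, sort(sample(1:(L - 2), 12)), L - 1)
  q <- sample(1:(L - 2), 50)   # interior only
  expect_equal(sort(as.numeric(relativeDistances(q, refs, L, "drop"))),
               sort(as.numeric(relativeDistances(q, refs, L, "circular"))))
})

test_that("KS uniformity test has the expected degenerate statistics", {
  expect_equal(ksUniformTest(rep(0, 20))$statistic, 1)
  expect_equal(ksUniformTest(rep(0.25, 50))$statistic, 0.5)
  expect_error(ksUniformTest(c(0.1, 0.7)), "outside")
  expect_error(ksUniformTest(numeric(0)), "empty")
})

test_that("ECDF area matches its closed-form limits and the 4S identity", {
  expect_equal(ecdfArea(rep(0, 7)), 0.25)
  expect_equal(ecdfArea(rep(0.5, 7)), -0.25)
  n <- 1000
  grid <- (seq_len(n) - 0.5) / (2 * n)
  expect_lt(abs(ecdfArea(grid)), 1e-3)

  set.seed(25)
  for (i in 1:100) {
    d <- runif(sample(1:500, 1), 0, 0.5)
    expect_equal(4 * ecdfArea(d), 1 - 4 * mean(d), tolerance = 1e-9)
    expect_equal(correlationMeasure(d), 4 * ecdfArea(d), tolerance = 1e-9)
  }
})

test_that("area permutation p behaves at the statistic's boundaries", {
  expect_equal(areaPermutationTest(0, 10, nPerm = 200, seed = 1), 1)
  # |S| = 1/4 is unattainable for continuous uniform draws
  expect_equal(areaPermutationTest(0.25, 5, nPerm = 200, seed = 1), 1 / 201)
  expect_error(areaPermutationTest(0.1, 10, nPerm = 50), "nPerm")
  p1 <- areaPermutationTest(0.05, 100, nPerm = 300, seed = 42)
  p2 <- areaPermutationTest(0.05, 100, nPerm = 300, seed = 42)
  expect_identical(p1, p2)
})

test_that("correlation measure hits its stated limits", {
  expect_equal(correlationMeasure(rep(0, 10)), 1)
  expect_equal(correlationMeasure(rep(0.5, 10)), -1)
})

test_that("the GRanges-level wrapper pools chromosomes and calls direction", {
  sim <- simulateFeatureSets("coincident", nQuery = 120, seed = 31)
  res <- relativeDistanceTest(sim$query, sim$reference, nPerm = 200, seed = 1)
  expect_s4_class(res, "RelativeDistanceResult")
  expect_equal(res@correlation, 1)
  expect_identical(res@direction, "closer")
  expect_identical(res@scope, "genome")
  expect_identical(res@nQuery, 120L)
  expect_equal(pValue(res), min(res@ksP, res@areaP))

  # a reference-free chromosome is skipped, not fatal
  si <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(1000L, 1000L))
  q <- GenomicRanges::GRanges(c("chrA", "chrB"),
                              IRanges::IRanges(c(101, 101), width = 1),
                              seqinfo = si)
  r <- GenomicRanges::GRanges("chrA", IRanges::IRanges(c(51, 151), width = 1),
                              seqinfo = si)
  res <- relativeDistanceTest(q, r, nPerm = 200, seed = 1)
  expect_identical(res@nQuery, 1L)
  expect_warning(relativeDistanceTest(q[0], r, nPerm = 200), "no chromosome")
})
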