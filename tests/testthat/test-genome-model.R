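test_that("chromosome-sizes files parse with order kept and errors located", {
  tf <- withr::local_tempfile()
  writeLines(c("chrB\t500", "chrA\t1000"), tf)
  si <- readChromSizes(tf)
  expect_identical(GenomeInfoDb::seqnames(si), c("chrB", "chrA"))
  expect_identical(unname(GenomeInfoDb::seqlengths(si)), c(500L, 1000L))

  writeLines(c("chrA\t1000", "chrA\t900"), tf)
  expect_error(readChromSizes(tf), "duplicate.*line 2")
  writeLines(c("chrA\t1000", "chrB\t0"), tf)
  expect_error(readChromSizes(tf), "line 2.*positive")
  writeLines(character(0), tf)
  expect_length(GenomeInfoDb::seqnames(readChromSizes(tf)), 0)
})

test_that("BED and GFF records convert to the internal convention", {
  si <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(1000L, 500L))
  tf <- withr::local_tempfile(fileext = ".bed")

  writeLines(c("track name=x", "chrA\t10\t20\tfeat1\t0\t+", "chrB\t0\t1"), tf)
  fs <- readFeatures(tf, "bed", si)
  expect_identical(GenomicRanges::start(fs), c(11L, 1L))
  expect_identical(GenomicRanges::end(fs), c(20L, 1L))

  # GFF is 1-based closed: start=11,end=20 is the same interval as BED 10..20
  tg <- withr::local_tempfile(fileext = ".gff")
  writeLines("chrA\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1", tg)
  fg <- readFeatures(tg, "gff", si)
  expect_identical(GenomicRanges::start(fg), 11L)
  expect_identical(GenomicRanges::end(fg), 20L)

  writeLines("chrA\t20\t10", tf)
  expect_error(readFeatures(tf, "bed", si), "record 1")
  writeLines(c("chrA\t10\t20", "chrA\t990\t1100"), tf)
  expect_error(readFeatures(tf, "bed", si), "record 2.*exceeds")
  writeLines(c("chrA\t10\t20", "chrZ\t1\t2"), tf)
  expect_error(readFeatures(tf, "bed", si), "record 2.*unknown chromosome")
  expect_message(fs <- readFeatures(tf, "bed", si, skipUnknown = TRUE),
                 "1 record")
  expect_length(fs, 1)
})

test_that("gzip-compressed inputs are accepted", {
  si <- GenomeInfoDb::Seqinfo("chrA", 1000L)
  tf <- withr::local_tempfile(fileext = ".bed.gz")
  con <- gzfile(tf, "w")
  writeLines("chrA\t10\t20", con)
  close(con)
  fs <- readFeatures(tf, "bed", si)
  expect_identical(GenomicRanges::start(fs), 11L)
})

test_that("the feature reader agrees with rtracklayer on plain BED", {
  skip_if_not_installed("rtracklayer")
  si <- GenomeInfoDb::Seqinfo("chrA", 100000L)
  tf <- withr::local_tempfile(fileext = ".bed")
  set.seed(11)
  s <- sort(sample.int(99000, 50)) - 1
  writeLines(sprintf("chrA\t%d\t%d", s, s + sample.int(500, 50, TRUE)), tf)
  mine <- readFeatures(tf, "bed", si)
  theirs <- rtracklayer::import(tf, format = "bed")
  expect_identical(GenomicRanges::start(mine), GenomicRanges::start(theirs))
  expect_identical(GenomicRanges::end(mine), GenomicRanges::end(theirs))
})

test_that("midpoint reduction follows the round-down rule and keeps order", {
  # BED [10,20) -> covered-base midpoint 14 (0-based), i.e. 15 in 1-based
  expect_identical(GenomicRanges::start(featureMidpoints(gr1(11, 20))), 15L)
  expect_identical(GenomicRanges::start(featureMidpoints(gr1(11, 11))), 11L)
  # BED [0,2) -> base 0
  expect_identical(GenomicRanges::start(featureMidpoints(gr1(1, 2))), 1L)

  set.seed(5)
  s <- sort(sample.int(900, 40))
  gr <- gr1(s, s + sample.int(50, 40, replace = TRUE))
  mids <- featureMidpoints(gr)
  expect_false(is.unsorted(GenomicRanges::start(mids)))
  expect_true(all(GenomicRanges::width(mids) == 1L))
})

test_that("normalization merges overlap and abutment and is idempotent", {
  m <- normalizeFeatures(gr1(c(1, 6), c(10, 15)))
  expect_identical(GenomicRanges::start(m), 1L)
  expect_identical(GenomicRanges::end(m), 15L)
  m <- normalizeFeatures(gr1(c(1, 11), c(10, 20)))
  expect_length(m, 1)
  m0 <- gr1(c(1, 21), c(10, 30))
  expect_equal(GenomicRanges::ranges(normalizeFeatures(m0)),
               GenomicRanges::ranges(m0))

  set.seed(6)
  for (i in 1:20) {
    s <- sample.int(950, 15)
    gr <- gr1(s, pmin(1000, s + sample.int(100, 15, replace = TRUE)))
    nm <- normalizeFeatures(gr)
    expect_equal(normalizeFeatures(nm), nm)
    expect_equal(sum(GenomicRanges::width(nm)),
                 sum(oracleMembership(GenomicRanges::start(gr) - 1,
                                      GenomicRanges::end(gr), 1000)))
  }
})

test_that("coverage fractions match the definition", {
  expect_equal(coverageFraction(gr1(1, 500)), 0.5)
  expect_equal(coverageFraction(gr1(1, 1000)), 1.0)
  si <- GenomeInfoDb::Seqinfo("chrA", 1000L)
  expect_equal(coverageFraction(GenomicRanges::GRanges(seqinfo = si)), 0)
  expect_error(coverageFraction(gr1(1, 10), chrom = "chrZ"), "unknown")
})

test_that("mask restriction clips, shifts, and round-trips through BED", {
  fs <- gr1(101, 200)                       # BED [100,200)
  mask <- gr1(151, 300)                     # BED [150,300)
  rs <- restrictToMask(fs, mask)
  expect_identical(as.character(GenomicRanges::seqnames(rs)), "chrA:150-300")
  expect_identical(GenomicRanges::start(rs), 1L)
  expect_identical(GenomicRanges::end(rs), 50L)
  expect_identical(unname(GenomeInfoDb::seqlengths(rs)), 150L)

  expect_length(restrictToMask(gr1(1, 50), gr1(101, 200)), 0)
  full <- restrictToMask(mask, mask)
  expect_equal(coverageFraction(full), 1)
  expect_error(restrictToMask(fs, fs[0]), "empty mask")

  tf <- withr::local_tempfile(fileext = ".bed")
  writeFeatures(rs, tf)
  back <- readFeatures(tf, "bed", GenomeInfoDb::seqinfo(rs))
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(rs))
})

test_that("restricted coverage equals brute-force coverage of fs within mask", {
  set.seed(7)
  L <- 10000
  for (i in 1:10) {
    f <- randomIntervalSet(L)
    m <- randomIntervalSet(L, maxN = 5, maxLen = 2000)
    fs <- gr1(f$start + 1, f$end, L)
    mask <- gr1(m$start + 1, m$end, L)
    rs <- restrictToMask(fs, mask)
    fmem <- oracleMembership(f$start, f$end, L)
    mmem <- oracleMembership(m$start, m$end, L)
    expect_equal(sum(GenomicRanges::width(normalizeFeatures(rs))),
                 sum(fmem & mmem))
    expect_equal(coverageFraction(rs), sum(fmem & mmem) / sum(mmem))
  }
})
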