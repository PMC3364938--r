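## End-to-end runs over the configuration surface.

writeFixtureRun <- function(dir, relationship = "coincident", nQuery = 60,
                            nReference = 40, seed = 71, ...) {
  sim <- simulateFeatureSets(relationship, nQuery = nQuery,
                             nReference = nReference, seed = seed)
  writeSimulation(sim, dir)
  sim
}

makeConfig <- function(dir, ...) {
  runConfig(query = file.path(dir, "query.bed"),
            reference = file.path(dir, "reference.bed"),
            genome = file.path(dir, "genome.sizes"),
            nPerm = 100L, seed = 5L, outDir = dir, ...)
}

test_that("INI configuration files round-trip into RunConfig", {
  tf <- withr::local_tempfile(fileext = ".config")
  writeLines(c("[data]", "query = q.bed", "reference = r.gff",
               "reference_format = gff", "genome = g.sizes",
               "[tests]", "tests = relative, jaccard", "n_perm = 250",
               "seed = 7", "[options]", "edge_mode = drop",
               "both_directions = false", "alpha = 0.01",
               "# a comment", "out = results"), tf)
  cfg <- readRunConfig(tf)
  expect_identical(cfg@referenceFormat, "gff")
  expect_identical(cfg@tests, c("relative", "jaccard"))
  expect_identical(cfg@nPerm, 250L)
  expect_identical(cfg@seed, 7L)
  expect_identical(cfg@edgeMode, "drop")
  expect_false(cfg@bothDirections)
  expect_equal(cfg@alpha, 0.01)
  expect_null(cfg@mask)

  writeLines(c("query = q", "reference = r", "genome = g", "n_prem = 10"), tf)
  expect_error(readRunConfig(tf), "unknown configuration key")
  writeLines(c("query = q", "genome = g"), tf)
  expect_error(readRunConfig(tf), "missing 'reference'")
  expect_error(runConfig("q", "r", "g", nPerm = 50), "nPerm")
  expect_error(runConfig("q", "r", "g", tests = "banana"), "unknown tests")
})

test_that("a coincident dataset is symmetric: correlation 1 in both directions", {
  dir <- withr::local_tempdir()
  writeFixtureRun(dir)
  rep <- runCorrelation(makeConfig(dir))
  for (d in c("query_vs_reference", "reference_vs_query")) {
    res <- getResult(rep, "relative", "genome", d)
    expect_equal(res@correlation, 1)
    expect_identical(res@direction, "closer")
  }
  # Jaccard statistic is the only direction-symmetric quantity
  expect_equal(getResult(rep, "jaccard", "genome", "query_vs_reference")@jaccard,
               getResult(rep, "jaccard", "genome", "reference_vs_query")@jaccard)
})

test_that("an asymmetric dataset is significant only sparse -> dense", {
  sim <- simulateFeatureSets("asymmetric", seed = 72)
  rep <- correlateFeatures(sim$query, sim$reference, tests = "relative",
                           nPerm = 200, seed = 3)
  fwd <- getResult(rep, "relative", "genome", "query_vs_reference")
  rev <- getResult(rep, "relative", "genome", "reference_vs_query")
  expect_lt(fwd@ksP, 1e-6)
  expect_lt(fwd@areaP, 0.01)
  expect_identical(fwd@direction, "closer")
  expect_gt(rev@ksP, 0.05)
})

test_that("test selection filters the report and leaves substreams intact", {
  dir <- withr::local_tempdir()
  writeFixtureRun(dir, "independent")
  full <- runCorrelation(makeConfig(dir))
  jacOnly <- runCorrelation(makeConfig(dir, tests = "jaccard"))
  tab <- reportTable(jacOnly)
  expect_true(all(tab$test == "jaccard"))
  # substream seeding: dropping other tests must not change jaccard numbers
  expect_equal(getResult(jacOnly, "jaccard")@p, getResult(full, "jaccard")@p)
  expect_equal(getResult(jacOnly, "jaccard")@jaccard,
               getResult(full, "jaccard")@jaccard)
})

test_that("identical configurations reproduce the report bit-for-bit", {
  dir <- withr::local_tempdir()
  writeFixtureRun(dir, "independent")
  r1 <- runCorrelation(makeConfig(dir))
  r2 <- runCorrelation(makeConfig(dir))
  d1 <- file.path(dir, "out1"); d2 <- file.path(dir, "out2")
  writeReport(r1, d1); writeReport(r2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "report.tsv")),
                   readLines(file.path(d2, "report.tsv")))
})

test_that("removing a chromosome leaves other per-chromosome results unchanged", {
  sim <- simulateFeatureSets("independent", nQuery = 80, nReference = 60,
                             seed = 73)
  full <- correlateFeatures(sim$query, sim$reference, nPerm = 100, seed = 9)
  keep <- GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(sim$query)) != "chr4"
  prune <- function(gr) {
    gr <- gr[GenomicRanges::seqnames(gr) != "chr4"]
    GenomeInfoDb::seqlevels(gr) <- setdiff(GenomeInfoDb::seqlevels(gr), "chr4")
    gr
  }
  part <- correlateFeatures(prune(sim$query), prune(sim$reference),
                            nPerm = 100, seed = 9)
  for (test in c("relative", "absolute", "projection", "jaccard"))
    expect_equal(getResult(part, test, "chr2"), getResult(full, test, "chr2"))
})

test_that("scopes that cannot be tested are reported as skipped", {
  si <- GenomeInfoDb::Seqinfo(c("chrA", "chrB"), c(10000L, 10000L))
  q <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(sort(sample.int(9000, 20)), width = 1), seqinfo = si)
  r <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(sort(sample.int(9000, 20)), width = 100), seqinfo = si)
  rep <- correlateFeatures(q, r, nPerm = 100, seed = 1,
                           bothDirections = FALSE)
  expect_true(all(c("chrA", "genome") %in%
                  names(rep@results$query_vs_reference)))
  expect_false("chrB" %in% names(rep@results$query_vs_reference))
  expect_true(all(rep@skipped$scope == "chrB"))
  tab <- reportTable(rep)
  expect_false("chrB" %in% tab$scope)
  # every requested test appears for every non-skipped scope
  for (sc in names(rep@results$query_vs_reference))
    expect_setequal(names(rep@results$query_vs_reference[[sc]]),
                    c("relative", "absolute", "projection", "jaccard"))

  dir <- withr::local_tempdir()
  writeReport(rep, dir)
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(length(j$skipped) >= 1)
})

test_that("JSON serialization round-trips to an equal report", {
  sim <- simulateFeatureSets("independent", nQuery = 40, nReference = 30,
                             seed = 74)
  rep <- correlateFeatures(sim$query, sim$reference, nPerm = 100, seed = 2)
  dir <- withr::local_tempdir()
  writeReport(rep, dir, "json")
  back <- readReport(file.path(dir, "report.json"))
  for (d in names(rep@results))
    for (sc in names(rep@results[[d]]))
      for (te in names(rep@results[[d]][[sc]]))
        expect_equal(back@results[[d]][[sc]][[te]],
                     rep@results[[d]][[sc]][[te]])
  expect_equal(back@skipped, rep@skipped)
})

test_that("an empty-query run yields a header-only TSV, not an error", {
  si <- GenomeInfoDb::Seqinfo("chrA", 1000L)
  rep <- correlateFeatures(GenomicRanges::GRanges(seqinfo = si),
                           GenomicRanges::GRanges(seqinfo = si),
                           nPerm = 100, seed = 1)
  dir <- withr::local_tempdir()
  writeReport(rep, dir)
  expect_identical(length(readLines(file.path(dir, "report.tsv"))), 1L)
})

test_that("mask restriction feeds the run and contradictory masks error early", {
  dir <- withr::local_tempdir()
  sim <- writeFixtureRun(dir, "independent", nQuery = 200, nReference = 100)
  # mask = first half of chr1
  writeLines("chr1\t0\t500000", file.path(dir, "mask.bed"))
  cfg <- makeConfig(dir, mask = file.path(dir, "mask.bed"),
                    tests = "projection", bothDirections = FALSE)
  rep <- runCorrelation(cfg)
  scopes <- names(rep@results$query_vs_reference)
  expect_true(all(grepl("^chr1:0-500000$|^genome$", scopes)))

  writeLines(character(0), file.path(dir, "mask.bed"))
  expect_error(runCorrelation(cfg), "mask")
})

test_that("plotting writes a PDF and failures stay non-fatal", {
  sim <- simulateFeatureSets("attraction", nQuery = 80, nReference = 60,
                             seed = 75)
  rep <- correlateFeatures(sim$query, sim$reference,
                           tests = c("relative", "absolute"),
                           nPerm = 100, seed = 4)
  pdf <- withr::local_tempfile(fileext = ".pdf")
  plotReport(rep, pdf)
  expect_true(file.exists(pdf) && file.size(pdf) > 1000)
  expect_warning(plotReport(rep, file.path(tempdir(), "no/such/dir/x.pdf")),
                 "plotting failed")
})
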