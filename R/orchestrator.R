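## Orchestrator: configuration, execution of all requested tests per
## direction and scope, and the nested report.
##
## Seed discipline: each (direction, scope, test) combination receives its
## own substream seed derived from the master seed by a stable string
## hash, so removing one test or chromosome never changes another's
## numbers and re-running a configuration reproduces the report
## bit-for-bit.

#' Build a run configuration in code
#'
#' See \linkS4class{RunConfig} for the meaning of every field;
#' [readRunConfig()] builds the same object from an INI-style file.
#'
#' @param query,reference input paths.
#' @param genome chromosome-sizes path.
#' @param queryFormat,referenceFormat \code{"bed"} or \code{"gff"}.
#' @param mask optional BED path, or NULL.
#' @param tests tests to run.
#' @param nPerm permutations per test.
#' @param seed master seed.
#' @param edgeMode,gapScaling,jaccardMode convention switches.
#' @param bothDirections also run with roles swapped.
#' @param alpha reporting significance level.
#' @param outDir output directory.
#' @param skipUnknown tolerate records on unknown chromosomes.
#' @return a validated \linkS4class{RunConfig}.
#' @export
runConfig <- function(query, reference, genome,
                      queryFormat = "bed", referenceFormat = "bed",
                      mask = NULL,
                      tests = c("relative", "absolute", "projection",
                                "jaccard"),
                      nPerm = 1000L, seed = 0L,
                      edgeMode = "circular", gapScaling = "n+1",
                      jaccardMode = "rotation", bothDirections = TRUE,
                      alpha = 0.05, outDir = ".", skipUnknown = FALSE) {
  new("RunConfig", query = query, queryFormat = queryFormat,
      reference = reference, referenceFormat = referenceFormat,
      genome = genome, mask = mask, tests = tests,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      edgeMode = edgeMode, gapScaling = gapScaling,
      jaccardMode = jaccardMode, bothDirections = bothDirections,
      alpha = alpha, outDir = outDir, skipUnknown = skipUnknown)
}

#' Read a run configuration from an INI-style file
#'
#' Flat \code{key = value} lines under \code{[data]}, \code{[tests]} and
#' \code{[options]} section headers (sections are cosmetic; keys are
#' global).  Recognized keys: query, query_format, reference,
#' reference_format, genome, mask, tests (comma-separated), n_perm, seed,
#' edge_mode, gap_scaling, jaccard_mode, both_directions, alpha, out,
#' skip_unknown.  Unknown keys are an error, so typos do not silently
#' fall back to defaults.
#'
#' @param path configuration file.
#' @return a validated \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kvs <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kvs) != 3L)
  if (length(bad))
    stop("malformed configuration line: '", lines[bad[1L]], "'")
  keys <- trimws(vapply(kvs, `[[`, character(1), 2L))
  vals <- trimws(vapply(kvs, `[[`, character(1), 3L))
  known <- c("query", "query_format", "reference", "reference_format",
             "genome", "mask", "tests", "n_perm", "seed", "edge_mode",
             "gap_scaling", "jaccard_mode", "both_directions", "alpha",
             "out", "skip_unknown")
  if (length(unk <- setdiff(keys, known)))
    stop("unknown configuration key(s): ", paste(unk, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate configuration key: ", keys[anyDuplicated(keys)])
  get <- function(k, default) if (k %in% keys) vals[keys == k] else default
  for (req in c("query", "reference", "genome"))
    if (!req %in% keys) stop("configuration is missing '", req, "'")
  runConfig(
    query = get("query", NA), queryFormat = get("query_format", "bed"),
    reference = get("reference", NA),
    referenceFormat = get("reference_format", "bed"),
    genome = get("genome", NA),
    mask = if ("mask" %in% keys) get("mask", NULL) else NULL,
    tests = trimws(strsplit(get("tests",
      "relative,absolute,projection,jaccard"), ",")[[1L]]),
    nPerm = as.integer(get("n_perm", "1000")),
    seed = as.integer(get("seed", "0")),
    edgeMode = get("edge_mode", "circular"),
    gapScaling = get("gap_scaling", "n+1"),
    jaccardMode = get("jaccard_mode", "rotation"),
    bothDirections = tolower(get("both_directions", "true")) %in%
      c("true", "yes", "1"),
    alpha = as.numeric(get("alpha", "0.05")),
    outDir = get("out", "."),
    skipUnknown = tolower(get("skip_unknown", "false")) %in%
      c("true", "yes", "1"))
}

#' Run all requested association tests on in-memory feature sets
#'
#' The engine behind [runCorrelation()].  For each direction (query vs
#' reference and, when \code{bothDirections}, the swap) and each scope
#' (every chromosome with data, plus the pooled \code{"genome"}), runs the
#' requested tests.  Chromosomes that cannot support a test (for example,
#' too few reference points) are skipped with a recorded reason.
#'
#' @param query,reference GRanges sharing a Seqinfo.
#' @param tests subset of relative/absolute/projection/jaccard.
#' @param nPerm permutations per test.
#' @param seed master seed (substreams derived per direction, scope, test).
#' @param edgeMode,gapScaling,jaccardMode convention switches.
#' @param bothDirections also run with the roles swapped.
#' @param alpha reporting significance level for direction calls.
#' @param configEcho optional list stored in the report metadata.
#' @return an \linkS4class{AssociationReport}.
#' @export
correlateFeatures <- function(query, reference,
                              tests = c("relative", "absolute",
                                        "projection", "jaccard"),
                              nPerm = 1000L, seed = 0L,
                              edgeMode = "circular", gapScaling = "n+1",
                              jaccardMode = "rotation",
                              bothDirections = TRUE, alpha = 0.05,
                              configEcho = list()) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(identical(GenomeInfoDb::seqlevels(query),
                      GenomeInfoDb::seqlevels(reference)))
  dirs <- c("query_vs_reference",
            if (bothDirections) "reference_vs_query")
  results <- list(); distances <- list()
  skipped <- data.frame(direction = character(0), scope = character(0),
                        test = character(0), reason = character(0))
  for (dirName in dirs) {
    q <- if (dirName == "query_vs_reference") query else reference
    r <- if (dirName == "query_vs_reference") reference else query
    scopes <- c(GenomeInfoDb::seqlevels(q), "genome")
    results[[dirName]] <- list()
    distances[[dirName]] <- list()
    for (scope in scopes) {
      ch <- if (scope == "genome") NULL else scope
      res <- list()
      for (test in tests) {
        sseed <- substreamSeed(seed, dirName, scope, test)
        notes <- character(0)
        out <- withCallingHandlers(
          tryCatch(
            switch(test,
              relative = relativeDistanceTest(q, r, chrom = ch,
                nPerm = nPerm, seed = sseed, edgeMode = edgeMode,
                alpha = alpha),
              absolute = absoluteDistanceTest(q, r, chrom = ch,
                nPerm = nPerm, seed = sseed, gapScaling = gapScaling),
              projection = projectionTest(q, r, chrom = ch),
              jaccard = jaccardTest(q, r, chrom = ch, nPerm = nPerm,
                seed = sseed, mode = jaccardMode)),
            error = function(e) {
              notes <<- c(notes, conditionMessage(e))
              NULL
            }),
          warning = function(w) {
            notes <<- c(notes, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        if (!is.null(out)) {
          res[[test]] <- out
        } else {
          skipped[nrow(skipped) + 1L, ] <- list(
            dirName, scope, test,
            if (length(notes)) paste(notes, collapse = "; ") else "skipped")
        }
      }
      if (length(res)) results[[dirName]][[scope]] <- res
      distances[[dirName]][[scope]] <- retainDistances(q, r, ch, tests,
                                                       edgeMode, gapScaling)
    }
  }
  new("AssociationReport", results = results, skipped = skipped,
      meta = list(
        package = "GenomicAssociations",
        version = as.character(utils::packageVersion("GenomicAssociations")),
        seed = seed, nPerm = nPerm, tests = tests,
        edgeMode = edgeMode, gapScaling = gapScaling,
        jaccardMode = jaccardMode, alpha = alpha,
        bothDirections = bothDirections, config = configEcho),
      distances = distances)
}

## Distance vectors kept for plotting (quietly NULL where undefined).
retainDistances <- function(q, r, ch, tests, edgeMode, gapScaling) {
  out <- list()
  if ("relative" %in% tests)
    out$relative <- tryCatch(
      suppressWarnings(as.numeric(
        pooledRelativeDistances(q, r, ch, edgeMode))),
      error = function(e) NULL)
  if ("absolute" %in% tests) {
    qp <- midpointPositions(q); rp <- lapply(midpointPositions(r), unique)
    lens <- GenomeInfoDb::seqlengths(q)
    chroms <- if (is.null(ch)) names(qp) else ch
    d <- lapply(chroms, function(cc) {
      if (length(qp[[cc]]) == 0L || length(rp[[cc]]) == 0L) return(NULL)
      suppressWarnings(
        scaledMinDistances(qp[[cc]], rp[[cc]], lens[[cc]], gapScaling))
    })
    out$absolute <- as.numeric(unlist(d))
  }
  out
}

#' Run a full configured analysis
#'
#' Loads the genome and both feature sets, applies the mask restriction if
#' configured, and executes every requested test in the configured
#' direction(s), per chromosome and genome-wide.
#'
#' @param config a \linkS4class{RunConfig} from [runConfig()] or
#'   [readRunConfig()].
#' @return an \linkS4class{AssociationReport}.
#' @export
runCorrelation <- function(config) {
  stopifnot(is(config, "RunConfig"))
  methods::validObject(config)
  genome <- readChromSizes(config@genome)
  if (length(GenomeInfoDb::seqnames(genome)) == 0L)
    stop("empty genome: no chromosomes to test")
  query <- readFeatures(config@query, config@queryFormat, genome,
                        config@skipUnknown)
  reference <- readFeatures(config@reference, config@referenceFormat,
                            genome, config@skipUnknown)
  if (!is.null(config@mask)) {
    mask <- readFeatures(config@mask, "bed", genome, config@skipUnknown)
    if (length(mask) == 0L) stop("mask file contains no usable intervals")
    query <- restrictToMask(query, mask)
    reference <- restrictToMask(reference, mask)
  }
  correlateFeatures(query, reference,
                    tests = config@tests, nPerm = config@nPerm,
                    seed = config@seed, edgeMode = config@edgeMode,
                    gapScaling = config@gapScaling,
                    jaccardMode = config@jaccardMode,
                    bothDirections = config@bothDirections,
                    alpha = config@alpha,
                    configEcho = configAsList(config))
}

configAsList <- function(config) {
  list(query = config@query, query_format = config@queryFormat,
       reference = config@reference,
       reference_format = config@referenceFormat,
       genome = config@genome, mask = config@mask,
       tests = config@tests, n_perm = config@nPerm, seed = config@seed,
       edge_mode = config@edgeMode, gap_scaling = config@gapScaling,
       jaccard_mode = config@jaccardMode,
       both_directions = config@bothDirections, alpha = config@alpha,
       out = config@outDir, skip_unknown = config@skipUnknown)
}
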