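## Report serialization: flat TSV and full-precision nested JSON.

resultToList <- function(x) {
  if (is(x, "RelativeDistanceResult"))
    list(test = "relative", n_query = x@nQuery, n_dropped = x@nDropped,
         ks_statistic = x@ksStatistic, ks_p = x@ksP,
         area_S = x@areaS, area_p = x@areaP,
         correlation = x@correlation, direction = x@direction)
  else if (is(x, "AbsoluteDistanceResult"))
    list(test = "absolute", n_query = x@nQuery,
         mean_scaled_distance = x@meanScaledDistance, p = x@p,
         perm_mean = x@permMean, n_perm = x@nPerm, direction = x@direction)
  else if (is(x, "ProjectionResult"))
    list(test = "projection", n_query = x@nQuery, n_hits = x@nHits,
         coverage_p = x@coverageP, p = x@p, direction = x@direction,
         low_information = x@lowInformation)
  else if (is(x, "JaccardResult"))
    list(test = "jaccard", jaccard = x@jaccard, p = x@p,
         n_perm = x@nPerm, direction = x@direction)
  else stop("unknown result class: ", class(x))
}

resultRow <- function(x, dirName, scope, test) {
  common <- data.frame(direction = dirName, scope = scope, test = test,
                       stringsAsFactors = FALSE)
  if (test == "relative")
    cbind(common, data.frame(
      n = x@nQuery, statistic = x@correlation, p = x@areaP,
      call = x@direction, secondary_statistic = x@ksStatistic,
      secondary_p = x@ksP))
  else if (test == "absolute")
    cbind(common, data.frame(
      n = x@nQuery, statistic = x@meanScaledDistance, p = x@p,
      call = x@direction, secondary_statistic = x@permMean,
      secondary_p = NA_real_))
  else if (test == "projection")
    cbind(common, data.frame(
      n = x@nQuery, statistic = x@nHits, p = x@p, call = x@direction,
      secondary_statistic = x@coverageP, secondary_p = NA_real_))
  else
    cbind(common, data.frame(
      n = x@nPerm, statistic = x@jaccard, p = x@p, call = x@direction,
      secondary_statistic = NA_real_, secondary_p = NA_real_))
}

#' Flatten a report into one row per direction, scope and test
#'
#' For the relative-distance test, \code{statistic} is the correlation
#' measure and \code{p} the ECDF-area permutation p-value, with the KS
#' statistic and p-value in the secondary columns; for the absolute test
#' the secondary statistic is the permutation mean; for the projection
#' test \code{statistic} is the hit count and the secondary statistic the
#' coverage fraction.
#'
#' @param report an \linkS4class{AssociationReport}.
#' @return a data.frame (zero rows when nothing was testable).
#' @export
reportTable <- function(report) {
  stopifnot(is(report, "AssociationReport"))
  rows <- list()
  for (dirName in names(report@results))
    for (scope in names(report@results[[dirName]]))
      for (test in names(report@results[[dirName]][[scope]]))
        rows[[length(rows) + 1L]] <- resultRow(
          report@results[[dirName]][[scope]][[test]], dirName, scope, test)
  if (length(rows) == 0L)
    return(data.frame(direction = character(0), scope = character(0),
                      test = character(0), n = integer(0),
                      statistic = numeric(0), p = numeric(0),
                      call = character(0),
                      secondary_statistic = numeric(0),
                      secondary_p = numeric(0)))
  do.call(rbind, rows)
}

#' Write a report to disk
#'
#' \code{report.json} holds the full nested structure (all floats at full
#' precision, skipped scopes listed with reasons, configuration echo);
#' \code{report.tsv} holds the flat [reportTable()].  Output is
#' byte-stable for identical reports.
#'
#' @param report an \linkS4class{AssociationReport}.
#' @param dir output directory (created if needed).
#' @param formats subset of \code{c("json", "tsv")}.
#' @return invisible character vector of the files written.
#' @export
writeReport <- function(report, dir, formats = c("json", "tsv")) {
  stopifnot(is(report, "AssociationReport"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    written <- c(written, path)
  }
  if ("tsv" %in% formats) {
    path <- file.path(dir, "report.tsv")
    utils::write.table(reportTable(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}

reportAsList <- function(report) {
  res <- lapply(report@results, function(byScope)
    lapply(byScope, function(byTest) lapply(byTest, resultToList)))
  list(meta = report@meta,
       results = res,
       skipped = if (nrow(report@skipped)) report@skipped else list())
}

#' Rebuild an AssociationReport from its JSON serialization
#'
#' Inverse of the JSON half of [writeReport()] for the test results and
#' skip table (retained distance vectors are not serialized).  Used to
#' verify the serialization round trip.
#'
#' @param path path to a \code{report.json}.
#' @return an \linkS4class{AssociationReport} without distances.
#' @export
readReport <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  results <- lapply(j$results, function(byScope) {
    out <- lapply(names(byScope), function(scope)
      lapply(byScope[[scope]], listToResult, scope = scope))
    names(out) <- names(byScope)
    out
  })
  skipped <- if (length(j$skipped))
    do.call(rbind, lapply(j$skipped, function(s)
      data.frame(direction = s$direction, scope = s$scope, test = s$test,
                 reason = s$reason, stringsAsFactors = FALSE)))
  else data.frame(direction = character(0), scope = character(0),
                  test = character(0), reason = character(0))
  new("AssociationReport", results = results, skipped = skipped,
      meta = lapply(j$meta, simplifyMeta), distances = list())
}

simplifyMeta <- function(x)
  if (is.list(x) && all(lengths(x) == 1L) && is.null(names(x)))
    unlist(x) else x

listToResult <- function(l, scope) {
  switch(l$test,
    relative = new("RelativeDistanceResult",
      nQuery = as.integer(l$n_query), nDropped = as.integer(l$n_dropped),
      ksStatistic = l$ks_statistic, ksP = l$ks_p,
      areaS = l$area_S, areaP = l$area_p, correlation = l$correlation,
      direction = l$direction, scope = scope),
    absolute = new("AbsoluteDistanceResult",
      nQuery = as.integer(l$n_query),
      meanScaledDistance = l$mean_scaled_distance, p = l$p,
      permMean = l$perm_mean, nPerm = as.integer(l$n_perm),
      direction = l$direction, scope = scope),
    projection = new("ProjectionResult",
      nQuery = as.integer(l$n_query), nHits = as.integer(l$n_hits),
      coverageP = l$coverage_p, p = l$p, direction = l$direction,
      lowInformation = isTRUE(l$low_information), scope = scope),
    jaccard = new("JaccardResult",
      jaccard = l$jaccard, p = l$p, nPerm = as.integer(l$n_perm),
      direction = l$direction, scope = scope),
    stop("unknown test in JSON: ", l$test))
}
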