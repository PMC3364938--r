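## Summary graphics: ECDF of relative distances against the uniform-null
## straight line, and a histogram of scaled absolute distances with the
## permutation-mean reference line.  One page per scope (each chromosome
## plus the genome summary), base graphics, written to PDF.

plotScope <- function(report, dirName, scope) {
  d <- report@distances[[dirName]][[scope]]
  res <- report@results[[dirName]][[scope]]
  graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 3, 1))
  if (!is.null(d$relative) && length(d$relative)) {
    x <- sort(d$relative)
    graphics::plot(c(0, x, 0.5), c(0, seq_along(x) / length(x), 1),
                   type = "s", xlim = c(0, 0.5), ylim = c(0, 1),
                   xlab = "relative distance d", ylab = "ECDF",
                   main = paste0(dirName, "\n", scope), cex.main = 0.9)
    graphics::abline(0, 2, lty = 2, col = "grey40")
    if (!is.null(res$relative))
      graphics::legend("bottomright", bty = "n", cex = 0.8, legend = c(
        sprintf("corr = %.3f", res$relative@correlation),
        sprintf("KS p = %.3g", res$relative@ksP),
        sprintf("area p = %.3g", res$relative@areaP)))
  } else {
    graphics::plot.new()
    graphics::title(main = paste0(dirName, "\n", scope,
                                  "\n(no relative distances)"),
                    cex.main = 0.9)
  }
  if (!is.null(d$absolute) && length(d$absolute)) {
    graphics::hist(d$absolute, breaks = 30, col = "grey80",
                   border = "white",
                   xlab = "scaled distance to nearest reference",
                   main = "absolute distances", cex.main = 0.9)
    if (!is.null(res$absolute)) {
      graphics::abline(v = res$absolute@permMean, lty = 2, col = "red3")
      graphics::legend("topright", bty = "n", cex = 0.8, legend = c(
        sprintf("mean = %.3f", res$absolute@meanScaledDistance),
        sprintf("null mean = %.3f", res$absolute@permMean),
        sprintf("p = %.3g", res$absolute@p)))
    }
  } else {
    graphics::plot.new()
    graphics::title(main = "(no absolute distances)", cex.main = 0.9)
  }
}

#' Plot the distance summaries of a report to PDF
#'
#' Per direction: a genome summary page followed by one page per
#' chromosome, each with the relative-distance ECDF (null line y = 2x
#' overlaid) and the scaled absolute-distance histogram (permutation mean
#' as the null reference line).  Requires a report produced with the
#' relative and/or absolute tests; plotting failures are warnings, not
#' errors (the statistics are already on disk).
#'
#' @param report an \linkS4class{AssociationReport}.
#' @param file output PDF path.
#' @return \code{file}, invisibly.
#' @export
plotReport <- function(report, file) {
  stopifnot(is(report, "AssociationReport"))
  tryCatch({
    grDevices::pdf(file, width = 9, height = 4.5)
    on.exit(grDevices::dev.off())
    for (dirName in names(report@distances)) {
      scopes <- names(report@distances[[dirName]])
      scopes <- c(intersect("genome", scopes), setdiff(scopes, "genome"))
      for (scope in scopes) plotScope(report, dirName, scope)
    }
  }, error = function(e)
    warning("plotting failed: ", conditionMessage(e)))
  invisible(file)
}
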