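## Coordinate universe, feature I/O, midpoint reduction, coverage, masking.
##
## Intervals live in GRanges (1-based closed, the Bioconductor convention);
## BED input/output is converted at the boundary.  The chromosome universe
## is a GenomeInfoDb::Seqinfo and every GRanges produced here carries it,
## so downstream tests always know chromosome lengths.

#' Read a chromosome-sizes table
#'
#' Two whitespace/tab-delimited columns: chromosome name and length in bp.
#' Input order is preserved; duplicate names and non-positive lengths are
#' errors naming the offending line.
#'
#' @param path path to the file (plain or gzip-compressed).
#' @return a [GenomeInfoDb::Seqinfo] with one entry per line.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chrA\t1000", "chrB\t500"), tf)
#' readChromSizes(tf)
#' @export
readChromSizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(GenomeInfoDb::Seqinfo(character(0), integer(0)))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("chromosome-sizes line ", bad[1L], " has fewer than 2 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(len))
    stop("chromosome-sizes line ", which(is.na(len))[1L],
         ": length is not numeric")
  if (any(len <= 0))
    stop("chromosome-sizes line ", which(len <= 0)[1L],
         ": length must be positive")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name '", nm[anyDuplicated(nm)],
         "' at line ", anyDuplicated(nm))
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a feature set from BED or GFF
#'
#' BED coordinates are 0-based half-open and converted on read; GFF
#' coordinates are 1-based closed (columns 4 and 5 used as-is).  Strand is
#' ignored throughout.  Records on chromosomes absent from \code{genome}
#' are an error unless \code{skipUnknown = TRUE}, in which case they are
#' counted, dropped, and reported via a message.
#'
#' @param path input path (plain text or gzip).
#' @param format \code{"bed"} (3+ columns, extras ignored) or \code{"gff"}
#'   (9 columns).
#' @param genome a [GenomeInfoDb::Seqinfo], e.g. from [readChromSizes()].
#' @param skipUnknown drop records on unknown chromosomes instead of
#'   erroring.
#' @return a sorted [GenomicRanges::GRanges] carrying \code{genome} as its
#'   seqinfo.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrA", 1000)
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chrA\t10\t20", tf)
#' readFeatures(tf, "bed", si)   # GRanges chrA:11-20 (1-based closed)
#' @export
readFeatures <- function(path, format = c("bed", "gff"), genome,
                         skipUnknown = FALSE) {
  format <- match.arg(format)
  stopifnot(is(genome, "Seqinfo"))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  recno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = genome))
  }
  fields <- strsplit(lines, "\t")
  ## fall back to generic whitespace when the file is not tab-delimited
  if (any(lengths(fields) < 3L))
    fields <- strsplit(trimws(lines), "[ \t]+")
  need <- if (format == "bed") 3L else 5L
  bad <- which(lengths(fields) < need)
  if (length(bad))
    stop(format, " record ", recno[bad[1L]], " has fewer than ", need,
         " columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  if (format == "bed") {
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    start1 <- s + 1   # 0-based half-open -> 1-based closed
    end1 <- e
  } else {
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
    start1 <- s
    end1 <- e
  }
  if (anyNA(start1) || anyNA(end1))
    stop(format, " record ",
         recno[which(is.na(start1) | is.na(end1))[1L]],
         ": non-numeric coordinates")
  bad <- which(end1 < start1 | start1 < 1)
  if (length(bad))
    stop(format, " record ", recno[bad[1L]],
         ": empty or negative interval after coordinate conversion")
  unknown <- !(chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(unknown)) {
    if (!skipUnknown)
      stop(format, " record ", recno[which(unknown)[1L]],
           ": unknown chromosome '", chrom[which(unknown)[1L]], "'")
    message(sum(unknown), " record(s) on unknown chromosomes skipped")
    chrom <- chrom[!unknown]; start1 <- start1[!unknown]
    end1 <- end1[!unknown]; recno <- recno[!unknown]
  }
  if (length(chrom) == 0L)
    return(GenomicRanges::GRanges(seqinfo = genome))
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  over <- which(end1 > lens)
  if (length(over))
    stop(format, " record ", recno[over[1L]],
         ": interval end ", end1[over[1L]], " exceeds length of '",
         chrom[over[1L]], "' (", lens[over[1L]], ")")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                               seqinfo = genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a feature set as 3-column BED
#'
#' Inverse of [readFeatures()] for BED: 1-based closed GRanges become
#' 0-based half-open records.  A write/read round trip is lossless.
#'
#' @param x a GRanges.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a Seqinfo as a chromosome-sizes file
#' @param genome a Seqinfo.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChromSizes <- function(genome, path) {
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(genome),
               GenomeInfoDb::seqlengths(genome)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Midpoint reduction
#'
#' Each interval is represented by the midpoint of its covered bases,
#' rounding down for even lengths (a fixed rule; the choice is irrelevant
#' to the statistics but required for reproducibility).  Duplicate
#' midpoints are retained.
#'
#' @param x a GRanges.
#' @return a width-1 GRanges, sorted.
#' @examples
#' gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(11, 20)) # BED [10,20)
#' GenomicRanges::start(featureMidpoints(gr))  # 15 (0-based base 14)
#' @export
featureMidpoints <- function(x) {
  mid <- floor((GenomicRanges::start(x) + GenomicRanges::end(x)) / 2)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(x),
                                IRanges::IRanges(mid, width = 1L),
                                seqinfo = GenomeInfoDb::seqinfo(x))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

## 0-based midpoint positions split by chromosome: named list of sorted
## numeric vectors, one per seqlevel (possibly empty).
midpointPositions <- function(x) {
  mid <- floor((GenomicRanges::start(x) + GenomicRanges::end(x)) / 2) - 1
  f <- factor(as.character(GenomicRanges::seqnames(x)),
              levels = GenomeInfoDb::seqlevels(x))
  lapply(split(mid, f), sort)
}

#' Merge overlapping and abutting intervals
#'
#' Normalization used before coverage and Jaccard computations; total
#' covered bp is invariant and the operation is idempotent.
#'
#' @param x a GRanges.
#' @return a GRanges with disjoint, non-abutting intervals.
#' @export
normalizeFeatures <- function(x) {
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Fraction of a chromosome (or the genome) covered by a feature set
#'
#' @param x a GRanges carrying seqlengths (merged internally).
#' @param chrom a chromosome name, or NULL for the whole genome (total
#'   covered bp over total genome length).
#' @return a fraction in [0, 1].
#' @export
coverageFraction <- function(x, chrom = NULL) {
  x <- normalizeFeatures(x)
  lens <- GenomeInfoDb::seqlengths(x)
  if (any(is.na(lens)))
    stop("coverageFraction requires seqlengths on all chromosomes")
  if (!is.null(chrom)) {
    if (!chrom %in% names(lens)) stop("unknown chromosome '", chrom, "'")
    x <- x[GenomicRanges::seqnames(x) == chrom]
    return(sum(GenomicRanges::width(x)) / lens[[chrom]])
  }
  sum(GenomicRanges::width(x)) / sum(as.numeric(lens))
}

#' Pseudo-chromosome universe defined by a mask
#'
#' Each mask interval becomes its own pseudo-chromosome named
#' \code{"chrom:start-end"} (0-based half-open display coordinates) with
#' length equal to the interval width.
#'
#' @param mask a normalized GRanges.
#' @return a Seqinfo over the pseudo-chromosomes.
#' @export
maskGenome <- function(mask) {
  if (length(mask) == 0L) stop("empty mask")
  mask <- GenomicRanges::sort(normalizeFeatures(mask), ignore.strand = TRUE)
  nm <- paste0(GenomicRanges::seqnames(mask), ":",
               GenomicRanges::start(mask) - 1L, "-",
               GenomicRanges::end(mask))
  GenomeInfoDb::Seqinfo(nm, GenomicRanges::width(mask))
}

#' Restrict a feature set to a genomic subset
#'
#' Confines the comparison to investigator-defined intervals: features are
#' clipped to the mask intervals and re-expressed in the coordinates of the
#' pseudo-chromosomes of [maskGenome()]; features outside the mask are
#' dropped.  Both query and reference must be restricted with the same
#' mask before testing.
#'
#' @param x a GRanges to restrict.
#' @param mask the mask GRanges (merged internally; must be nonempty).
#' @return a GRanges on the pseudo-chromosome universe.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chrA", 1000)
#' fs <- GenomicRanges::GRanges("chrA", IRanges::IRanges(101, 200), seqinfo = si)
#' mk <- GenomicRanges::GRanges("chrA", IRanges::IRanges(151, 300), seqinfo = si)
#' restrictToMask(fs, mk)   # "chrA:150-300":1-50
#' @export
restrictToMask <- function(x, mask) {
  if (length(mask) == 0L) stop("empty mask")
  mask <- GenomicRanges::sort(normalizeFeatures(mask), ignore.strand = TRUE)
  newSi <- maskGenome(mask)
  hits <- GenomicRanges::findOverlaps(x, mask, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  cs <- pmax(GenomicRanges::start(x)[qi], GenomicRanges::start(mask)[si])
  ce <- pmin(GenomicRanges::end(x)[qi], GenomicRanges::end(mask)[si])
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(newSi)[si],
    IRanges::IRanges(cs - GenomicRanges::start(mask)[si] + 1L,
                     ce - GenomicRanges::start(mask)[si] + 1L),
    seqinfo = newSi)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
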