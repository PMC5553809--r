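#' Read / write genome FASTA
#'
#' @param file FASTA path.
#' @return `readGenomeFasta()` returns a `DNAString`; the id is attached as
#'   the `"genomeId"` attribute.
#' @export
readGenomeFasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  if (length(x) != 1L)
    stop("expected a single-sequence genome FASTA")
  g <- x[[1L]]
  attr(g, "genomeId") <- sub("\\s.*$", "", names(x)[1L])
  g
}

#' @rdname readGenomeFasta
#' @param genome a `DNAString` or character sequence.
#' @param genomeId FASTA record name.
#' @export
writeGenomeFasta <- function(genome, file, genomeId = "genome") {
  x <- Biostrings::DNAStringSet(as.character(genome))
  names(x) <- genomeId
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

.grWithSeqlengths <- function(gr, G) {
  sn <- as.character(GenomeInfoDb::seqnames(gr))
  lev <- if (length(sn)) sn[1L] else "genome"
  GenomeInfoDb::seqlevels(gr) <- lev
  GenomeInfoDb::seqlengths(gr) <- G
  gr
}

#' Interval and track I/O (BED / bedGraph)
#'
#' BED files are 0-based half-open on disk; in-memory `GRanges` follow the
#' usual 1-based inclusive convention and [rtracklayer::export()] converts
#' between the two. Per-position profiles and tracks are run-length
#' compressed into bedGraph.
#'
#' @param gr a `GRanges`.
#' @param file output path.
#' @param G genome length (needed so the written header is complete).
#' @export
writeIntervalsBed <- function(gr, file, G = NULL) {
  if (!is.null(G)) gr <- .grWithSeqlengths(gr, G)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname writeIntervalsBed
#' @export
readIntervalsBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  gr
}

#' @rdname writeIntervalsBed
#' @param x an [AnchorProfile-class], [CoverageTrack-class],
#'   [RatioTrack-class] or numeric per-position vector.
#' @param genomeId sequence name written to the file.
#' @export
writeTrackBedGraph <- function(x, file, genomeId = NULL) {
  vals <- if (is(x, "AnchorProfile")) x@counts
          else if (is(x, "CoverageTrack") || is(x, "RatioTrack")) x@values
          else as.numeric(x)
  if (is.null(genomeId))
    genomeId <- if (is.numeric(x)) "genome" else x@genomeId
  rl <- rle(vals)
  ends <- cumsum(rl$lengths)
  gr <- GenomicRanges::GRanges(
    genomeId,
    IRanges::IRanges(start = ends - rl$lengths + 1L, end = ends),
    score = rl$values)
  gr <- .grWithSeqlengths(gr, length(vals))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname writeIntervalsBed
#' @export
readTrackBedGraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  G <- max(GenomicRanges::end(gr))
  vals <- numeric(G)
  for (k in seq_along(gr))
    vals[GenomicRanges::start(gr)[k]:GenomicRanges::end(gr)[k]] <-
      S4Vectors::mcols(gr)$score[k]
  vals
}

#' Write the planted truth of a synthetic experiment
#'
#' Sites go to BED plus a TSV of enrichment factors; repeat footprints to a
#' second BED.
#'
#' @param truth a [TruthSet-class].
#' @param dir output directory.
#' @param G genome length.
#' @return Invisibly, the paths written.
#' @export
writeTruth <- function(truth, dir, G) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sitesBed <- file.path(dir, "truth_sites.bed")
  repsBed <- file.path(dir, "truth_repeats.bed")
  facTsv <- file.path(dir, "truth_factors.tsv")
  writeIntervalsBed(truth@sites, sitesBed, G)
  writeIntervalsBed(truth@repeats, repsBed, G)
  df <- data.frame(start = GenomicRanges::start(truth@sites),
                   end = GenomicRanges::end(truth@sites),
                   factor = S4Vectors::mcols(truth@sites)$enrichment)
  utils::write.table(df, facTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sitesBed, repsBed, facTsv))
}
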