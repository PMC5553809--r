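#' Read / write a FASTQ library
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] producing [ReadLibrary-class] objects
#' (Sanger Phred+33 qualities).
#'
#' @param file FASTQ path.
#' @param label `"control"` or `"ip"`.
#' @param experiment experiment identifier.
#' @export
readFastqLibrary <- function(file, label = "control", experiment = "1") {
  x <- Biostrings::readDNAStringSet(file, format = "fastq",
                                    with.qualities = TRUE)
  qual <- S4Vectors::mcols(x)$qualities
  new("ReadLibrary", sequences = x,
      qualities = if (is.null(qual)) Biostrings::BStringSet() else
        Biostrings::BStringSet(qual),
      label = label, experiment = experiment)
}

#' @rdname readFastqLibrary
#' @param lib a [ReadLibrary-class].
#' @export
writeFastqLibrary <- function(lib, file) {
  if (!length(lib@qualities))
    stop("library has no qualities; FASTQ requires them")
  seqs <- lib@sequences
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("read_%06d", seq_along(seqs))
  Biostrings::writeXStringSet(seqs, file, format = "fastq",
                              qualities = lib@qualities)
  invisible(file)
}

.minQuality <- function(qualities) {
  # minimum Phred score per read; Inf for zero-length reads
  q <- as(Biostrings::PhredQuality(qualities), "IntegerList")
  vapply(q, function(v) if (length(v)) min(v) else Inf, numeric(1))
}

#' Quality-filter a read library
#'
#' Retains exactly the reads whose every base quality is at least `qMin`
#' (default Q20, i.e. 99% probability of a correct call at every position).
#' Order is preserved; retained / discarded tallies are reported via
#' `message()` and attached as the `"filterStats"` attribute.
#'
#' @param lib a [ReadLibrary-class] with qualities.
#' @param qMin minimum per-base Phred score (inclusive).
#' @return The filtered [ReadLibrary-class].
#' @export
#' @examples
#' lib <- new("ReadLibrary",
#'   sequences = Biostrings::DNAStringSet(c("ACGT", "GGCC")),
#'   qualities = Biostrings::BStringSet(c("IIII", "II4I")),
#'   label = "control", experiment = "1")
#' qualityFilter(lib, 20)   # keeps the first read only
qualityFilter <- function(lib, qMin = 20) {
  stopifnot(is(lib, "ReadLibrary"))
  if (!length(lib@qualities))
    stop("library has no base qualities; disable filtering instead ",
         "of calling qualityFilter()")
  keep <- .minQuality(lib@qualities) >= qMin
  out <- lib[keep]
  message("qualityFilter: retained ", sum(keep), " of ", length(keep),
          " reads (Q >= ", qMin, ")")
  attr(out, "filterStats") <- c(retained = sum(keep),
                                discarded = sum(!keep))
  out
}

#' Trim reads to a standard length taken from their centre
#'
#' Reads of length >= `target` are replaced by their central
#' `target`-length substring (an odd surplus leaves one extra base on the
#' right: left offset = floor((len - target) / 2)); shorter reads are
#' discarded. Qualities are trimmed identically.
#'
#' @param lib a [ReadLibrary-class].
#' @param target standard read length in bp.
#' @return The standardized [ReadLibrary-class]; all reads have width
#'   `target`.
#' @export
#' @examples
#' lib <- new("ReadLibrary",
#'   sequences = Biostrings::DNAStringSet(strrep("ACGT", 30)),
#'   qualities = Biostrings::BStringSet(strrep("I", 120)),
#'   label = "ip", experiment = "2")
#' Biostrings::width(trimToCenter(lib, 50)@sequences)
trimToCenter <- function(lib, target = 50) {
  stopifnot(is(lib, "ReadLibrary"), target >= 1)
  target <- as.integer(target)
  w <- Biostrings::width(lib@sequences)
  keep <- w >= target
  out <- lib[keep]
  off <- (Biostrings::width(out@sequences) - target) %/% 2L
  out@sequences <- Biostrings::subseq(out@sequences, start = off + 1L,
                                      width = target)
  if (length(out@qualities))
    out@qualities <- Biostrings::subseq(out@qualities, start = off + 1L,
                                        width = target)
  validObject(out)
  out
}
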