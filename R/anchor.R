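.asGenomeString <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (length(genome) != 1L)
      stop("expected a single genome sequence")
    genome <- genome[[1L]]
  }
  toupper(as.character(genome))
}

#' Build an exact-match index of a genome
#'
#' Indexes every `readLength`-mer of the top strand (including
#' origin-spanning k-mers for circular genomes). Lookups are
#' strand-collapsed: a read and its exact reverse complement resolve to the
#' same left coordinate, the behaviour that lets signals from fully
#' complementary reads coincide.
#'
#' @param genome a `DNAString`, single-sequence `DNAStringSet`, or character
#'   string over {A,C,G,T}.
#' @param readLength the fixed read length the index will be queried with.
#' @param circular whether the genome is circular.
#' @param genomeId genome identifier carried into downstream objects.
#' @return An [ExactIndex-class].
#' @export
#' @examples
#' idx <- buildIndex("ACGTACGTGGTACC", 4, circular = FALSE)
#' lookupKmer(idx, "ACGT")   # left positions 1 and 5
#' lookupKmer(idx, "ACCA")   # 8: revcomp(ACCA) = TGGT is there (strand collapse)
buildIndex <- function(genome, readLength, circular = TRUE,
                       genomeId = "genome") {
  g <- .asGenomeString(genome)
  ptr <- .build_index_cpp(g, as.integer(readLength), circular)
  new("ExactIndex", genome = g, genomeId = genomeId,
      readLength = as.integer(readLength), circular = circular, ptr = ptr)
}

# rebuild the hash if the external pointer did not survive serialization
.ensurePtr <- function(index) {
  if (.index_is_null_cpp(index@ptr))
    .build_index_cpp(index@genome, index@readLength, index@circular)
  else index@ptr
}

#' Look up the exact genomic occurrences of a k-mer
#'
#' @param index an [ExactIndex-class].
#' @param kmer a character string (or `DNAString`) of the index read length.
#' @return Sorted 1-based left coordinates of every exact occurrence of the
#'   k-mer or of its reverse complement; empty when absent from both
#'   strands.
#' @export
lookupKmer <- function(index, kmer) {
  stopifnot(is(index, "ExactIndex"))
  .lookup_kmer_cpp(.ensurePtr(index), toupper(as.character(kmer))) + 1L
}

#' Anchor a read library onto the genome
#'
#' Every read is matched exactly (no mismatches) against both strands; a
#' match contributes a count at its left genome coordinate. Under the
#' default `"all-occurrences"` policy a read matching k loci adds 1 at each
#' of them (so repeated loci such as rRNA operons remain countable); under
#' `"unique-only"` multi-locus reads are dropped and tallied. Reads with no
#' exact match anywhere (including reads containing N) are tallied as
#' unanchored.
#'
#' @param lib a [ReadLibrary-class]; all reads must have the index read
#'   length (use [trimToCenter()] first).
#' @param index an [ExactIndex-class].
#' @param policy `"all-occurrences"` or `"unique-only"`.
#' @return An [AnchorProfile-class].
#' @export
anchorReads <- function(lib, index,
                        policy = c("all-occurrences", "unique-only")) {
  stopifnot(is(lib, "ReadLibrary"), is(index, "ExactIndex"))
  policy <- match.arg(policy)
  w <- Biostrings::width(lib@sequences)
  if (length(w) && !all(w == index@readLength))
    stop("all reads must have length ", index@readLength,
         "; run trimToCenter() first")
  res <- .anchor_reads_cpp(.ensurePtr(index),
                           as.character(lib@sequences),
                           policy == "unique-only")
  new("AnchorProfile", genomeId = index@genomeId, counts = res$counts,
      policy = policy, nAnchored = res$n_anchored,
      nUnanchored = res$n_unanchored, nMulti = res$n_multi,
      readLength = index@readLength, circular = index@circular)
}
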