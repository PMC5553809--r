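.defaultRanges <- list(
  direct   = list(i = 5:24, j = 0:20),
  inverted = list(i = 5:18, j = 3:20)
)

#' Scan a genome for direct or inverted repeat pairs
#'
#' Enumerates, for every arm length i and spacer j in range, each top-strand
#' position whose i-mer arm is followed after exactly j bases by an
#' identical copy (direct) or by its reverse complement (inverted). Each
#' qualifying (position, i, j) is counted once; circular genomes honour
#' origin-spanning pairs. Default ranges are the published scan settings:
#' direct 5-24 bp arms / 0-20 bp spacers, inverted 5-18 bp arms / 3-20 bp
#' spacers.
#'
#' With `maximality = "none"` (default) every qualifying combination is
#' reported, which keeps the per-(i, j) totals exactly multiplicative
#' (L_ij = n_ij * (2i + j)). `"arm-maximal"` suppresses pairs extendable to
#' a longer qualifying pair along the same matching axis: for direct pairs
#' the match run at fixed offset i + j, for inverted pairs the palindrome at
#' fixed centre (outward, and inward when j >= 2).
#'
#' @param genome `DNAString` / character genome over {A,C,G,T}.
#' @param type `"inverted"` or `"direct"`.
#' @param iRange,jRange integer vectors of arm lengths / spacers; defaults
#'   depend on `type` as above.
#' @param circular whether to honour origin-spanning pairs.
#' @param maximality `"none"` or `"arm-maximal"`.
#' @param genomeId genome identifier.
#' @return A [RepeatCatalog-class].
#' @export
#' @examples
#' # an inverted (i = 5, j = 3) pair by construction: AATTC = revcomp(GAATT)
#' scanRepeats("GAATTCCCAATTC", "inverted", iRange = 5, jRange = 3,
#'             circular = FALSE)
scanRepeats <- function(genome,
                        type = c("inverted", "direct"),
                        iRange = NULL, jRange = NULL,
                        circular = TRUE,
                        maximality = c("none", "arm-maximal"),
                        genomeId = "genome") {
  type <- match.arg(type)
  maximality <- match.arg(maximality)
  if (is.null(iRange)) iRange <- .defaultRanges[[type]]$i
  if (is.null(jRange)) jRange <- .defaultRanges[[type]]$j
  if (!length(iRange) || !length(jRange))
    stop("arm-length and spacer ranges must be non-empty")
  g <- .asGenomeString(genome)
  df <- .scan_repeats_cpp(g, type == "inverted", as.integer(iRange),
                          as.integer(jRange), circular,
                          maximality == "arm-maximal")
  df$start <- df$start + 1L
  new("RepeatCatalog", pairs = df, type = type,
      genomeLength = nchar(g), genomeId = genomeId, circular = circular,
      maximality = maximality)
}

#' Count and summed footprint for one (i, j) cell
#'
#' Footprints are counted with multiplicity (no merging of overlapping
#' pairs), so the summed length is exactly n_ij * (2i + j); an absent
#' (i, j) combination gives `c(n = 0, L = 0)`.
#'
#' @param cat a [RepeatCatalog-class].
#' @param i arm length in bp.
#' @param j spacer in bp.
#' @return Named numeric vector with elements `n` (pair count) and `L`
#'   (summed footprint in bp).
#' @export
catalogTotals <- function(cat, i, j) {
  stopifnot(is(cat, "RepeatCatalog"))
  n <- sum(cat@pairs$i == i & cat@pairs$j == j)
  c(n = n, L = n * (2L * i + j))
}

#' Per-(i, j) summary of a repeat catalog
#'
#' @param object a [RepeatCatalog-class].
#' @param ... unused.
#' @return `data.frame` with one row per (i, j) present: `i`, `j`, `n`,
#'   `L` and the genome fraction `L / G`.
#' @export
setMethod("summary", "RepeatCatalog", function(object, ...) {
  p <- object@pairs
  if (!nrow(p))
    return(data.frame(i = integer(), j = integer(), n = integer(),
                      L = integer(), fraction = numeric()))
  agg <- stats::aggregate(list(n = rep(1L, nrow(p))),
                          by = list(i = p$i, j = p$j), FUN = sum)
  agg$L <- agg$n * (2L * agg$i + agg$j)
  agg$fraction <- agg$L / object@genomeLength
  agg[order(agg$i, agg$j), ]
})

#' Repeat-pair footprints as genomic intervals
#'
#' Each pair contributes its full arm + spacer + arm span as one interval
#' (the holistic-unit convention). Footprints wrapping the origin of a
#' circular genome are split into their two arcs.
#'
#' @param cat a [RepeatCatalog-class], optionally restricted with `i`, `j`.
#' @param i,j optional arm length / spacer filters.
#' @return A `GRanges` with `i`, `j` metadata columns (duplicates retained).
#' @export
repeatFootprints <- function(cat, i = NULL, j = NULL) {
  stopifnot(is(cat, "RepeatCatalog"))
  p <- cat@pairs
  if (!is.null(i)) p <- p[p$i %in% i, , drop = FALSE]
  if (!is.null(j)) p <- p[p$j %in% j, , drop = FALSE]
  G <- cat@genomeLength
  if (!nrow(p))
    return(GenomicRanges::GRanges())
  w <- 2L * p$i + p$j
  en <- p$start + w - 1L
  wraps <- en > G
  main <- GenomicRanges::GRanges(
    cat@genomeId,
    IRanges::IRanges(start = p$start, end = pmin(en, G)),
    i = p$i, j = p$j)
  if (any(wraps)) {
    tail <- GenomicRanges::GRanges(
      cat@genomeId,
      IRanges::IRanges(start = 1L, end = en[wraps] - G),
      i = p$i[wraps], j = p$j[wraps])
    main <- c(main, tail)
  }
  main
}
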