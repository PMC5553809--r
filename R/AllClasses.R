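#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' A set of sequencing reads with optional base qualities
#'
#' Container for one ChIP-seq library (control or immunoprecipitated).
#' Sequences are held as a [Biostrings::DNAStringSet]; qualities, when
#' present, as a `BStringSet` of Sanger Phred+33 strings parallel to the
#' sequences.
#'
#' @slot sequences `DNAStringSet` of reads.
#' @slot qualities `BStringSet` of Phred+33 quality strings (may be empty).
#' @slot label `"control"` or `"ip"`.
#' @slot experiment free-text experiment identifier.
#' @export
setClass("ReadLibrary",
  slots = c(
    sequences  = "DNAStringSet",
    qualities  = "BStringSet",
    label      = "character",
    experiment = "character"
  )
)

setValidity("ReadLibrary", function(object) {
  msg <- character()
  if (length(object@qualities) > 0L) {
    if (length(object@qualities) != length(object@sequences))
      msg <- c(msg, "sequences and qualities have different lengths")
    else if (!all(Biostrings::width(object@qualities) ==
                  Biostrings::width(object@sequences)))
      msg <- c(msg, "per-read sequence and quality widths differ")
  }
  if (length(object@label) != 1L ||
      !object@label %in% c("control", "ip"))
    msg <- c(msg, "label must be \"control\" or \"ip\"")
  if (length(msg)) msg else TRUE
})

#' Exact-match k-mer index over a genome
#'
#' Supports strand-collapsed exact lookup of fixed-length reads against both
#' strands of a (possibly circular) genome; origin-spanning k-mers are
#' indexed for circular genomes. The hash lives in an external pointer and is
#' rebuilt transparently from the stored sequence if the pointer does not
#' survive serialization.
#'
#' @slot genome genome sequence as a single character string.
#' @slot genomeId genome identifier.
#' @slot readLength the k-mer length the index answers queries for.
#' @slot circular whether the genome is circular.
#' @slot ptr external pointer to the C++ hash.
#' @export
setClass("ExactIndex",
  slots = c(
    genome     = "character",
    genomeId   = "character",
    readLength = "integer",
    circular   = "logical",
    ptr        = "ANY"
  )
)

#' Per-position anchored-read counts for one library
#'
#' The anchoring output: an integer-valued count at every genome position
#' giving the number of reads whose exact match (of the read or its reverse
#' complement) has its left coordinate there. Counts become fractional after
#' scaling normalization.
#'
#' @slot genomeId genome identifier.
#' @slot counts numeric vector of length G (position 1 = genome position 1).
#' @slot policy `"all-occurrences"` or `"unique-only"`.
#' @slot nAnchored,nUnanchored,nMulti anchoring tallies; `nMulti` counts
#'   reads matching more than one locus (dropped under `"unique-only"`).
#' @slot readLength read length used.
#' @slot circular whether the genome is circular.
#' @export
setClass("AnchorProfile",
  slots = c(
    genomeId    = "character",
    counts      = "numeric",
    policy      = "character",
    nAnchored   = "integer",
    nUnanchored = "integer",
    nMulti      = "integer",
    readLength  = "integer",
    circular    = "logical"
  )
)

setValidity("AnchorProfile", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!object@policy %in% c("all-occurrences", "unique-only"))
    msg <- c(msg, "unknown anchoring policy")
  if (length(msg)) msg else TRUE
})

#' Running-window count track
#'
#' Value at position p is the sum of per-position counts over the
#' `window`-length window centred at p (circular wrap when the genome is
#' circular, truncation at the ends otherwise).
#'
#' @slot genomeId genome identifier.
#' @slot values numeric vector of length G.
#' @slot window window width in bp.
#' @slot circular whether the genome is circular.
#' @export
setClass("CoverageTrack",
  slots = c(
    genomeId = "character",
    values   = "numeric",
    window   = "integer",
    circular = "logical"
  )
)

#' Per-position enrichment-ratio track
#'
#' R(p) = (IP window count + pseudocount) / (control window count +
#' pseudocount), with the IP profile scaling-normalized beforehand. This is
#' the occupancy signal that peaks (R >= 1.5) and unbound regions (R < 1)
#' are called from.
#'
#' @slot genomeId genome identifier.
#' @slot values numeric R values, length G.
#' @slot window window width the counts were computed with.
#' @slot pseudocount pseudocount added to both window counts.
#' @slot experiment experiment identifier.
#' @slot circular whether the genome is circular.
#' @export
setClass("RatioTrack",
  slots = c(
    genomeId    = "character",
    values      = "numeric",
    window      = "integer",
    pseudocount = "numeric",
    experiment  = "character",
    circular    = "logical"
  )
)

setValidity("RatioTrack", function(object) {
  if (any(object@values < 0)) "R values must be >= 0" else TRUE
})

#' Result of trimmed-mean scaling normalization
#'
#' @slot trim fraction of positions removed from each tail before the mean.
#' @slot ipTrimmedMean,ctrlTrimmedMean trimmed means of the raw profiles.
#' @slot factor multiplier applied to the IP profile
#'   (control trimmed mean / IP trimmed mean).
#' @export
setClass("ScalingResult",
  slots = c(
    trim            = "numeric",
    ipTrimmedMean   = "numeric",
    ctrlTrimmedMean = "numeric",
    factor          = "numeric"
  )
)

#' Parameters of ratio-threshold peak and unbound-region calling
#'
#' Defaults follow the published rule set: peaks require R >= 1.5 at >= 50%
#' of positions over >= 60 bp with above-threshold ends; unbound regions
#' require R < 1.0 at every position in both experiments over >= 60 bp;
#' regions separated by < 30 bp merge when every intermediate position has
#' R <= 1.1.
#'
#' @slot rMin peak threshold on R (inclusive).
#' @slot minFrac minimum fraction of above-threshold positions (inclusive).
#' @slot minLen minimum region length in bp (inclusive).
#' @slot mergeGap regions closer than this many bp are merge candidates
#'   (strict).
#' @slot mergeMaxR maximum R tolerated at intermediate positions when
#'   merging (inclusive).
#' @slot urMaxR unbound threshold on R (strict).
#' @slot window running-window width the R track should be built with.
#' @export
setClass("PeakCallParams",
  slots = c(
    rMin      = "numeric",
    minFrac   = "numeric",
    minLen    = "integer",
    mergeGap  = "integer",
    mergeMaxR = "numeric",
    urMaxR    = "numeric",
    window    = "integer"
  )
)

setValidity("PeakCallParams", function(object) {
  msg <- character()
  if (object@rMin <= object@urMaxR)
    msg <- c(msg, "rMin must exceed urMaxR")
  if (object@minFrac <= 0 || object@minFrac > 1)
    msg <- c(msg, "minFrac must be in (0, 1]")
  if (object@minLen < 1L) msg <- c(msg, "minLen must be >= 1")
  if (object@mergeGap < 0L) msg <- c(msg, "mergeGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Catalog of direct or inverted repeat pairs
#'
#' One row per qualifying (position, arm length i, spacer j) combination.
#' The footprint of a pair spans arm + spacer + arm, i.e. 2i + j bp, and the
#' per-(i, j) summed footprint obeys L_ij = n_ij * (2i + j) exactly (no
#' union-deduplication: each pair is a holistic unit).
#'
#' @slot pairs `data.frame` with columns `i`, `j`, `start` (1-based leftmost
#'   coordinate of the pair).
#' @slot type `"direct"` or `"inverted"`.
#' @slot genomeLength genome length G.
#' @slot genomeId genome identifier.
#' @slot circular whether the genome was scanned circularly.
#' @slot maximality `"none"` (every qualifying pair) or `"arm-maximal"`.
#' @export
setClass("RepeatCatalog",
  slots = c(
    pairs        = "data.frame",
    type         = "character",
    genomeLength = "integer",
    genomeId     = "character",
    circular     = "logical",
    maximality   = "character"
  )
)

#' Observed-versus-expected overlap of two interval collections
#'
#' @slot label element-set label (e.g. `"inverted i=5 j=3"` or a set name).
#' @slot target target-set label.
#' @slot observed observed overlapping base pairs O.
#' @slot expected expected overlap E = (L_elements / G) * L_set under
#'   independent placement.
#' @slot k ratio K = O / E (`NA` when E = 0).
#' @slot convention `"multiplicity"` or `"union"`.
#' @export
setClass("EnrichmentResult",
  slots = c(
    label      = "character",
    target     = "character",
    observed   = "numeric",
    expected   = "numeric",
    k          = "numeric",
    convention = "character"
  )
)

#' Specification of a synthetic ChIP-seq experiment
#'
#' Describes the genome (length, base composition, planted repeat pairs),
#' the planted occupancy sites with their per-site IP enrichment factors,
#' the origin-proximal copy-number gradient, and the two read libraries to
#' simulate. Identical spec + seed gives byte-identical outputs.
#'
#' @slot genomeLength genome length in bp (>= 1000).
#' @slot gcFraction G+C fraction of the random background in `[0, 1]`.
#' @slot plantedRepeats `data.frame(type, i, j, position)`; `position` is the
#'   1-based leftmost coordinate of the pair (wrap allowed).
#' @slot plantedSites `data.frame(start, end, factor)`; 1-based inclusive
#'   intervals with IP enrichment factors >= 1.
#' @slot gradientOrigin 1-based position of the replication origin.
#' @slot gradientMax maximal relative copy number at the origin (>= 1).
#' @slot gradientSpan distance over which the copy number decays to 1.
#' @slot readLength emitted read length in bp.
#' @slot readLengthRange optional `c(min, max)` for variable-length reads
#'   (exercises centre-trimming); equal to `readLength` when fixed.
#' @slot nControl,nIp reads per library.
#' @slot fragmentMin,fragmentMax sonication fragment length range in bp.
#' @slot qualityDegradeRate per-read probability of one low-quality base
#'   (0 = constant Q40).
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  slots = c(
    genomeLength       = "integer",
    gcFraction         = "numeric",
    plantedRepeats     = "data.frame",
    plantedSites       = "data.frame",
    gradientOrigin     = "integer",
    gradientMax        = "numeric",
    gradientSpan       = "integer",
    readLength         = "integer",
    readLengthRange    = "integer",
    nControl           = "integer",
    nIp                = "integer",
    fragmentMin        = "integer",
    fragmentMax        = "integer",
    qualityDegradeRate = "numeric",
    seed               = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  G <- object@genomeLength
  if (G < 1000L) msg <- c(msg, "genomeLength must be >= 1000")
  if (object@gcFraction < 0 || object@gcFraction > 1)
    msg <- c(msg, "gcFraction must be in [0, 1]")
  ps <- object@plantedSites
  if (nrow(ps)) {
    if (any(ps$factor < 1)) msg <- c(msg, "enrichment factors must be >= 1")
    if (any(ps$start < 1L | ps$start > G | ps$end < ps$start))
      msg <- c(msg, "planted sites must lie within [1, genomeLength]")
  }
  pr <- object@plantedRepeats
  if (nrow(pr)) {
    if (!all(pr$type %in% c("direct", "inverted")))
      msg <- c(msg, "planted repeat type must be direct or inverted")
    if (any(pr$position < 1L | pr$position > G))
      msg <- c(msg, "planted repeat positions must lie within [1, genomeLength]")
    if (any(pr$i < 1L) || any(pr$j < 0L))
      msg <- c(msg, "planted repeat arms must be >= 1 and spacers >= 0")
  }
  if (object@gradientMax < 1)
    msg <- c(msg, "gradientMax must be >= 1")
  if (object@fragmentMin > object@fragmentMax)
    msg <- c(msg, "fragmentMin must not exceed fragmentMax")
  if (object@readLength > object@fragmentMin)
    msg <- c(msg, "readLength must not exceed the minimum fragment length")
  if (object@readLength > G)
    msg <- c(msg, "readLength must not exceed genomeLength")
  if (object@nControl < 1L || object@nIp < 1L)
    msg <- c(msg, "nControl and nIp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Planted truth of a synthetic experiment
#'
#' @slot sites `GRanges` of planted occupancy sites with an `enrichment`
#'   metadata column.
#' @slot repeats `GRanges` of planted repeat footprints with `type`, `i`,
#'   `j` metadata columns.
#' @slot expectedCoverage per-position relative copy number (mean 1): the
#'   expected relative fragment coverage of the control library.
#' @export
setClass("TruthSet",
  slots = c(
    sites            = "GRanges",
    repeats          = "GRanges",
    expectedCoverage = "numeric"
  )
)
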