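#' Build a synthetic-experiment specification
#'
#' Constructs and validates a [SyntheticSpec-class]. The defaults mirror the
#' conditions of the study the pipeline was designed around: 50-nt single-end
#' reads from 150-300 bp sonication fragments, constant Q40 base qualities,
#' and a replication-associated copy-number gradient that is maximal at the
#' origin and decays linearly to 1 at the antipode.
#'
#' @param genomeLength genome length in bp (>= 1000).
#' @param gcFraction G+C fraction of the random background.
#' @param plantedRepeats `data.frame(type, i, j, position)` of repeat pairs
#'   to write into the genome (1-based leftmost coordinates).
#' @param plantedSites `data.frame(start, end, factor)` of occupancy sites
#'   (1-based inclusive) with IP enrichment factors >= 1. Factors between 2
#'   and 10 reproduce the dynamic range of published R values.
#' @param gradientOrigin 1-based origin position.
#' @param gradientMax relative copy number at the origin (>= 1); 2 is
#'   typical of exponentially growing bacteria.
#' @param gradientSpan decay distance in bp; default half the genome
#'   (linear decay to the antipode).
#' @param readLength read length in bp.
#' @param readLengthRange optional `c(min, max)` to emit variable-length
#'   reads (to exercise centre-trimming).
#' @param nControl,nIp number of reads per library.
#' @param fragmentRange `c(min, max)` sonication fragment lengths in bp.
#' @param qualityDegradeRate per-read probability that one base is assigned
#'   Q2 instead of Q40.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   genomes and libraries.
#' @return A validated [SyntheticSpec-class].
#' @export
#' @examples
#' sp <- syntheticSpec(5000, plantedSites = data.frame(
#'   start = 2000, end = 2200, factor = 3), nControl = 2000, nIp = 2000)
#' sp
syntheticSpec <- function(genomeLength,
                          gcFraction = 0.5,
                          plantedRepeats = NULL,
                          plantedSites = NULL,
                          gradientOrigin = 1L,
                          gradientMax = 2,
                          gradientSpan = NULL,
                          readLength = 50L,
                          readLengthRange = NULL,
                          nControl = 10000L,
                          nIp = 10000L,
                          fragmentRange = c(150L, 300L),
                          qualityDegradeRate = 0,
                          seed = 1L) {
  if (is.null(plantedRepeats))
    plantedRepeats <- data.frame(type = character(), i = integer(),
                                 j = integer(), position = integer())
  if (is.null(plantedSites))
    plantedSites <- data.frame(start = integer(), end = integer(),
                               factor = numeric())
  if (is.null(gradientSpan)) gradientSpan <- as.integer(genomeLength %/% 2L)
  if (is.null(readLengthRange)) readLengthRange <- c(readLength, readLength)
  new("SyntheticSpec",
      genomeLength = as.integer(genomeLength),
      gcFraction = gcFraction,
      plantedRepeats = plantedRepeats,
      plantedSites = plantedSites,
      gradientOrigin = as.integer(gradientOrigin),
      gradientMax = gradientMax,
      gradientSpan = as.integer(gradientSpan),
      readLength = as.integer(readLength),
      readLengthRange = as.integer(readLengthRange),
      nControl = as.integer(nControl),
      nIp = as.integer(nIp),
      fragmentMin = as.integer(fragmentRange[1L]),
      fragmentMax = as.integer(fragmentRange[2L]),
      qualityDegradeRate = qualityDegradeRate,
      seed = as.integer(seed))
}

# circular distance of 1-based positions to the origin
.circDist <- function(pos, origin, G) {
  d <- abs(pos - origin)
  pmin(d, G - d)
}

#' Per-position copy-number multiplier of the replication gradient
#'
#' Linear decay from `gradientMax` at the origin to 1 at `gradientSpan` bp
#' away (applied symmetrically on the circle), emulating the origin-proximal
#' coverage bias of exponentially replicating chromosomes.
#'
#' @param spec a [SyntheticSpec-class].
#' @return Numeric vector of length `genomeLength(spec)`, all values >= 1.
#' @export
gradientMultiplier <- function(spec) {
  G <- spec@genomeLength
  d <- .circDist(seq_len(G), spec@gradientOrigin, G)
  frac <- pmin(d, spec@gradientSpan) / spec@gradientSpan
  spec@gradientMax - (spec@gradientMax - 1) * frac
}

.randomBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.revcompChar <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# 1-based circular footprint positions of a repeat pair
.repeatFootprintPos <- function(position, i, j, G) {
  ((position - 1L + seq_len(2L * i + j) - 1L) %% G) + 1L
}

#' Generate a synthetic genome with planted truth
#'
#' Draws a random background sequence at the requested base composition and
#' writes every planted repeat pair into it (for inverted pairs the second
#' arm is the reverse complement of the first). Planted repeat footprints
#' must not overlap one another: overlapping elements could contradict each
#' other and are rejected.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list with elements `genome` (a [Biostrings::DNAString]) and
#'   `truth` (a [TruthSet-class] recording planted sites, planted repeat
#'   footprints and the expected relative coverage).
#' @export
#' @examples
#' sp <- syntheticSpec(2000, plantedRepeats = data.frame(
#'   type = "inverted", i = 6L, j = 4L, position = 500L))
#' g <- makeGenome(sp)
#' g$truth
makeGenome <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  G <- spec@genomeLength
  set.seed(spec@seed)
  bases <- .randomBases(G, spec@gcFraction)

  pr <- spec@plantedRepeats
  if (nrow(pr)) {
    foot <- lapply(seq_len(nrow(pr)), function(k)
      .repeatFootprintPos(pr$position[k], pr$i[k], pr$j[k], G))
    allpos <- unlist(foot)
    if (anyDuplicated(allpos))
      stop("overlapping planted repeat footprints contradict each other: ",
           "positions ", paste(utils::head(
             unique(allpos[duplicated(allpos)]), 5L), collapse = ", "))
    for (k in seq_len(nrow(pr))) {
      i <- pr$i[k]; j <- pr$j[k]
      arm1 <- .randomBases(i, spec@gcFraction)
      arm2 <- if (pr$type[k] == "direct") arm1 else
        chartr("ACGT", "TGCA", rev(arm1))
      pos <- foot[[k]]
      bases[pos[seq_len(i)]] <- arm1
      bases[pos[(i + j + 1L):(2L * i + j)]] <- arm2
    }
  }

  genome <- Biostrings::DNAString(paste(bases, collapse = ""))

  sites <- if (nrow(spec@plantedSites))
    GenomicRanges::GRanges("synthetic", IRanges::IRanges(
      start = spec@plantedSites$start, end = spec@plantedSites$end),
      enrichment = spec@plantedSites$factor)
  else GenomicRanges::GRanges()
  repTruth <- if (nrow(pr)) {
    w <- 2L * pr$i + pr$j
    GenomicRanges::GRanges("synthetic", IRanges::IRanges(
      start = pr$position, width = w),
      type = pr$type, i = pr$i, j = pr$j)
  } else GenomicRanges::GRanges()

  m <- gradientMultiplier(spec)
  truth <- new("TruthSet", sites = sites, repeats = repTruth,
               expectedCoverage = m / mean(m))
  list(genome = genome, truth = truth)
}

.extractReads <- function(doubled, starts0, lens, G) {
  # starts0 are 0-based; doubled is the genome concatenated with itself
  substring(doubled, starts0 + 1L, starts0 + lens)
}

.simulateLibrary <- function(doubled, G, n, weights, spec, label) {
  fraglen <- sample(spec@fragmentMin:spec@fragmentMax, n, replace = TRUE)
  mid <- sample.int(G, n, replace = TRUE, prob = weights)
  start0 <- ((mid - 1L) - fraglen %/% 2L) %% G
  lr <- spec@readLengthRange
  readlen <- if (lr[1L] == lr[2L]) rep.int(lr[1L], n) else
    pmin(sample(lr[1L]:lr[2L], n, replace = TRUE), fraglen)
  top <- sample(c(TRUE, FALSE), n, replace = TRUE)
  # a read is emitted from the 5' end of either fragment strand
  rstart0 <- ifelse(top, start0, (start0 + fraglen - readlen) %% G)
  seqs <- .extractReads(doubled, rstart0, readlen, G)
  dna <- Biostrings::DNAStringSet(seqs)
  if (any(!top))
    dna[!top] <- Biostrings::reverseComplement(dna[!top])
  names(dna) <- sprintf("%s_%06d", label, seq_len(n))
  qual <- strrep("I", readlen)  # Phred+33 "I" = Q40
  if (spec@qualityDegradeRate > 0) {
    hit <- stats::runif(n) < spec@qualityDegradeRate
    if (any(hit)) {
      at <- 1L + floor(stats::runif(sum(hit)) * readlen[hit])
      qual[hit] <- mapply(function(q, a) {
        substr(q, a, a) <- "#"  # Q2
        q
      }, qual[hit], at, USE.NAMES = FALSE)
    }
  }
  new("ReadLibrary", sequences = dna,
      qualities = Biostrings::BStringSet(qual),
      label = if (label == "ctrl") "control" else "ip",
      experiment = "synthetic")
}

#' Simulate control and immunoprecipitated read libraries
#'
#' Fragments are drawn with midpoint probability proportional to the
#' copy-number gradient (control library) and to gradient x site enrichment
#' factor where the fragment midpoint lies inside a planted site (IP
#' library). Fragment lengths are uniform on the configured range; each read
#' is emitted from the 5' end of a uniformly chosen fragment strand; base
#' qualities are constant Q40 unless a degradation rate is set. The control
#' library is generated first, so the whole simulation is a single
#' deterministic stream of the spec seed.
#'
#' @param genome a `DNAString` (or character) genome, normally from
#'   [makeGenome()].
#' @param truth the matching [TruthSet-class].
#' @param spec the [SyntheticSpec-class] used to build the genome.
#' @return A list with [ReadLibrary-class] elements `control` and `ip`.
#' @export
simulateReads <- function(genome, truth, spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  g <- as.character(genome)
  G <- nchar(g)
  if (G != spec@genomeLength)
    stop("genome length does not match the spec")
  if (spec@readLength > G) stop("readLength exceeds the genome length")
  doubled <- paste0(g, g)
  grad <- truth@expectedCoverage
  fac <- rep(1, G)
  if (length(truth@sites)) {
    for (k in seq_along(truth@sites)) {
      s <- GenomicRanges::start(truth@sites)[k]
      e <- GenomicRanges::end(truth@sites)[k]
      fac[s:e] <- pmax(fac[s:e],
                       S4Vectors::mcols(truth@sites)$enrichment[k])
    }
  }
  set.seed(spec@seed + 1L)
  control <- .simulateLibrary(doubled, G, spec@nControl, grad, spec, "ctrl")
  ip <- .simulateLibrary(doubled, G, spec@nIp, grad * fac, spec, "ip")
  list(control = control, ip = ip)
}
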