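#' Expected base-pair overlap under independent placement
#'
#' If elements with total length `LElements` and a target set of total
#' length `LSet` are placed independently on a genome of length `G`, the
#' expected number of shared base pairs is E = (LElements / G) * LSet.
#' `LElements` may exceed `G` under the multiplicity convention (warned).
#'
#' @param LElements summed element length in bp.
#' @param G genome length in bp.
#' @param LSet target-set length in bp.
#' @return Expected overlap in bp (real-valued).
#' @export
#' @examples
#' expectedOverlap(38909, 4641652, 109330)   # ~916 bp
expectedOverlap <- function(LElements, G, LSet) {
  if (G <= 0) stop("G must be positive")
  if (LElements < 0 || LSet < 0) stop("lengths must be >= 0")
  if (LElements > G)
    warning("summed element length exceeds the genome length ",
            "(multiplicity convention)")
  (LElements / G) * LSet
}

# base pairs shared by two interval collections (union convention);
# coordinate-only, so differing genome ids between otherwise comparable
# sets do not silently zero the overlap
.overlapBp <- function(a, b) {
  ra <- IRanges::reduce(IRanges::ranges(a))
  rb <- IRanges::reduce(IRanges::ranges(b))
  sum(IRanges::width(IRanges::intersect(ra, rb)))
}

#' Observed base-pair overlap between elements and a target set
#'
#' Under the `"multiplicity"` convention each element footprint is
#' intersected with the target independently and the widths are summed
#' (two identical footprints inside the target count twice) - the
#' convention matching additive repeat totals. Under `"union"` the
#' footprints are deduplicated first.
#'
#' @param elements a `GRanges` of element footprints (e.g. from
#'   [repeatFootprints()]); duplicates and overlaps allowed.
#' @param target a `GRanges` target set (internally reduced).
#' @param convention `"multiplicity"` or `"union"`.
#' @return Observed overlap in bp.
#' @export
observedOverlap <- function(elements, target,
                            convention = c("multiplicity", "union")) {
  convention <- match.arg(convention)
  if (!length(elements) || !length(target)) return(0)
  tgt <- IRanges::reduce(IRanges::ranges(target))
  el <- IRanges::ranges(elements)
  if (convention == "union")
    return(sum(IRanges::width(IRanges::intersect(IRanges::reduce(el),
                                                 tgt))))
  ov <- IRanges::findOverlaps(el, tgt)
  if (!length(ov)) return(0)
  sum(IRanges::width(IRanges::pintersect(
    el[S4Vectors::queryHits(ov)], tgt[S4Vectors::subjectHits(ov)])))
}

#' Observed / expected overlap ratio
#'
#' @param o observed overlap in bp.
#' @param e expected overlap in bp.
#' @return K = o / e; `NA` (with a warning) when e is zero.
#' @export
#' @examples
#' kRatio(1134, expectedOverlap(38909, 4641652, 109330))   # ~1.24
kRatio <- function(o, e) {
  if (e == 0) {
    warning("expected overlap is zero; K undefined")
    return(NA_real_)
  }
  o / e
}

#' Fold enrichment between two interval sets
#'
#' O = |a intersect b| at 1-bp resolution (union convention), E = |a| |b| /
#' G, K = O / E. Symmetric in its two sets.
#'
#' @param a,b `GRanges` on the same genome.
#' @param G genome length in bp.
#' @param labelA,labelB labels recorded in the result.
#' @return An [EnrichmentResult-class].
#' @export
foldEnrichment <- function(a, b, G, labelA = "a", labelB = "b") {
  la <- sum(GenomicRanges::width(GenomicRanges::reduce(a)))
  lb <- sum(GenomicRanges::width(GenomicRanges::reduce(b)))
  o <- if (length(a) && length(b)) .overlapBp(a, b) else 0
  e <- expectedOverlap(la, G, lb)
  k <- if (e > 0) o / e else NA_real_
  if (e == 0) warning("one of the sets is empty; K undefined")
  new("EnrichmentResult", label = labelA, target = labelB,
      observed = as.numeric(o), expected = e, k = k,
      convention = "union")
}

#' Per-(i, j) K values of a repeat catalog against a target set
#'
#' For every (i, j) cell of the catalog, computes the observed overlap of
#' its footprints with the target (default multiplicity convention), the
#' closed-form expectation from the summed footprint length, and their
#' ratio K_ij.
#'
#' @param cat a [RepeatCatalog-class].
#' @param target a `GRanges` (e.g. the combined bound set).
#' @param convention `"multiplicity"` or `"union"`; under `"union"` the
#'   expectation uses the deduplicated footprint length.
#' @return `data.frame` with columns `i`, `j`, `n`, `L`, `observed`,
#'   `expected`, `k`.
#' @export
repeatEnrichment <- function(cat, target,
                             convention = c("multiplicity", "union")) {
  convention <- match.arg(convention)
  stopifnot(is(cat, "RepeatCatalog"))
  G <- cat@genomeLength
  lt <- sum(GenomicRanges::width(GenomicRanges::reduce(target)))
  cells <- summary(cat)
  if (!nrow(cells)) {
    cells$observed <- cells$expected <- cells$k <- numeric()
    return(cells)
  }
  res <- lapply(seq_len(nrow(cells)), function(q) {
    fp <- repeatFootprints(cat, i = cells$i[q], j = cells$j[q])
    o <- observedOverlap(fp, target, convention)
    le <- if (convention == "multiplicity") cells$L[q] else
      sum(GenomicRanges::width(GenomicRanges::reduce(fp)))
    e <- expectedOverlap(le, G, lt)
    c(observed = o, expected = e, k = if (e > 0) o / e else NA_real_)
  })
  res <- do.call(rbind, res)
  cells$fraction <- NULL
  cbind(cells, as.data.frame(res))
}

#' Compare K distributions of bound versus unbound sets
#'
#' Two-sided rank-based comparison (Mann-Whitney U by default; Welch t as
#' an option) of per-(i, j) K values between two region sets. Degenerate
#' all-equal inputs give p = 1 with a warning.
#'
#' @param kCs,kUr numeric K values (length >= 3 each).
#' @param method `"wilcox"` or `"t"`.
#' @return An object of class `htest`; the test name is in `$method`.
#' @export
compareKDistributions <- function(kCs, kUr, method = c("wilcox", "t")) {
  method <- match.arg(method)
  kCs <- kCs[!is.na(kCs)]; kUr <- kUr[!is.na(kUr)]
  if (length(kCs) < 3L || length(kUr) < 3L)
    stop("each K list must contain at least 3 values")
  if (length(unique(c(kCs, kUr))) == 1L) {
    warning("all K values are equal; p = 1")
    out <- list(statistic = c(W = NA_real_), p.value = 1,
                method = "degenerate (all values equal)",
                alternative = "two.sided",
                data.name = "kCs and kUr")
    class(out) <- "htest"
    return(out)
  }
  if (method == "wilcox")
    suppressWarnings(stats::wilcox.test(kCs, kUr,
                                        alternative = "two.sided"))
  else
    stats::t.test(kCs, kUr, alternative = "two.sided")
}

#' Expand ChIP-chip probes to enriched intervals
#'
#' Selects probes with at least `minFold` enrichment (inclusive) and
#' expands each to its `width`-bp probe interval; overlapping intervals
#' are merged (union convention).
#'
#' @param probes `data.frame` with columns `start` (1-based probe start)
#'   and `ratio` (enrichment).
#' @param minFold inclusive enrichment cutoff.
#' @param width probe width in bp.
#' @param genomeId genome identifier.
#' @return A reduced `GRanges`.
#' @export
probesToIntervals <- function(probes, minFold = 2.0, width = 60,
                              genomeId = "genome") {
  stopifnot(all(c("start", "ratio") %in% names(probes)))
  sel <- probes[probes$ratio >= minFold, , drop = FALSE]
  if (!nrow(sel)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    genomeId, IRanges::IRanges(start = sel$start, width = width)))
}

#' Expand point coordinates to centred intervals
#'
#' Each point p becomes the interval starting at p - floor(width / 2) of
#' length `width` (so the point sits at the centre); overlapping intervals
#' are merged.
#'
#' @param points numeric genome positions.
#' @param width interval width in bp (36 for point-coordinate peak maxima
#'   of 36-bp-read data).
#' @param genomeId genome identifier.
#' @return A reduced `GRanges`.
#' @export
pointsToIntervals <- function(points, width = 36, genomeId = "genome") {
  if (width < 1) stop("width must be >= 1")
  if (!length(points)) return(GenomicRanges::GRanges())
  width <- as.integer(width)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    genomeId,
    IRanges::IRanges(start = as.integer(points) - width %/% 2L,
                     width = width)))
}
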