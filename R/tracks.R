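.trimmedMean <- function(x, trim) mean(x, trim = trim)

#' Scaling normalization of IP against control
#'
#' Assumes unaffected occupancy at most genomic positions (the microarray
#' scaling assumption): the per-position trimmed mean of each profile is
#' computed after discarding the `trim` highest and `trim` lowest position
#' values (zeros included), and the IP profile is multiplied by
#' control trimmed mean / IP trimmed mean. The control profile is returned
#' unchanged.
#'
#' @param ip,ctrl [AnchorProfile-class] objects on the same genome.
#' @param trim tail fraction to discard on each side (default 2%).
#' @return A list with elements `ip` (scaled profile), `ctrl` (unchanged)
#'   and `scaling` (a [ScalingResult-class]).
#' @export
scaleNormalize <- function(ip, ctrl, trim = 0.02) {
  stopifnot(is(ip, "AnchorProfile"), is(ctrl, "AnchorProfile"))
  if (length(ip@counts) != length(ctrl@counts))
    stop("profiles are on genomes of different length")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  mIp <- .trimmedMean(ip@counts, trim)
  mCtrl <- .trimmedMean(ctrl@counts, trim)
  if (mIp == 0)
    stop("trimmed mean of the IP profile is zero (degenerate library)")
  f <- mCtrl / mIp
  ip@counts <- ip@counts * f
  list(ip = ip, ctrl = ctrl,
       scaling = new("ScalingResult", trim = trim, ipTrimmedMean = mIp,
                     ctrlTrimmedMean = mCtrl, factor = f))
}

.windowSums <- function(x, w, circular) {
  n <- length(x)
  if (w < 1 || w > n) stop("window must be in [1, genome length]")
  if (w == 1) return(as.numeric(x))
  left <- (w - 1L) %/% 2L          # centred window; even w: extra base right
  right <- w - 1L - left
  pad <- if (circular) {
    c(x[(n - left + 1L):n], x, x[seq_len(right)])
  } else {
    c(numeric(left), x, numeric(right))
  }
  cs <- cumsum(c(0, pad))
  cs[seq_len(n) + w] - cs[seq_len(n)]
}

#' Running-window read counts
#'
#' Value at position p = sum of per-position counts over the w-length
#' window centred at p. Circular genomes wrap; linear genomes truncate at
#' the ends. Window mass is conserved on a circular genome:
#' sum(track) = w * sum(profile).
#'
#' @param profile an [AnchorProfile-class] (or numeric vector).
#' @param w window width in bp; the published analysis used 25, 35 or 75,
#'   selecting 35.
#' @return A [CoverageTrack-class].
#' @export
windowCounts <- function(profile, w = 35) {
  w <- as.integer(w)
  if (is.numeric(profile)) {
    return(new("CoverageTrack", genomeId = "genome",
               values = .windowSums(profile, w, circular = TRUE),
               window = w, circular = TRUE))
  }
  stopifnot(is(profile, "AnchorProfile"))
  new("CoverageTrack", genomeId = profile@genomeId,
      values = .windowSums(profile@counts, w, profile@circular),
      window = w, circular = profile@circular)
}

#' Enrichment-ratio track
#'
#' R(p) = (IP window count + pseudocount) / (control window count +
#' pseudocount). The pseudocount (default 1) guards against empty control
#' windows in coverage gaps; with `pseudocount = 0` a zero control window
#' is an error.
#'
#' @param ipTrack,ctrlTrack [CoverageTrack-class] objects with the same
#'   window on the same genome (IP scaled beforehand).
#' @param pseudocount non-negative real added to both window counts.
#' @param experiment experiment identifier recorded on the track.
#' @return A [RatioTrack-class].
#' @export
ratioTrack <- function(ipTrack, ctrlTrack, pseudocount = 1,
                       experiment = "1") {
  stopifnot(is(ipTrack, "CoverageTrack"), is(ctrlTrack, "CoverageTrack"))
  if (length(ipTrack@values) != length(ctrlTrack@values))
    stop("tracks are on genomes of different length")
  if (ipTrack@window != ctrlTrack@window)
    stop("tracks were computed with different windows")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(ctrlTrack@values == 0))
    stop("zero control window count with zero pseudocount")
  new("RatioTrack", genomeId = ipTrack@genomeId,
      values = (ipTrack@values + pseudocount) /
               (ctrlTrack@values + pseudocount),
      window = ipTrack@window, pseudocount = pseudocount,
      experiment = experiment, circular = ipTrack@circular)
}

#' Bin totals of a profile or interval set
#'
#' For a count profile, sums the per-position counts within consecutive
#' `bin`-bp bins. For a `GRanges`, accumulates covered base pairs per bin,
#' splitting intervals that straddle a bin boundary proportionally, so
#' total mass is conserved. With `percent = TRUE` values are expressed as
#' percentage of the grand total (summing to 100).
#'
#' @param x an [AnchorProfile-class], numeric vector, or `GRanges`.
#' @param bin bin width in bp (100,000 for chromosome-scale profiles,
#'   100 for correlation plots).
#' @param percent report percentages of the total instead of totals.
#' @param G genome length; required for `GRanges` input without seqlengths.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive bin
#'   bounds) and `total` (and `percent` if requested).
#' @export
binCounts <- function(x, bin = 1e5, percent = FALSE, G = NULL) {
  bin <- as.integer(bin)
  if (bin < 1L) stop("bin must be >= 1")
  if (is(x, "AnchorProfile")) x <- x@counts
  if (is(x, "CoverageTrack") || is(x, "RatioTrack")) x <- x@values
  if (is.numeric(x)) {
    G <- length(x)
    idx <- ((seq_len(G) - 1L) %/% bin) + 1L
    tot <- as.numeric(tapply(x, idx, sum))
  } else if (is(x, "GRanges")) {
    if (is.null(G)) {
      sl <- GenomeInfoDb::seqlengths(x)
      if (length(sl) == 1L && !is.na(sl[1L])) G <- as.integer(sl[1L])
      else stop("supply G for GRanges input")
    }
    nb <- as.integer(ceiling(G / bin))
    tot <- numeric(nb)
    if (length(x)) {
      chr <- as.character(GenomeInfoDb::seqnames(x))[1L]
      tiles <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(start = (seq_len(nb) - 1L) * bin + 1L,
                              end = pmin(seq_len(nb) * bin, G)))
      suppressWarnings({
        ov <- GenomicRanges::findOverlaps(tiles, x)
        pw <- GenomicRanges::width(GenomicRanges::pintersect(
          tiles[S4Vectors::queryHits(ov)], x[S4Vectors::subjectHits(ov)]))
      })
      agg <- tapply(pw, S4Vectors::queryHits(ov), sum)
      tot[as.integer(names(agg))] <- as.numeric(agg)
    }
  } else stop("unsupported input type for binCounts()")
  nb <- length(tot)
  out <- data.frame(start = (seq_len(nb) - 1L) * bin + 1L,
                    end = pmin(seq_len(nb) * bin, G),
                    total = tot)
  if (percent) {
    s <- sum(tot)
    if (s == 0) stop("cannot express empty input as percentages")
    out$percent <- 100 * tot / s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
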