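#' Peak-calling parameters
#'
#' Constructor with the published defaults; see [PeakCallParams-class].
#'
#' @param rMin,minFrac,minLen,mergeGap,mergeMaxR,urMaxR,window see
#'   [PeakCallParams-class].
#' @return A validated [PeakCallParams-class].
#' @export
peakParams <- function(rMin = 1.5, minFrac = 0.5, minLen = 60,
                       mergeGap = 30, mergeMaxR = 1.1, urMaxR = 1.0,
                       window = 35) {
  new("PeakCallParams", rMin = rMin, minFrac = minFrac,
      minLen = as.integer(minLen), mergeGap = as.integer(mergeGap),
      mergeMaxR = mergeMaxR, urMaxR = urMaxR, window = as.integer(window))
}

.grFromMatrix <- function(m, genomeId, provenance) {
  gr <- if (nrow(m) == 0L) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(
      genomeId, IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]))
  S4Vectors::metadata(gr)$provenance <- provenance
  gr
}

# Rotate a per-position vector so that `cut` (1-based) becomes the last
# element; returns the rotated vector and a function mapping rotated 0-based
# starts back to original 1-based positions.
.rotate <- function(x, cut) {
  n <- length(x)
  if (cut == n) return(list(x = x, back = function(p0) p0 + 1L))
  rot <- c(x[(cut + 1L):n], x[seq_len(cut)])
  list(x = rot, back = function(p0) ((p0 + cut) %% n) + 1L)
}

# Convert rotated 0-based half-open intervals to original coordinates,
# splitting any interval that spans the origin.
.unrotateIntervals <- function(m, back, n) {
  if (nrow(m) == 0L)
    return(matrix(integer(), ncol = 2L))
  out <- matrix(integer(), nrow = 0L, ncol = 2L)
  for (q in seq_len(nrow(m))) {
    s1 <- back(m[q, 1L])            # original 1-based start
    len <- m[q, 2L] - m[q, 1L]
    e1 <- s1 + len - 1L
    if (e1 <= n) {
      out <- rbind(out, c(s1 - 1L, e1))
    } else {                        # wraps the origin: split
      out <- rbind(out, c(s1 - 1L, n), c(0L, e1 - n))
    }
  }
  out[order(out[, 1L]), , drop = FALSE]
}

#' Call occupancy peaks from an R track
#'
#' Emits, deterministically, non-overlapping regions in which R >=
#' `rMin` at >= `minFrac` of positions over >= `minLen` bp, with
#' above-threshold first and last positions. Scanning left to right, the
#' longest such interval starting at the first uncovered above-threshold
#' position is emitted, then scanning continues past its end. On a circular
#' genome the track is cut at the global R minimum (an interval spanning
#' the origin is reported as its two arcs); a track with R >= `rMin`
#' everywhere yields one genome-spanning peak.
#'
#' @param rt a [RatioTrack-class].
#' @param params a [PeakCallParams-class].
#' @param merge also apply [mergeRegions()] to the called peaks (the merge
#'   rule primarily targets unbound regions; off by default).
#' @return A `GRanges` of peaks with metadata columns `maxR` and
#'   `fracAbove`.
#' @seealso [verifyPeaks()] for the position-wise self-check.
#' @export
callPeaks <- function(rt, params = peakParams(), merge = FALSE) {
  stopifnot(is(rt, "RatioTrack"), is(params, "PeakCallParams"))
  r <- rt@values
  n <- length(r)
  if (rt@circular && min(r) >= params@rMin) {
    gr <- GenomicRanges::GRanges(rt@genomeId,
                                 IRanges::IRanges(start = 1L, end = n))
  } else {
    if (rt@circular) {
      rot <- .rotate(r, which.min(r))
      m <- .call_peaks_cpp(rot$x, params@rMin, params@minFrac,
                           params@minLen)
      m <- .unrotateIntervals(m, rot$back, n)
    } else {
      m <- .call_peaks_cpp(r, params@rMin, params@minFrac, params@minLen)
    }
    gr <- .grFromMatrix(m, rt@genomeId, "peaks")
  }
  if (merge) gr <- mergeRegions(gr, rt, params@mergeGap, params@mergeMaxR)
  gr <- .annotatePeakStats(gr, r, params)
  S4Vectors::metadata(gr)$provenance <- paste0("peaks-exp", rt@experiment)
  gr
}

.annotatePeakStats <- function(gr, r, params) {
  if (!length(gr)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(maxR = numeric(),
                                                 fracAbove = numeric())
    return(gr)
  }
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  S4Vectors::mcols(gr)$maxR <- vapply(seq_along(gr), function(k)
    max(r[st[k]:en[k]]), numeric(1))
  S4Vectors::mcols(gr)$fracAbove <- vapply(seq_along(gr), function(k)
    mean(r[st[k]:en[k]] >= params@rMin), numeric(1))
  gr
}

#' Position-wise self-check of called peaks
#'
#' Re-evaluates the peak predicate (length, above-threshold fraction,
#' above-threshold ends) for each interval directly on the R values.
#' Origin-split arcs of a wrapped peak are validated jointly.
#'
#' @param gr peaks from [callPeaks()].
#' @param rt the [RatioTrack-class] they were called from.
#' @param params the [PeakCallParams-class] used.
#' @return Logical: `TRUE` when every peak satisfies the predicate.
#' @export
verifyPeaks <- function(gr, rt, params = peakParams()) {
  r <- rt@values
  n <- length(r)
  if (!length(gr)) return(TRUE)
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  # stitch origin-split arcs back together
  segs <- lapply(seq_along(gr), function(k) r[st[k]:en[k]])
  if (length(gr) >= 2L && st[1L] == 1L && en[length(gr)] == n &&
      min(r) < params@rMin) {
    segs[[1L]] <- c(segs[[length(segs)]], segs[[1L]])
    segs[[length(segs)]] <- NULL
  }
  all(vapply(segs, function(v) {
    length(v) >= params@minLen &&
      mean(v >= params@rMin) >= params@minFrac - 1e-9 &&
      v[1L] >= params@rMin && v[length(v)] >= params@rMin
  }, logical(1)))
}

.runsToMatrix <- function(ok, minLen) {
  rl <- rle(ok)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values & rl$lengths >= minLen
  cbind(starts[keep] - 1L, ends[keep])  # 0-based half-open
}

#' Call unbound regions from two replicate R tracks
#'
#' Maximal regions of >= `minLen` bp in which R < `urMaxR` at every
#' position in both experiments, merged under the gap rule (< `mergeGap` bp
#' apart with every intermediate position <= `mergeMaxR` in both tracks),
#' minus every region overlapping (by >= 1 bp) any supplied exclusion set
#' (e.g. an external peak catalog).
#'
#' @param rt1,rt2 [RatioTrack-class] objects for the two experiments.
#' @param exclusions a `GRanges` or list of `GRanges` of regions that must
#'   not intersect unbound regions.
#' @param params a [PeakCallParams-class].
#' @param merge apply the gap-merge rule (default `TRUE`).
#' @return A `GRanges` of unbound regions.
#' @export
callUnbound <- function(rt1, rt2, exclusions = list(),
                        params = peakParams(), merge = TRUE) {
  stopifnot(is(rt1, "RatioTrack"), is(rt2, "RatioTrack"))
  if (length(rt1@values) != length(rt2@values))
    stop("tracks are on genomes of different length")
  r <- pmax(rt1@values, rt2@values)
  ok <- r < params@urMaxR
  n <- length(ok)
  if (rt1@circular && all(ok)) {
    gr <- GenomicRanges::GRanges(rt1@genomeId,
                                 IRanges::IRanges(start = 1L, end = n))
  } else {
    if (rt1@circular) {
      cut <- which(!ok)[1L]
      rotOk <- .rotate(ok, cut)
      m <- .runsToMatrix(rotOk$x, params@minLen)
      m <- .unrotateIntervals(m, rotOk$back, n)
    } else {
      m <- .runsToMatrix(ok, params@minLen)
    }
    gr <- .grFromMatrix(m, rt1@genomeId, "UR")
  }
  if (merge)
    gr <- mergeRegions(gr, r, params@mergeGap, params@mergeMaxR)
  if (is(exclusions, "GRanges")) exclusions <- list(exclusions)
  for (ex in exclusions) {
    if (length(ex))
      gr <- gr[!IRanges::overlapsAny(IRanges::ranges(gr),
                                     IRanges::ranges(ex))]
  }
  S4Vectors::metadata(gr)$provenance <- "UR"
  gr
}

#' Merge nearby regions across low-signal gaps
#'
#' Adjacent regions separated by fewer than `maxGap` bp are combined when
#' every intermediate position has R <= `maxIntermediate`; applied
#' iteratively to a fixed point.
#'
#' @param s a sorted `GRanges`.
#' @param rt a [RatioTrack-class] (or numeric R vector) supplying the
#'   intermediate values.
#' @param maxGap gap threshold in bp (strict: a gap of exactly `maxGap` is
#'   not merged).
#' @param maxIntermediate inclusive ceiling on intermediate R values.
#' @return The merged `GRanges`.
#' @export
mergeRegions <- function(s, rt, maxGap = 30, maxIntermediate = 1.1) {
  r <- if (is(rt, "RatioTrack")) rt@values else rt
  if (length(s) < 2L) return(s)
  s <- GenomicRanges::sort(s)
  repeat {
    st <- GenomicRanges::start(s); en <- GenomicRanges::end(s)
    merged <- FALSE
    newSt <- integer(); newEn <- integer()
    curSt <- st[1L]; curEn <- en[1L]
    for (k in seq_len(length(s) - 1L)) {
      gap <- st[k + 1L] - curEn - 1L   # intermediate positions
      ok <- gap < maxGap &&
        (gap == 0L || all(r[(curEn + 1L):(st[k + 1L] - 1L)] <=
                            maxIntermediate + 1e-12))
      if (ok) {
        curEn <- max(curEn, en[k + 1L])
        merged <- TRUE
      } else {
        newSt <- c(newSt, curSt); newEn <- c(newEn, curEn)
        curSt <- st[k + 1L]; curEn <- en[k + 1L]
      }
    }
    newSt <- c(newSt, curSt); newEn <- c(newEn, curEn)
    s <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(s))[1L],
      IRanges::IRanges(start = newSt, end = newEn))
    if (!merged) break
  }
  s
}

#' Combine two replicate experiments into the supported bound set
#'
#' The combined set (CS) starts from the peaks of the deeper-replicate
#' experiment; every peak overlapping (by >= 1 bp) a region unbound in the
#' other experiment is removed whole (no clipping). The alternative
#' `"peak-support"` mode instead retains only peaks overlapping a peak of
#' the other experiment.
#'
#' @param peaks2 `GRanges` of peaks from the experiment that defines the
#'   candidate set.
#' @param unbound1 `GRanges` of unbound regions from the other experiment
#'   (used by the default mode).
#' @param mode `"unbound-overlap"` (default) or `"peak-support"`.
#' @param peaks1 `GRanges` of the other experiment's peaks (used by
#'   `"peak-support"`).
#' @return The combined-set `GRanges`.
#' @export
combineExperiments <- function(peaks2, unbound1 = NULL,
                               mode = c("unbound-overlap", "peak-support"),
                               peaks1 = NULL) {
  mode <- match.arg(mode)
  if (mode == "unbound-overlap") {
    if (is.null(unbound1)) stop("unbound1 is required for this mode")
    cs <- if (length(unbound1))
      peaks2[!IRanges::overlapsAny(IRanges::ranges(peaks2),
                                   IRanges::ranges(unbound1))]
    else peaks2
  } else {
    if (is.null(peaks1)) stop("peaks1 is required for peak-support mode")
    cs <- peaks2[IRanges::overlapsAny(IRanges::ranges(peaks2),
                                      IRanges::ranges(peaks1))]
  }
  S4Vectors::metadata(cs)$provenance <- "CS"
  cs
}
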