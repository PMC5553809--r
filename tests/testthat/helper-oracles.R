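# Independent brute-force oracles. These deliberately avoid the package's
# C++ paths: string slicing, exhaustive interval enumeration and indicator
# vectors only.

randomGenome <- function(G, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), G, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# quadruple-loop repeat scan: (i, j) x position with substring comparison
bruteRepeatScan <- function(g, type, iRange, jRange, circular = FALSE) {
  G <- nchar(g)
  s <- if (circular) paste0(g, g) else g
  out <- list()
  for (i in iRange) for (j in jRange) {
    span <- 2L * i + j
    if (span > G) next
    nstart <- if (circular) G else G - span + 1L
    if (nstart < 1L) next
    p <- seq_len(nstart)
    arm1 <- substring(s, p, p + i - 1L)
    arm2 <- substring(s, p + i + j, p + 2L * i + j - 1L)
    hit <- if (type == "direct") arm1 == arm2 else
      arm2 == revcompStr(arm1)
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = j,
                                            start = p[hit])
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), start = integer()))
  do.call(rbind, out)
}

sortPairs <- function(df) {
  df <- df[order(df$i, df$j, df$start), c("i", "j", "start")]
  rownames(df) <- NULL
  df
}

# exhaustive qualifying-interval enumeration + left-to-right longest
# selection (linear track, 1-based starts/ends)
brutePeaks <- function(r, rMin = 1.5, minFrac = 0.5, minLen = 60) {
  n <- length(r)
  above <- r >= rMin - 1e-9
  cand <- NULL
  for (a in which(above)) {
    cs <- cumsum(above[a:n])
    len <- seq_len(n - a + 1L)
    ok <- above[a:n] & (cs >= minFrac * len - 1e-9) & len >= minLen
    bs <- which(ok) + a - 1L
    if (length(bs)) cand <- rbind(cand, cbind(a = a, b = bs))
  }
  peaks <- NULL
  pos <- 1L
  while (TRUE) {
    nexta <- which(above & seq_len(n) >= pos)
    if (!length(nexta)) break
    a0 <- nexta[1L]
    rows <- cand[cand[, "a"] == a0, , drop = FALSE]
    if (is.null(cand) || !nrow(rows)) {
      pos <- a0 + 1L
      next
    }
    b <- max(rows[, "b"])
    peaks <- rbind(peaks, c(a0, b))
    pos <- b + 1L
  }
  if (is.null(peaks)) matrix(integer(), ncol = 2L) else peaks
}

# position-wise unbound evaluation (linear, no merging)
bruteUnbound <- function(r1, r2, urMax = 1.0, minLen = 60) {
  ok <- r1 < urMax & r2 < urMax
  idx <- which(ok)
  if (!length(idx)) return(matrix(integer(), ncol = 2L))
  grp <- cumsum(c(1L, diff(idx) != 1L))
  out <- t(vapply(split(idx, grp), function(v) c(min(v), max(v)),
                  integer(2)))
  out[out[, 2L] - out[, 1L] + 1L >= minLen, , drop = FALSE]
}

# sort-and-slice trimmed mean (mirrors microarray scaling arithmetic)
sortSliceTrimmedMean <- function(x, trim) {
  n <- length(x)
  k <- floor(n * trim)
  s <- sort(x)
  mean(s[(k + 1L):(n - k)])
}

# indicator-vector base-pair overlap
indicatorOverlap <- function(starts, ends, tStarts, tEnds, G,
                             multiplicity = TRUE) {
  tv <- logical(G)
  for (q in seq_along(tStarts)) tv[tStarts[q]:tEnds[q]] <- TRUE
  per <- vapply(seq_along(starts), function(q)
    sum(tv[starts[q]:ends[q]]), numeric(1))
  if (multiplicity) sum(per) else {
    ev <- logical(G)
    for (q in seq_along(starts)) ev[starts[q]:ends[q]] <- TRUE
    sum(ev & tv)
  }
}

makeLib <- function(seqs, quals = NULL, label = "control",
                    experiment = "1") {
  new("ReadLibrary",
      sequences = Biostrings::DNAStringSet(seqs),
      qualities = if (is.null(quals)) Biostrings::BStringSet() else
        Biostrings::BStringSet(quals),
      label = label, experiment = experiment)
}

# linear (non-circular) ratio track wrapper for toy vectors
toyTrack <- function(r, window = 35L, experiment = "1",
                     circular = FALSE) {
  new("RatioTrack", genomeId = "toy", values = as.numeric(r),
      window = as.integer(window), pseudocount = 1,
      experiment = experiment, circular = circular)
}

grIv <- function(starts, ends, id = "toy") {
  GenomicRanges::GRanges(id, IRanges::IRanges(start = starts, end = ends))
}

# shared simulation for calibration-style tests: returns the ratio track,
# called peaks and truth for a given spec
simulatePipeline <- function(spec, window = 75L,
                             params = peakParams(window = window)) {
  g <- makeGenome(spec)
  sim <- simulateReads(g$genome, g$truth, spec)
  idx <- buildIndex(g$genome, spec@readLength, TRUE, "synthetic")
  pIp <- anchorReads(sim$ip, idx)
  pCtrl <- anchorReads(sim$control, idx)
  sc <- scaleNormalize(pIp, pCtrl)
  rt <- ratioTrack(windowCounts(sc$ip, window),
                   windowCounts(sc$ctrl, window))
  peaks <- callPeaks(rt, params)
  list(track = rt, peaks = peaks, truth = g$truth, genome = g$genome)
}
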