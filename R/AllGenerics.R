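#' @importFrom BiocGenerics counts
NULL

#' Accessors
#'
#' `counts()` returns the per-position count vector of an
#' [AnchorProfile-class]; `trackValues()` the value vector of a
#' [CoverageTrack-class] or [RatioTrack-class]; `anchorStats()` the anchoring
#' tallies; `repeatPairs()` the pair table of a [RepeatCatalog-class];
#' `genomeLength()` the genome length of an object that carries one.
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackValues", function(object) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("anchorStats", function(object) standardGeneric("anchorStats"))

#' @rdname accessors
#' @export
setGeneric("repeatPairs", function(object) standardGeneric("repeatPairs"))

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(object) standardGeneric("genomeLength"))

#' @rdname accessors
#' @export
setMethod("counts", "AnchorProfile", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("trackValues", "CoverageTrack", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("trackValues", "RatioTrack", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("anchorStats", "AnchorProfile", function(object) {
  c(anchored = object@nAnchored, unanchored = object@nUnanchored,
    multi = object@nMulti)
})

#' @rdname accessors
#' @export
setMethod("repeatPairs", "RepeatCatalog", function(object) object@pairs)

#' @rdname accessors
#' @export
setMethod("genomeLength", "AnchorProfile",
          function(object) length(object@counts))

#' @rdname accessors
#' @export
setMethod("genomeLength", "CoverageTrack",
          function(object) length(object@values))

#' @rdname accessors
#' @export
setMethod("genomeLength", "RatioTrack",
          function(object) length(object@values))

#' @rdname accessors
#' @export
setMethod("genomeLength", "RepeatCatalog",
          function(object) object@genomeLength)

#' @rdname accessors
#' @export
setMethod("genomeLength", "SyntheticSpec",
          function(object) object@genomeLength)

setMethod("length", "ReadLibrary", function(x) length(x@sequences))

setMethod("[", "ReadLibrary", function(x, i, j, ..., drop = TRUE) {
  qual <- if (length(x@qualities)) x@qualities[i] else x@qualities
  new("ReadLibrary", sequences = x@sequences[i], qualities = qual,
      label = x@label, experiment = x@experiment)
})

setMethod("show", "ReadLibrary", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("ReadLibrary (", object@label, ", experiment ", object@experiment,
      "): ", length(object), " reads",
      if (length(w)) paste0(", widths ", min(w), "-", max(w)) else "",
      if (length(object@qualities)) ", with qualities" else ", no qualities",
      "\n", sep = "")
})

setMethod("show", "AnchorProfile", function(object) {
  cat("AnchorProfile on ", object@genomeId, " (", length(object@counts),
      " bp, ", if (object@circular) "circular" else "linear", ")\n",
      "  policy: ", object@policy, "; read length ", object@readLength, "\n",
      "  anchored ", object@nAnchored, ", unanchored ", object@nUnanchored,
      ", multi-locus ", object@nMulti, "\n", sep = "")
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack on ", object@genomeId, " (", length(object@values),
      " bp): window ", object@window, " bp, mean ",
      signif(mean(object@values), 4), "\n", sep = "")
})

setMethod("show", "RatioTrack", function(object) {
  cat("RatioTrack on ", object@genomeId, " (", length(object@values),
      " bp): window ", object@window, " bp, pseudocount ",
      object@pseudocount, "\n  R range ",
      signif(min(object@values), 4), "-", signif(max(object@values), 4),
      ", mean ", signif(mean(object@values), 4), "\n", sep = "")
})

setMethod("show", "ScalingResult", function(object) {
  cat("ScalingResult: trim ", object@trim, "; trimmed means IP ",
      signif(object@ipTrimmedMean, 6), ", control ",
      signif(object@ctrlTrimmedMean, 6), "; factor ",
      signif(object@factor, 6), "\n", sep = "")
})

setMethod("show", "PeakCallParams", function(object) {
  cat("PeakCallParams: R >= ", object@rMin, " at >= ",
      100 * object@minFrac, "% of >= ", object@minLen,
      " bp; unbound R < ", object@urMaxR, "; merge gap < ",
      object@mergeGap, " bp with R <= ", object@mergeMaxR,
      "; window ", object@window, " bp\n", sep = "")
})

setMethod("show", "RepeatCatalog", function(object) {
  cat("RepeatCatalog: ", nrow(object@pairs), " ", object@type,
      " repeat pairs on ", object@genomeId, " (", object@genomeLength,
      " bp, maximality ", object@maximality, ")\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult [", object@convention, "]: ", object@label,
      " vs ", object@target, "\n  observed ", object@observed,
      " bp, expected ", signif(object@expected, 6), " bp, K = ",
      signif(object@k, 4), "\n", sep = "")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec: ", object@genomeLength, " bp genome (GC ",
      object@gcFraction, "), ", nrow(object@plantedSites),
      " planted sites, ", nrow(object@plantedRepeats),
      " planted repeat pairs\n  reads: ", object@nControl, " control + ",
      object@nIp, " IP x ", object@readLength, " nt, fragments ",
      object@fragmentMin, "-", object@fragmentMax, " bp, seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet: ", length(object@sites), " planted sites, ",
      length(object@repeats), " planted repeat footprints\n", sep = "")
})
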