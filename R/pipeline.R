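.configDefaults <- function() {
  list(
    genome = NULL,            # path to FASTA, DNAString, or SyntheticSpec
    experiments = NULL,       # list of list(control=, ip=) paths/libraries
    circular = TRUE,
    qMin = 20,
    filterQuality = TRUE,
    targetLength = 50L,
    policy = "all-occurrences",
    trim = 0.02,
    window = 35L,
    pseudocount = 1,
    rMin = 1.5,
    minFrac = 0.5,
    minLen = 60L,
    mergeGap = 30L,
    mergeMaxR = 1.1,
    urMaxR = 1.0,
    repeatType = "inverted",
    iRange = NULL,
    jRange = NULL,
    maximality = "none",
    convention = "multiplicity",
    exclusions = list(),      # BED paths or GRanges
    outDir = NULL,
    seed = 1L
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Unknown keys are rejected; every threshold is echoed verbatim into the
#' run manifest. See [runPipeline()] for the fields.
#'
#' @param ... configuration fields overriding the defaults.
#' @return A validated configuration (classed list).
#' @export
pipelineConfig <- function(...) {
  cfg <- .configDefaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  # invariant enforcement happens here, before any stage runs
  peakParams(cfg$rMin, cfg$minFrac, cfg$minLen, cfg$mergeGap,
             cfg$mergeMaxR, cfg$urMaxR, cfg$window)
  if (!cfg$policy %in% c("all-occurrences", "unique-only"))
    stop("unknown anchoring policy: ", cfg$policy)
  if (!cfg$convention %in% c("multiplicity", "union"))
    stop("unknown overlap convention: ", cfg$convention)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML path; keys as in [pipelineConfig()].
#' @return A validated configuration.
#' @export
readPipelineConfig <- function(file) {
  do.call(pipelineConfig, yaml::read_yaml(file))
}

.stageMsg <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

.loadLibrary <- function(x, label, experiment) {
  if (is(x, "ReadLibrary")) return(x)
  readFastqLibrary(x, label = label, experiment = experiment)
}

.processExperiment <- function(genome, index, lib, cfg, expId) {
  t0 <- as.numeric(Sys.time())
  ctrl <- .loadLibrary(lib$control, "control", expId)
  ip <- .loadLibrary(lib$ip, "ip", expId)
  if (cfg$filterQuality) {
    ctrl <- suppressMessages(qualityFilter(ctrl, cfg$qMin))
    ip <- suppressMessages(qualityFilter(ip, cfg$qMin))
  }
  ctrl <- trimToCenter(ctrl, cfg$targetLength)
  ip <- trimToCenter(ip, cfg$targetLength)
  .stageMsg(paste0("read_prep/exp", expId), t0)

  t0 <- as.numeric(Sys.time())
  pCtrl <- anchorReads(ctrl, index, cfg$policy)
  pIp <- anchorReads(ip, index, cfg$policy)
  .stageMsg(paste0("anchor_map/exp", expId), t0)

  t0 <- as.numeric(Sys.time())
  sc <- scaleNormalize(pIp, pCtrl, cfg$trim)
  wIp <- windowCounts(sc$ip, cfg$window)
  wCtrl <- windowCounts(sc$ctrl, cfg$window)
  rt <- ratioTrack(wIp, wCtrl, cfg$pseudocount, experiment = expId)
  .stageMsg(paste0("tracks/exp", expId), t0)

  list(control = pCtrl, ip = pIp, scaling = sc$scaling, ratio = rt)
}

#' Run the occupancy pipeline end to end
#'
#' Executes read preparation, anchoring, normalization and tracks, peak and
#' unbound-region calling, repeat scanning and overlap enrichment for one
#' or two experiments, writing BED/bedGraph/TSV outputs plus a
#' machine-readable run manifest when `outDir` is set. With two
#' experiments the combined set (CS) is formed from the experiment-2 peaks
#' minus those overlapping experiment-1 unbound regions, and unbound
#' regions require R < `urMaxR` in both experiments. When `genome` is a
#' [SyntheticSpec-class] the genome and libraries are simulated first and
#' a truth-versus-peaks recall report is produced.
#'
#' @param cfg a configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return A result bundle (list) with the per-experiment profiles and
#'   tracks, called intervals, repeat catalog, enrichment table, and the
#'   manifest.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  t0 <- as.numeric(Sys.time())
  truth <- NULL
  if (is(cfg$genome, "SyntheticSpec")) {
    spec <- cfg$genome
    g <- makeGenome(spec)
    genome <- g$genome
    truth <- g$truth
    sim <- simulateReads(genome, truth, spec)
    cfg$experiments <- list(list(control = sim$control, ip = sim$ip))
    genomeId <- "synthetic"
    .stageMsg("synthetic_data", t0)
  } else if (is.character(cfg$genome)) {
    genome <- readGenomeFasta(cfg$genome)
    genomeId <- attr(genome, "genomeId")
  } else {
    genome <- cfg$genome
    genomeId <- "genome"
  }
  if (is.null(cfg$experiments) || !length(cfg$experiments))
    stop("stage read_prep: no experiments configured")

  index <- buildIndex(genome, cfg$targetLength, cfg$circular, genomeId)
  G <- nchar(index@genome)
  params <- peakParams(cfg$rMin, cfg$minFrac, cfg$minLen, cfg$mergeGap,
                       cfg$mergeMaxR, cfg$urMaxR, cfg$window)

  exps <- lapply(seq_along(cfg$experiments), function(k)
    .processExperiment(genome, index, cfg$experiments[[k]], cfg,
                       as.character(k)))

  t0 <- as.numeric(Sys.time())
  peaks <- lapply(exps, function(e) callPeaks(e$ratio, params))
  exclusions <- lapply(cfg$exclusions, function(x)
    if (is.character(x)) readIntervalsBed(x) else x)
  if (length(exps) == 2L) {
    ur <- callUnbound(exps[[1L]]$ratio, exps[[2L]]$ratio, exclusions,
                      params)
    ur1 <- callUnbound(exps[[1L]]$ratio, exps[[1L]]$ratio, exclusions,
                       params)
    cs <- combineExperiments(peaks[[2L]], ur1)
  } else {
    ur <- callUnbound(exps[[1L]]$ratio, exps[[1L]]$ratio, exclusions,
                      params)
    cs <- peaks[[1L]]
    S4Vectors::metadata(cs)$provenance <- "CS"
  }
  .stageMsg("peaks", t0)

  t0 <- as.numeric(Sys.time())
  cat <- scanRepeats(genome, cfg$repeatType, cfg$iRange, cfg$jRange,
                     cfg$circular, cfg$maximality, genomeId)
  .stageMsg("repeats", t0)

  t0 <- as.numeric(Sys.time())
  enr <- repeatEnrichment(cat, cs, cfg$convention)
  .stageMsg("enrichment", t0)

  recall <- NULL
  if (!is.null(truth) && length(truth@sites)) {
    mid <- (GenomicRanges::start(truth@sites) +
              GenomicRanges::end(truth@sites)) %/% 2L
    hit <- vapply(mid, function(m) any(
      GenomicRanges::start(cs) <= m & GenomicRanges::end(cs) >= m),
      logical(1))
    recall <- data.frame(site = seq_along(mid), midpoint = mid,
                         recovered = hit)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("ChIPratio")),
    genomeId = genomeId, genomeLength = G,
    parameters = cfg[setdiff(names(cfg), c("genome", "experiments",
                                           "exclusions"))],
    stages = c("read_prep", "anchor_map", "tracks", "peaks", "repeats",
               "enrichment"),
    nExperiments = length(exps),
    anchorStats = lapply(exps, function(e)
      list(control = as.list(anchorStats(e$control)),
           ip = as.list(anchorStats(e$ip)))),
    scalingFactors = vapply(exps, function(e) e$scaling@factor,
                            numeric(1)),
    nPeaks = vapply(peaks, length, integer(1)),
    nUnbound = length(ur), nCombined = length(cs),
    recallRecovered = if (!is.null(recall)) sum(recall$recovered) else NA,
    recallTotal = if (!is.null(recall)) nrow(recall) else NA
  )

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(exps)) {
      writeTrackBedGraph(exps[[k]]$ratio,
                         file.path(cfg$outDir,
                                   sprintf("ratio_exp%d.bedGraph", k)))
      writeIntervalsBed(peaks[[k]],
                        file.path(cfg$outDir,
                                  sprintf("peaks_exp%d.bed", k)), G)
    }
    writeIntervalsBed(ur, file.path(cfg$outDir, "unbound.bed"), G)
    writeIntervalsBed(cs, file.path(cfg$outDir, "combined_set.bed"), G)
    utils::write.table(cat@pairs,
                       file.path(cfg$outDir, "repeat_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(cfg$outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) writeTruth(truth, cfg$outDir, G)
    if (!is.null(recall))
      utils::write.table(recall, file.path(cfg$outDir, "recall.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    beds <- list.files(cfg$outDir, pattern = "\\.(bed|bedGraph|tsv)$",
                       full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(beds))
    jsonlite::write_json(manifest,
                         file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }

  list(experiments = exps, peaks = peaks, unbound = ur, combined = cs,
       repeats = cat, enrichment = enr, recall = recall,
       manifest = manifest, truth = truth)
}
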