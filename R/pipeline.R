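#' Robustly expressed genes from an FPKM table
#'
#' @param expr `data.frame` with a gene column and FPKM columns.
#' @param minFpkm FPKM floor (default 9.5, the threshold used to call a
#'   gene robustly expressed).
#' @param fpkmCol name of the FPKM column (default `"fpkmA"`).
#' @param geneCol name of the gene column (default `"gene"`).
#' @return Character vector of gene identifiers.
#' @export
expressedGenes <- function(expr, minFpkm = 9.5, fpkmCol = "fpkmA",
                           geneCol = "gene") {
  expr[[geneCol]][expr[[fpkmCol]] > minFpkm]
}

#' Genes changing expression between two conditions
#'
#' Fold-change filter on an FPKM table: at least `fold`-fold change in
#' either direction (3-fold is the conventional cutoff for comparison with
#' regions changing turnover, 4-fold for accessibility analyses), with a
#' small pseudocount guarding against zero FPKM.
#'
#' @param expr `data.frame` with gene and FPKM columns.
#' @param fold minimum fold change (default 3).
#' @param colA,colB FPKM column names for the two conditions.
#' @param geneCol gene column name.
#' @param pseudo pseudocount added to both FPKM values (default 0.1).
#' @return Character vector of gene identifiers.
#' @export
changingGenes <- function(expr, fold = 3, colA = "fpkmA", colB = "fpkmB",
                          geneCol = "gene", pseudo = 0.1) {
  fc <- (expr[[colA]] + pseudo) / (expr[[colB]] + pseudo)
  expr[[geneCol]][fc >= fold | fc <= 1 / fold]
}

.defaultThresholds <- function() {
  list(nTop = 1000L, q = 0.025, pMax = 0.01, alpha = 1e-5, zThreshold = 7,
       distanceBp = 50000L, foldChange = 3, foldChangeMacc = 4,
       fpkmFloor = 9.5, windowBins = 3L)
}

.validateConfig <- function(config) {
  if (is.null(config$binSize)) config$binSize <- 1000L
  if (is.null(config$timepoints)) config$timepoints <- c(0, 3, 6, 12)
  if (is.null(config$seed)) config$seed <- 1L
  tp <- config$timepoints
  if (is.unsorted(tp, strictly = TRUE) || tp[1L] != 0)
    stop("config field 'timepoints' must be ascending and start at 0 hr ",
         "(a 0 hr sample is required)")
  th <- .defaultThresholds()
  th[names(config$thresholds)] <- config$thresholds
  if (any(unlist(th) <= 0)) stop("config field 'thresholds': all must be > 0")
  config$thresholds <- th
  if (is.null(config$synthetic) && is.null(config$samples))
    stop("config must provide either 'synthetic' or 'samples'")
  config
}

# condition -> list of TurnoverTracks + spike QC, from BED files on disk
.tiFromFiles <- function(cond, bins, tp, th) {
  reps <- lapply(seq_along(cond$reps), function(r) {
    paths <- cond$reps[[r]]
    if (length(paths$timepoints) != length(tp))
      stop("replicate ", r, ": config field 'timepoints' does not match ",
           "the supplied fragment files")
    input <- readFragments(paths$input, spikeInPrefix = cond$spikePrefix)
    inputTrack <- binCounts(filterAnomalousPositions(input, th$zThreshold),
                            bins, "rpm")
    fsets <- lapply(paths$timepoints, function(p)
      filterAnomalousPositions(
        readFragments(p, spikeInPrefix = cond$spikePrefix), th$zThreshold))
    trks <- lapply(fsets, function(fs)
      subtractInput(binCounts(fs, bins, "rpm"), inputTrack))
    list(ti = computeTI(TimeCourse(tp, trks, paste0("rep", r))),
         spike = spikeInScaling(fsets, tp))
  })
  list(tracks = lapply(reps, `[[`, "ti"),
       spike = lapply(reps, `[[`, "spike"))
}

#' Run the full turnover pipeline from a single config
#'
#' Orchestrates fragment input (or synthetic simulation), turnover index
#' computation per replicate, replicate averaging and concordance,
#' top-region discovery with resampling FDR, feature overrepresentation,
#' differential turnover (when a second condition is present), NB peak
#' calling (when ChIP data is present) and MACC accessibility (when a
#' titration is present). All outputs are written under `outDir` together
#' with a JSON manifest recording the seed, input hashes and per-stage
#' summaries. A single seed fans out to stable stage-specific child
#' seeds, so reruns with the same config are numerically identical.
#'
#' The config is an R list (or a path to a JSON file) with fields
#' `binSize`, `timepoints`, `seed`, `thresholds` (see details), and either
#' `synthetic` (list: `scale`, `nChroms`, `chromLen`, `depth`, `nReps`,
#' `conditionB` flag, `chip` flag, `titration` flag) or `samples` (per
#' condition: `reps` = list of `list(timepoints = paths, input = path)`,
#' `spikePrefix`), plus optional `annotations` (named BED paths),
#' `blacklist`, `chromSizes` and `expression` (TSV with gene/fpkm
#' columns). Thresholds default to `nTop = 1000`, `q = 0.025`,
#' `pMax = 0.01`, `alpha = 1e-5`, `zThreshold = 7`, `distanceBp = 50000`,
#' `foldChange = 3`, `foldChangeMacc = 4`, `fpkmFloor = 9.5`,
#' `windowBins = 3`.
#'
#' @param config R list or path to a JSON config file.
#' @param outDir output directory.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  tp <- config$timepoints
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed, binSize = config$binSize,
                   timepoints = tp, thresholds = th,
                   stages = list(), outputs = character(0))
  addOut <- function(path) manifest$outputs <<- c(manifest$outputs, path)

  annotations <- list()
  blacklist <- NULL
  exprTab <- NULL

  if (!is.null(config$synthetic)) {
    sy <- config$synthetic
    if (is.null(sy$scale)) sy$scale <- 0.2
    if (is.null(sy$nChroms)) sy$nChroms <- 2L
    if (is.null(sy$chromLen)) sy$chromLen <- 1.25e6
    if (is.null(sy$depth)) sy$depth <- 3e5
    if (is.null(sy$nReps)) sy$nReps <- 3L
    truth <- buildGenome(escLikeSpecs(sy$scale), nChroms = sy$nChroms,
                         chromLen = sy$chromLen, binSize = config$binSize,
                         seed = .childSeed(seed, "truth"))
    bins <- genomeBins(truth)
    truthPaths <- writeTruth(truth, file.path(outDir, "truth"))
    for (p in truthPaths) addOut(p)
    annotations <- as.list(truth@regions)
    exprTab <- truth@expression
    repsA <- simulateTITracks(truth, nReps = sy$nReps, timepoints = tp,
                              depth = sy$depth,
                              seed = .childSeed(seed, "condA"))
    manifest$stages$synthetic <- list(
      nBins = nBins(bins), depth = sy$depth, nReps = sy$nReps,
      classes = as.list(table(truth@classLabel)))
    repsB <- NULL
    if (isTRUE(sy$conditionB)) {
      # condition B: enhancers cool down, Polycomb targets speed up
      truthB <- truth
      sel <- truthB@classLabel == "enhancer"
      truthB@k[sel] <- truthB@k[sel] * 0.3
      sel <- truthB@classLabel == "pcg_target"
      truthB@k[sel] <- truthB@k[sel] * 4
      repsB <- simulateTITracks(truthB, nReps = sy$nReps, timepoints = tp,
                                depth = sy$depth,
                                seed = .childSeed(seed, "condB"))
    }
    chipPair <- if (isTRUE(sy$chip))
      simulateChip(truth, chipDepth = sy$depth, inputDepth = sy$depth,
                   seed = .childSeed(seed, "chip")) else NULL
    titration <- if (isTRUE(sy$titration))
      lapply(simulateMnaseTitration(truth, depth = sy$depth,
                                    seed = .childSeed(seed, "mnase")),
             function(fs) binCounts(fs, bins, "rpm")) else NULL
    spikeQC <- NULL
  } else {
    chromSizes <- readChromSizes(config$chromSizes)
    bins <- GenomeBins(chromSizes, config$binSize)
    condA <- .tiFromFiles(config$samples[[1L]], bins, tp, th)
    repsA <- condA$tracks
    spikeQC <- condA$spike
    repsB <- if (length(config$samples) >= 2L)
      .tiFromFiles(config$samples[[2L]], bins, tp, th)$tracks else NULL
    chipPair <- if (!is.null(config$chip))
      list(chip = readFragments(config$chip$chip),
           input = readFragments(config$chip$input)) else NULL
    titration <- if (!is.null(config$titration))
      lapply(config$titration, function(p)
        binCounts(readFragments(p), bins, "rpm")) else NULL
    for (nm in names(config$annotations))
      annotations[[nm]] <- fragments(readFragments(config$annotations[[nm]]))
    if (!is.null(config$blacklist))
      blacklist <- fragments(readFragments(config$blacklist))
    if (!is.null(config$expression))
      exprTab <- as.data.frame(data.table::fread(config$expression))
  }

  # --- turnover stage ---
  meanTI <- averageReplicates(repsA)
  conc <- if (length(repsA) >= 2L) replicateConcordance(repsA) else NULL
  p <- file.path(outDir, "ti_mean.tsv")
  writeTurnoverTsv(meanTI, p, bedgraph = file.path(outDir, "ti_mean.bg"))
  addOut(p); addOut(file.path(outDir, "ti_mean.bg"))
  manifest$stages$turnover <- list(
    nReps = length(repsA),
    coveredBins = sum(coverageMask(meanTI)),
    concordance = if (is.null(conc)) NULL else
      as.list(conc[upper.tri(conc)]),
    spikeRelativeReads = if (is.null(spikeQC)) NULL else
      lapply(spikeQC, function(s) s$relativeReads))

  # --- region discovery stage ---
  smoothed <- smoothTI(meanTI, th$windowBins)
  nTop <- min(th$nTop, sum(coverageMask(smoothed)) - 1L)
  top <- topRegions(smoothed, n = nTop, blacklist = blacklist)
  fdr <- empiricalFdr(smoothed, top,
                      nDraw = min(1000L, sum(coverageMask(smoothed))),
                      seed = .childSeed(seed, "fdr"))
  p <- file.path(outDir, "top_regions.bed")
  writePeaksBed(top, p); addOut(p)
  enrich <- if (length(annotations))
    featureOverrepresentation(top, annotations, bins) else NULL
  if (!is.null(enrich)) {
    p <- file.path(outDir, "feature_overrepresentation.tsv")
    data.table::fwrite(enrich, p, sep = "\t"); addOut(p)
  }
  manifest$stages$regions <- list(nTop = nTop, fdr = as.numeric(fdr),
                                  threshold = attr(fdr, "threshold"))

  # --- differential stage ---
  if (!is.null(repsB)) {
    res <- selectChanged(moderatedTest(repsA, repsB), q = th$q,
                         pMax = th$pMax)
    p <- file.path(outDir, "differential.tsv")
    data.table::fwrite(res, p, sep = "\t"); addOut(p)
    changed <- selectedRegions(res)
    manifest$stages$differential <- list(
      nSelected = sum(res$selected),
      counts = as.list(attr(res, "counts")),
      hyper = attr(res, "hyper")[c("d0", "s02")])
    genes <- annotations[["active_tss"]]
    enh <- annotations[["enhancer"]]
    if (!is.null(genes) && !is.null(enh) && length(changed) > 0) {
      unanno <- classifyUnannotated(changed, genes, enh)
      ov <- overlapSignificance(unanno, genes, bins,
                                mode = "within_distance",
                                distanceBp = th$distanceBp,
                                seed = .childSeed(seed, "overlap"))
      manifest$stages$differential$unannotated <- list(
        n = length(unanno), nearGenes = ov$observed, pValue = ov$pValue)
    }
  }

  # --- peak calling stage ---
  if (!is.null(chipPair)) {
    stats <- windowScan(chipPair$chip, chipPair$input,
                        chromSizes = bins@seqlengths, alpha = th$alpha)
    peaks <- mergeWindows(stats)
    p <- file.path(outDir, "peaks.bed")
    writePeaksBed(peaks, p); addOut(p)
    manifest$stages$peaks <- list(
      nSignificantWindows = sum(S4Vectors::mcols(stats)$significant),
      nPeaks = length(peaks),
      nbSize = S4Vectors::metadata(stats)$nbSize)
  }

  # --- accessibility stage ---
  if (!is.null(titration)) {
    macc <- computeMacc(titration)
    p <- file.path(outDir, "macc.bg")
    writeBedGraph(BinnedTrack(bins, ifelse(is.na(maccValues(macc)), 0,
                                           maccValues(macc)),
                              "rpm_minus_input"), p)
    addOut(p)
    manifest$stages$accessibility <- list(
      nWithMacc = sum(!is.na(maccValues(macc))))
    enh <- annotations[["enhancer"]]
    if (!is.null(enh) && length(enh) >= 3) {
      ct <- correlateTracks(meanTI, macc, enh)
      manifest$stages$accessibility$tiMaccEnhancerR <- ct$r
    }
  }

  # --- expression filters ---
  if (!is.null(exprTab) && nrow(exprTab) > 0) {
    manifest$stages$expression <- list(
      nRobust = length(expressedGenes(exprTab, th$fpkmFloor)),
      nChanging3x = length(changingGenes(exprTab, th$foldChange)),
      nChanging4x = length(changingGenes(exprTab, th$foldChangeMacc)))
  }

  manifest$inputHashes <- as.list(tools::md5sum(
    manifest$outputs[file.exists(manifest$outputs)]))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Run the packaged synthetic end-to-end demo
#'
#' Builds the ESC-like synthetic genome, simulates two conditions plus
#' ChIP and MNase titration, and runs the full pipeline.
#'
#' @param seed integer seed (default 7).
#' @param outDir output directory (default a tempdir subdirectory).
#' @param scale genome/class-count scale factor (default 0.2, a 2.5 Mb
#'   demo genome).
#' @param depth reads per library (default 3e5).
#' @return Invisibly, the pipeline manifest.
#' @export
synthDemo <- function(seed = 7, outDir = file.path(tempdir(), "synthdemo"),
                      scale = 0.2, depth = 3e5) {
  config <- list(seed = seed,
                 synthetic = list(scale = scale, nChroms = 2L,
                                  chromLen = 1.25e6 * scale / 0.2,
                                  depth = depth, nReps = 3L,
                                  conditionB = TRUE, chip = TRUE,
                                  titration = TRUE),
                 # selection size scaled to the demo genome (~2500 bins)
                 thresholds = list(nTop = max(50L, as.integer(500 * scale))))
  runPipeline(config, outDir)
}
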