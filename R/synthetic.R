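# Synthetic genomes with known turnover ground truth. Labeled-histone
# signal decays exponentially per bin; sequencing counts are negative
# binomial around the decayed expectation; a dedicated spike-in contig
# receives a constant expected read count so the genomic:spike ratio
# tracks the decaying labeled pool.

.SPIKE_CHROM <- "spike_001"
.SPIKE_LEN <- 50000L

# derive a child seed (< 2^31) from a base seed and a stage tag
.childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587 + 1)
}

#' Region class specification table for synthetic genomes
#'
#' One row per region class with its placement count, width, labeled
#' histone decay rate (per hour), 0 hr pulldown enrichment over background,
#' true accessibility slope and factor-ChIP fold enrichment.
#'
#' @param name class names.
#' @param count regions to place per class.
#' @param widthBp region width in bp (ideally a multiple of the bin size so
#'   bin-level truth is unambiguous).
#' @param k labeled-histone decay rate per hour (>= 0).
#' @param enrichment0h 0 hr enrichment, fold over background (>= 0).
#' @param accessibilityA true accessibility slope (MACC-like).
#' @param chipFold factor-ChIP fold enrichment (e.g. a Polycomb mark).
#' @return A `data.frame` of class specs.
#' @export
regionClassSpec <- function(name, count, widthBp, k, enrichment0h,
                            accessibilityA = 0, chipFold = 1) {
  stopifnot(all(k >= 0), all(enrichment0h >= 0))
  data.frame(name = name, count = as.integer(count),
             widthBp = as.integer(widthBp), k = k,
             enrichment0h = enrichment0h,
             accessibilityA = accessibilityA, chipFold = chipFold,
             stringsAsFactors = FALSE)
}

#' ESC-like default class specification
#'
#' The default synthetic world mirrors the qualitative ordering seen in
#' pluripotent cells: super-enhancers turn over fastest, then conventional
#' enhancers, then active TSSs/TTSs; Polycomb targets are enriched for the
#' labeled histone but replace it only slightly faster than the bulk
#' genome; heterochromatin is barely pulled down. Every decay rate
#' includes a shared replication-dilution floor of about ln(2)/12 per
#' hour (labeled histones are diluted two-fold per ~12 hr cell cycle in
#' ESCs) with locus-specific replication-independent turnover on top, and
#' regulatory classes occupy a realistically small fraction of the
#' genome — both matter because per-million normalization makes the index
#' relative to the enrichment-weighted pool decay. Accessibility tracks
#' turnover (fast-turnover classes are more MNase accessible). Counts are
#' sized for a 10 Mb genome and scaled by `scale`.
#'
#' @param scale multiplier on the per-class counts (default 1, sized for a
#'   10 Mb genome; use genome bp / 1e7).
#' @return A class spec `data.frame` (see [regionClassSpec()]).
#' @export
escLikeSpecs <- function(scale = 1) {
  sp <- rbind(
    regionClassSpec("active_tss",      120, 1000, 0.12, 6, 0.07),
    regionClassSpec("tts",              80, 1000, 0.10, 4, 0.05),
    regionClassSpec("enhancer",         80, 2000, 0.18, 5, 0.12),
    regionClassSpec("super_enhancer",   10, 6000, 0.30, 8, 0.15),
    regionClassSpec("pcg_target",       60, 3000, 0.09, 5, 0.03,
                    chipFold = 8),
    regionClassSpec("heterochromatin",  60, 5000, 0.055, 0.2, 0.00))
  sp$count <- pmax(1L, as.integer(round(sp$count * scale)))
  sp
}

.BACKGROUND <- list(k = 0.06, enrichment = 1, accessibility = 0.02,
                    chipFold = 1)

#' Build a synthetic genome with known per-bin truth
#'
#' Places the requested region classes uniformly at random without overlap
#' on a multi-chromosome genome (regions are aligned to bin boundaries so
#' every bin has exactly one class), assigns per-region decay rates with
#' optional lognormal jitter around the class rate, and generates a
#' synthetic expression table. Deterministic given `(specs, seed)`.
#'
#' @param specs class spec `data.frame` from [regionClassSpec()] /
#'   [escLikeSpecs()]; empty for an all-background genome.
#' @param nChroms number of chromosomes.
#' @param chromLen chromosome length in bp.
#' @param binSize bin width in bp.
#' @param seed integer RNG seed.
#' @param rateJitterSd sd of mean-preserving lognormal jitter applied to
#'   each region's decay rate (default 0.35, matching the broad within-class
#'   turnover spread real data shows; 0 = every region gets exactly the class rate).
#' @param coupleAccessibility scale each region's accessibility with its
#'   realized decay rate (`a = classA * kRegion / classK`), emulating the
#'   observed coupling between turnover and MNase accessibility.
#' @param accessibilityJitterSd sd of additive Gaussian per-bin jitter on
#'   the accessibility truth (default 0.03), giving a continuous
#'   genome-wide accessibility distribution within the linear range of the
#'   titration response rather than a few class-constant values; set 0 to
#'   disable.
#' @return A [SyntheticTruth].
#' @examples
#' truth <- buildGenome(escLikeSpecs(0.2), nChroms = 1, chromLen = 2e6,
#'                      seed = 1)
#' truth
#' @export
buildGenome <- function(specs = escLikeSpecs(), nChroms = 2,
                        chromLen = 5e6, binSize = 1000, seed = 1,
                        rateJitterSd = 0.35, coupleAccessibility = TRUE,
                        accessibilityJitterSd = 0.03) {
  sl <- setNames(rep(as.integer(chromLen), nChroms),
                 paste0("chr", seq_len(nChroms)))
  gb <- GenomeBins(sl, binSize)
  nb <- nBins(gb)
  if (nrow(specs) > 0 && sum(specs$count * specs$widthBp) >= sum(sl))
    stop("total placed width must be smaller than the genome")
  set.seed(.childSeed(seed, "genome"))
  classLabel <- rep("background", nb)
  k <- rep(.BACKGROUND$k, nb)
  enr <- rep(.BACKGROUND$enrichment, nb)
  acc <- rep(.BACKGROUND$accessibility, nb)
  cf <- rep(.BACKGROUND$chipFold, nb)
  occupied <- rep(FALSE, nb)
  npc <- .binsPerChrom(gb)
  off <- .binOffsets(gb)
  regions <- list()
  ord <- if (nrow(specs) > 0) order(-specs$widthBp) else integer(0)
  for (si in ord) {
    sp <- specs[si, ]
    wBins <- max(1L, as.integer(ceiling(sp$widthBp / binSize)))
    placed <- 0L
    tries <- 0L
    starts <- integer(sp$count); chromIdx <- integer(sp$count)
    while (placed < sp$count) {
      tries <- tries + 1L
      if (tries > 1000L * sp$count)
        stop("could not place ", sp$count, " regions of class ", sp$name,
             "; reduce counts or widths")
      ci <- sample.int(nChroms, 1L)
      maxStart <- npc[ci] - wBins
      if (maxStart < 0L) next
      b0 <- sample.int(maxStart + 1L, 1L) - 1L
      idx <- off[ci] + b0 + seq_len(wBins)
      if (any(occupied[idx])) next
      occupied[idx] <- TRUE
      placed <- placed + 1L
      starts[placed] <- b0; chromIdx[placed] <- ci
      jit <- if (rateJitterSd > 0)
        exp(rnorm(1L, -rateJitterSd^2 / 2, rateJitterSd)) else 1
      kReg <- sp$k * jit
      aReg <- if (coupleAccessibility && sp$k > 0)
        sp$accessibilityA * kReg / sp$k else sp$accessibilityA
      classLabel[idx] <- sp$name
      k[idx] <- kReg
      enr[idx] <- sp$enrichment0h
      acc[idx] <- aReg
      cf[idx] <- sp$chipFold
    }
    regions[[sp$name]] <- GRanges(
      names(sl)[chromIdx],
      IRanges(start = starts * binSize + 1L,
              width = wBins * binSize))
  }
  regions <- GenomicRanges::GRangesList(
    lapply(regions, function(g) BiocGenerics::sort(g)))
  if (accessibilityJitterSd > 0)
    acc <- acc + rnorm(nb, 0, accessibilityJitterSd)
  expr <- .syntheticExpression(classLabel)
  new("SyntheticTruth", bins = gb, classLabel = classLabel, k = k,
      enrichment = enr, accessibility = acc, chipFold = cf,
      regions = regions, expression = expr, classSpecs = specs,
      seed = as.integer(seed))
}

# one synthetic gene per active_tss/pcg_target region-start bin; ~20% of
# active genes change >= 4-fold between conditions
.syntheticExpression <- function(classLabel) {
  isGene <- classLabel %in% c("active_tss", "pcg_target")
  idx <- which(isGene)
  if (length(idx) == 0L)
    return(data.frame(gene = character(0), class = character(0),
                      fpkmA = numeric(0), fpkmB = numeric(0)))
  cls <- classLabel[idx]
  meanlog <- ifelse(cls == "active_tss", log(30), log(0.5))
  fpkmA <- exp(rnorm(length(idx), meanlog, 1))
  change <- runif(length(idx)) < 0.2
  dirUp <- runif(length(idx)) < 0.5
  fold <- exp(rnorm(length(idx), log(5), 0.2))
  fpkmB <- ifelse(change, ifelse(dirUp, fpkmA * fold, fpkmA / fold), fpkmA)
  data.frame(gene = paste0("gene_", seq_along(idx)), class = cls,
             binIndex = idx, fpkmA = fpkmA, fpkmB = fpkmB,
             stringsAsFactors = FALSE)
}

# NB counts per bin -> fragment GRanges with midpoints inside the bin
.fragmentsFromCounts <- function(counts, gb, width = 150L) {
  npc <- .binsPerChrom(gb)
  chromOfBin <- rep(names(gb@seqlengths), npc)
  binStart0 <- unlist(lapply(npc, function(n) seq_len(n) - 1L),
                      use.names = FALSE) * gb@binSize
  nz <- which(counts > 0L)
  chrom <- rep(chromOfBin[nz], counts[nz])
  bs0 <- rep(binStart0[nz], counts[nz])
  len <- unname(gb@seqlengths[chrom])
  binEnd0 <- pmin(bs0 + gb@binSize, len)
  mid <- bs0 + floor(runif(length(bs0)) * (binEnd0 - bs0))
  half <- width %/% 2L
  mid <- pmin(pmax(mid, half), len - half)
  s0 <- mid - half
  GRanges(chrom, IRanges(start = s0 + 1L, width = width),
          seqinfo = Seqinfo(names(gb@seqlengths), unname(gb@seqlengths)))
}

.spikeFragments <- function(n, width = 150L) {
  if (n <= 0L) return(GRanges())
  s0 <- floor(runif(n) * (.SPIKE_LEN - width))
  GRanges(.SPIKE_CHROM, IRanges(start = sort(s0) + 1L, width = width))
}

#' Simulate one pulse-chase time course replicate
#'
#' Expected labeled signal in bin b at chase time t is proportional to
#' `enrichment(b) * exp(-k(b) * t)`; observed per-bin counts are negative
#' binomial around that expectation, scaled so the expected genomic read
#' total at t = 0 equals `depth` and decays with the global labeled pool.
#' The spike-in contig receives a constant expected `spikeRatio * depth`
#' reads at every time point, so the genomic:spike read ratio decays like
#' the labeled pool. Replicate-to-replicate spread is emulated by one
#' mean-preserving lognormal factor per bin drawn once per call
#' (`replicateSd`); the matched input library is drawn flat over all bins.
#'
#' @param truth a [SyntheticTruth].
#' @param timepoints chase times in hours, starting at 0 (default
#'   `c(0, 3, 6, 12)`).
#' @param depth expected genomic reads at t = 0 (and input depth).
#' @param replicateSd lognormal sd of the per-bin replicate factor
#'   (default 0.15).
#' @param spikeRatio expected spike-in reads as a fraction of `depth`
#'   (default 0.05).
#' @param nbSize negative binomial size (dispersion) parameter
#'   (default 10).
#' @param seed integer seed; same seed gives identical output.
#' @param replicateId replicate label.
#' @return List with elements `timecourse` (named list of [FragmentSet]s,
#'   `"t0"`, `"t3"`, ...) and `input` (a [FragmentSet]).
#' @export
simulateTimecourse <- function(truth, timepoints = c(0, 3, 6, 12),
                               depth = 2e6, replicateSd = 0.15,
                               spikeRatio = 0.05, nbSize = 10, seed = 1,
                               replicateId = "rep1") {
  stopifnot(depth > 0, timepoints[1L] == 0)
  gb <- genomeBins(truth)
  set.seed(.childSeed(seed, paste0("tc_", replicateId)))
  nb <- nBins(gb)
  repFactor <- if (replicateSd > 0)
    exp(rnorm(nb, -replicateSd^2 / 2, replicateSd)) else rep(1, nb)
  e <- truth@enrichment * repFactor
  w0 <- sum(e)
  out <- vector("list", length(timepoints))
  names(out) <- paste0("t", timepoints)
  for (i in seq_along(timepoints)) {
    mu <- depth * e * exp(-truth@k * timepoints[i]) / w0
    counts <- rnbinom(nb, size = nbSize, mu = mu)
    spikeN <- rpois(1L, spikeRatio * depth)
    gr <- .fragmentsFromCounts(counts, gb)
    out[[i]] <- FragmentSet(gr, totalReads = length(gr) + spikeN,
                            spikeInReads = spikeN,
                            spikeFragments = .spikeFragments(spikeN),
                            label = paste0(replicateId, "_t", timepoints[i]))
  }
  muIn <- rep(depth / nb, nb)
  inCounts <- rnbinom(nb, size = nbSize, mu = muIn)
  inGr <- .fragmentsFromCounts(inCounts, gb)
  input <- FragmentSet(inGr, label = paste0(replicateId, "_input"))
  list(timecourse = out, input = input)
}

#' Simulate several time-course replicates
#'
#' Fans the base seed out to one stable child seed per replicate.
#'
#' @inheritParams simulateTimecourse
#' @param nReps number of replicates.
#' @return List of length `nReps`; each element as returned by
#'   [simulateTimecourse()].
#' @export
simulateTimecourseReplicates <- function(truth, nReps = 3,
                                         timepoints = c(0, 3, 6, 12),
                                         depth = 2e6, replicateSd = 0.15,
                                         spikeRatio = 0.05, nbSize = 10,
                                         seed = 1) {
  lapply(seq_len(nReps), function(r)
    simulateTimecourse(truth, timepoints = timepoints, depth = depth,
                       replicateSd = replicateSd, spikeRatio = spikeRatio,
                       nbSize = nbSize, seed = .childSeed(seed, paste0("rep", r)),
                       replicateId = paste0("rep", r)))
}

#' Build an input-subtracted TimeCourse from simulated fragments
#'
#' Convenience path fragments -> binned RPM -> input subtraction.
#'
#' @param sim output of [simulateTimecourse()] (elements `timecourse`,
#'   `input`).
#' @param bins the [GenomeBins] to bin on.
#' @param timepoints hours matching `sim$timecourse`.
#' @param replicateId replicate label.
#' @return A [TimeCourse].
#' @export
timecourseFromFragments <- function(sim, bins,
                                    timepoints = c(0, 3, 6, 12),
                                    replicateId = "rep1") {
  inputTrack <- binCounts(sim$input, bins, "rpm")
  trks <- lapply(sim$timecourse, function(fs)
    subtractInput(binCounts(fs, bins, "rpm"), inputTrack))
  TimeCourse(timepoints, unname(trks), replicateId = replicateId)
}

#' Simulate replicates and compute their turnover tracks
#'
#' End-to-end helper for tests and the pipeline: simulate `nReps`
#' replicates from the truth, bin, input-subtract and compute TI for each,
#' discarding the fragment-level intermediates.
#'
#' @inheritParams simulateTimecourseReplicates
#' @return List of [TurnoverTrack]s, one per replicate.
#' @export
simulateTITracks <- function(truth, nReps = 3, timepoints = c(0, 3, 6, 12),
                             depth = 2e6, replicateSd = 0.15,
                             spikeRatio = 0.05, nbSize = 10, seed = 1) {
  gb <- genomeBins(truth)
  lapply(seq_len(nReps), function(r) {
    sim <- simulateTimecourse(truth, timepoints = timepoints, depth = depth,
                              replicateSd = replicateSd,
                              spikeRatio = spikeRatio, nbSize = nbSize,
                              seed = .childSeed(seed, paste0("rep", r)),
                              replicateId = paste0("rep", r))
    computeTI(timecourseFromFragments(sim, gb, timepoints,
                                      paste0("rep", r)))
  })
}

#' Simulate an MNase titration series
#'
#' MNase-seq of bulk chromatin has roughly flat coverage; the titration
#' response is modeled as expected log-signal linear in log2 enzyme units
#' with slope `-accessibility(b)`, i.e. accessible loci lose signal as
#' digestion strengthens. Counts are negative binomial; each concentration
#' is sequenced to the same expected depth.
#'
#' @param truth a [SyntheticTruth].
#' @param units MNase concentrations in enzyme units (>= 3 values,
#'   default `c(1, 4, 16, 64)`).
#' @param depth expected reads per concentration.
#' @param nbSize negative binomial size parameter (default 1000: titration
#'   libraries are technical re-digestions of one chromatin preparation,
#'   so counting noise is essentially Poisson, unlike the biological
#'   pulldown libraries, which default to size 10).
#' @param seed integer seed.
#' @return Named list of [FragmentSet]s, one per concentration
#'   (`"u1"`, `"u4"`, ...).
#' @export
simulateMnaseTitration <- function(truth, units = c(1, 4, 16, 64),
                                   depth = 2e6, nbSize = 1000, seed = 1) {
  if (length(units) < 3L) stop("need >= 3 MNase concentrations")
  gb <- genomeBins(truth)
  set.seed(.childSeed(seed, "mnase"))
  nb <- nBins(gb)
  out <- vector("list", length(units))
  names(out) <- paste0("u", units)
  for (i in seq_along(units)) {
    w <- exp(-truth@accessibility * log2(units[i]))
    mu <- depth * w / sum(w)
    counts <- rnbinom(nb, size = nbSize, mu = mu)
    gr <- .fragmentsFromCounts(counts, gb)
    out[[i]] <- FragmentSet(gr, label = paste0("mnase_u", units[i]))
  }
  out
}

#' Simulate a factor ChIP / input pair
#'
#' ChIP reads are enriched `chipFold`-fold over background inside the
#' target class intervals; the input is flat.
#'
#' @param truth a [SyntheticTruth].
#' @param targetClass class name carrying the enrichment (must exist in
#'   the truth).
#' @param chipDepth,inputDepth expected reads per library.
#' @param nbSize negative binomial size parameter.
#' @param seed integer seed.
#' @return List with [FragmentSet] elements `chip` and `input`.
#' @export
simulateChip <- function(truth, targetClass = "pcg_target", chipDepth = 1e6,
                         inputDepth = 1e6, nbSize = 10, seed = 1) {
  if (!targetClass %in% truth@classLabel)
    stop("class ", targetClass, " not present in truth")
  gb <- genomeBins(truth)
  set.seed(.childSeed(seed, paste0("chip_", targetClass)))
  nb <- nBins(gb)
  inTarget <- truth@classLabel == targetClass
  w <- ifelse(inTarget, truth@chipFold, 1)
  muChip <- chipDepth * w / sum(w)
  chipCounts <- rnbinom(nb, size = nbSize, mu = muChip)
  inCounts <- rnbinom(nb, size = nbSize, mu = rep(inputDepth / nb, nb))
  list(chip = FragmentSet(.fragmentsFromCounts(chipCounts, gb),
                          label = paste0("chip_", targetClass)),
       input = FragmentSet(.fragmentsFromCounts(inCounts, gb),
                           label = "chip_input"))
}

#' Write synthetic truth and annotations to disk
#'
#' Writes chrom.sizes (genomic contigs plus the spike-in contig), one BED
#' per region class, the per-bin truth table and the expression table, all
#' as plain text.
#'
#' @param truth a [SyntheticTruth].
#' @param dir output directory (created if needed).
#' @return Invisibly, a character vector of the written paths.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- genomeBins(truth)
  paths <- character(0)
  p <- file.path(dir, "genome.chrom.sizes")
  writeChromSizes(c(gb@seqlengths, setNames(.SPIKE_LEN, .SPIKE_CHROM)), p)
  paths <- c(paths, p)
  for (cls in names(truth@regions)) {
    gr <- truth@regions[[cls]]
    p <- file.path(dir, paste0(cls, ".bed"))
    write.table(data.frame(as.character(GenomeInfoDb::seqnames(gr)),
                           BiocGenerics::start(gr) - 1L,
                           BiocGenerics::end(gr)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths <- c(paths, p)
  }
  gr <- binRanges(gb)
  p <- file.path(dir, "truth_bins.tsv")
  data.table::fwrite(data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    class = truth@classLabel, k = truth@k,
    enrichment = truth@enrichment,
    accessibility = truth@accessibility,
    chip_fold = truth@chipFold), p, sep = "\t")
  paths <- c(paths, p)
  p <- file.path(dir, "expression.tsv")
  data.table::fwrite(truth@expression, p, sep = "\t")
  paths <- c(paths, p)
  invisible(paths)
}
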