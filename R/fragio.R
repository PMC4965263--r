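#' Read a chromosome sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  setNames(as.integer(dt$size), dt$chrom)
}

#' Write a chromosome sizes file
#' @param seqlengths named vector of chromosome lengths.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeChromSizes <- function(seqlengths, path) {
  write.table(data.frame(names(seqlengths), unname(seqlengths)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned fragments from BED or minimal SAM text
#'
#' Reads fragment intervals from a BED3+ file (0-based half-open, the
#' convention for all interval I/O in this package) or from a minimal SAM
#' text file (fragment reconstructed from POS and a positive TLEN of the
#' leftmost mate). Records on contigs whose name starts with
#' `spikeInPrefix` are partitioned out of the genomic records and counted
#' into the spike-in tally.
#'
#' @param path input file.
#' @param format `"bed"` or `"sam"`.
#' @param spikeInPrefix contig-name prefix identifying spike-in records
#'   (`NULL` to disable).
#' @param chromSizes optional named vector of genomic chromosome lengths;
#'   when given, fragments beyond a chromosome end raise an error and the
#'   returned ranges carry seqinfo.
#' @param label library label (defaults to the file name).
#' @return A [FragmentSet] with records sorted by (chrom, start);
#'   `totalReads = genomic records + spike-in reads`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t150", "chr1\t500\t650", "spike_001\t10\t160"), bed)
#' fs <- readFragments(bed, spikeInPrefix = "spike_")
#' nFragments(fs); spikeInReads(fs)
#' @export
readFragments <- function(path, format = c("bed", "sam"),
                          spikeInPrefix = NULL, chromSizes = NULL,
                          label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    raw <- readLines(path)
    keep <- !startsWith(raw, "track") & !startsWith(raw, "#") & nzchar(raw)
    lineno <- which(keep)
    fields <- strsplit(raw[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
      stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
           ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1),
                                                 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1),
                                               3L)))
    bad <- is.na(start0) | is.na(end0)
    if (any(bad))
      stop("malformed BED line ", lineno[which(bad)[1L]],
           ": non-numeric coordinates")
    if (any(end0 <= start0))
      stop("invalid interval at line ", lineno[which(end0 <= start0)[1L]],
           ": end <= start")
  } else {
    raw <- readLines(path)
    raw <- raw[!startsWith(raw, "@") & nzchar(raw)]
    fields <- strsplit(raw, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
      stop("malformed SAM line: fewer than 11 columns")
    chrom <- vapply(fields, `[[`, character(1), 3L)
    pos <- as.numeric(vapply(fields, `[[`, character(1), 4L))
    tlen <- as.numeric(vapply(fields, `[[`, character(1), 9L))
    keep <- chrom != "*" & !is.na(tlen) & tlen > 0
    chrom <- chrom[keep]
    start0 <- pos[keep] - 1
    end0 <- start0 + tlen[keep]
  }
  isSpike <- if (is.null(spikeInPrefix)) rep(FALSE, length(chrom)) else
    startsWith(chrom, spikeInPrefix)
  mkGr <- function(ch, s0, e0, sizes = NULL) {
    o <- order(ch, s0)
    gr <- GRanges(ch[o], IRanges(start = s0[o] + 1, end = e0[o]))
    if (!is.null(sizes)) {
      beyond <- e0 > unname(sizes[ch])
      beyond[is.na(beyond)] <- FALSE
      if (any(beyond))
        stop("fragment beyond chromosome end on ",
             paste(unique(ch[beyond]), collapse = ", "))
      known <- ch %in% names(sizes)
      if (all(known))
        GenomeInfoDb::seqlevels(gr) <- names(sizes)
      if (all(known))
        suppressWarnings(GenomeInfoDb::seqlengths(gr) <- unname(sizes))
    }
    gr
  }
  genomic <- mkGr(chrom[!isSpike], start0[!isSpike], end0[!isSpike],
                  chromSizes)
  spike <- mkGr(chrom[isSpike], start0[isSpike], end0[isSpike])
  FragmentSet(genomic, totalReads = length(genomic) + length(spike),
              spikeInReads = length(spike), spikeFragments = spike,
              label = label)
}

#' Write a FragmentSet as BED3
#'
#' Genomic records first, then spike-in records, 0-based half-open.
#'
#' @param x a [FragmentSet].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFragmentsBed <- function(x, path) {
  # genomic and spike-in contigs have disjoint seqlevels by design
  gr <- suppressWarnings(c(fragments(x), x@spikeFragments))
  dt <- data.table::data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                               start = BiocGenerics::start(gr) - 1L,
                               end = BiocGenerics::end(gr))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a BinnedTrack as BEDGraph
#' @param track a [BinnedTrack].
#' @param path output path.
#' @param dropZero drop zero-valued bins (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path, dropZero = TRUE) {
  gr <- binRanges(genomeBins(track))
  v <- trackValues(track)
  keep <- if (dropZero) v != 0 else rep(TRUE, length(v))
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr))[keep],
    start = BiocGenerics::start(gr)[keep] - 1L,
    end = BiocGenerics::end(gr)[keep],
    value = v[keep])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BEDGraph into a BinnedTrack
#'
#' Intervals must be aligned to the bin grid; bins absent from the file
#' get 0.
#'
#' @param path BEDGraph path.
#' @param bins target [GenomeBins].
#' @param units units to stamp on the track.
#' @return A [BinnedTrack].
#' @export
readBedGraph <- function(path, bins, units = "rpm") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  bad <- !dt$chrom %in% names(bins@seqlengths)
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(dt$chrom[bad]),
                                          collapse = ", "))
  idx <- .binIndex(bins, dt$chrom, dt$start)
  v <- numeric(nBins(bins))
  v[idx] <- dt$value
  BinnedTrack(bins, v, units)
}

#' Remove anomalous alignment positions
#'
#' Tags piling up at a single genomic start position far beyond the
#' genome-wide distribution are PCR/alignment artifacts. Start positions
#' whose tag count has a z-score above `zThreshold` (mean and sd computed
#' over positions carrying at least one tag) are dropped together with all
#' their tags. Applying the filter again to its own output (with
#' statistics recomputed) removes nothing further once no position exceeds
#' the threshold.
#'
#' @param frags a [FragmentSet].
#' @param zThreshold z-score cutoff (default 7).
#' @param perChromosome compute the statistics per chromosome instead of
#'   genome-wide (default `FALSE`).
#' @return A filtered [FragmentSet]; `totalReads` is reduced by the number
#'   of discarded tags.
#' @export
filterAnomalousPositions <- function(frags, zThreshold = 7,
                                     perChromosome = FALSE) {
  gr <- fragments(frags)
  if (length(gr) == 0L) stop("empty FragmentSet")
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  key <- paste0(chrom, ":", BiocGenerics::start(gr))
  grpAll <- if (perChromosome) chrom else rep("all", length(gr))
  drop <- rep(FALSE, length(gr))
  for (g in unique(grpAll)) {
    sel <- grpAll == g
    cnt <- table(key[sel])
    s <- sd(cnt)
    if (is.na(s) || s == 0) {
      warning("position counts have zero variance; nothing removed")
      next
    }
    z <- (as.numeric(cnt) - mean(cnt)) / s
    badPos <- names(cnt)[z > zThreshold]
    if (length(badPos)) drop[sel][key[sel] %in% badPos] <- TRUE
  }
  nDropped <- sum(drop)
  FragmentSet(gr[!drop], totalReads = totalReads(frags) - nDropped,
              spikeInReads = spikeInReads(frags),
              spikeFragments = frags@spikeFragments, label = frags@label)
}

#' Bin fragment counts genome-wide
#'
#' Each fragment is assigned to exactly one bin by its midpoint, which
#' avoids double counting across bin edges. RPM normalization divides by
#' the genomic mapped-read count (`totalReads - spikeInReads`) so library
#' size comparisons are not distorted by the spike-in.
#'
#' @param frags a [FragmentSet].
#' @param bins a [GenomeBins]; every fragment chromosome must be present.
#' @param normalize `"raw"` (integer counts) or `"rpm"`.
#' @return A [BinnedTrack].
#' @examples
#' gb <- GenomeBins(c(chr1 = 3000))
#' fs <- FragmentSet(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(start = c(401, 1401), end = c(600, 1600))))
#' trackValues(binCounts(fs, gb))
#' @export
binCounts <- function(frags, bins, normalize = c("raw", "rpm")) {
  normalize <- match.arg(normalize)
  gr <- fragments(frags)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- !chrom %in% names(bins@seqlengths)
  if (any(bad))
    stop("fragments on chromosome(s) absent from bins: ",
         paste(unique(chrom[bad]), collapse = ", "))
  # midpoint in 0-based coordinates: floor((start0 + end0) / 2)
  mid0 <- (BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) %/% 2
  idx <- .binIndex(bins, chrom, mid0)
  counts <- tabulate(idx, nbins = nBins(bins))
  if (normalize == "raw")
    return(BinnedTrack(bins, counts, "raw"))
  denom <- genomicReads(frags)
  if (denom <= 0) stop("no genomic reads to normalize by")
  BinnedTrack(bins, counts * 1e6 / denom, "rpm")
}

#' Subtract an input track from a ChIP track
#'
#' Elementwise `chip - input`, floored at 0: negative enrichment carries no
#' information for the turnover regression and would corrupt the slope fit.
#'
#' @param chip [BinnedTrack] in RPM units.
#' @param input [BinnedTrack] in RPM units on identical bins.
#' @return A [BinnedTrack] with units `rpm_minus_input`.
#' @export
subtractInput <- function(chip, input) {
  if (trackUnits(chip) != "rpm" || trackUnits(input) != "rpm")
    stop("both tracks must be in rpm units")
  if (!.sameBins(genomeBins(chip), genomeBins(input)))
    stop("chip and input are on different bins")
  BinnedTrack(genomeBins(chip),
              pmax(trackValues(chip) - trackValues(input), 0),
              "rpm_minus_input")
}

# offsets grid and anchor filtering shared by the profile methods
.profileGrid <- function(anchors, flank, step, seqlen) {
  if (length(anchors) == 0L) stop("anchors must be non-empty")
  if (flank %% step != 0) stop("flank must be a multiple of step")
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  pos0 <- BiocGenerics::start(anchors) - 1
  known <- chrom %in% names(seqlen)
  inb <- known
  inb[known] <- pos0[known] - flank >= 0 &
    pos0[known] + flank < unname(seqlen[chrom[known]])
  list(offsets = seq(-flank, flank, by = step), chrom = chrom, pos0 = pos0,
       keep = inb,
       minus = as.character(BiocGenerics::strand(anchors)) == "-")
}

.profileFromMatrix <- function(M, offsets, minus, nSkipped) {
  if (any(minus)) M[minus, ] <- M[minus, rev(seq_along(offsets)), drop = FALSE]
  out <- data.frame(offset = offsets, meanSignal = colMeans(M))
  attr(out, "nAnchors") <- nrow(M)
  attr(out, "nSkipped") <- nSkipped
  out
}

#' @describeIn aggregateProfile sample the per-bin track value at each
#'   offset (the value of the bin containing the position).
#' @export
setMethod("aggregateProfile", "BinnedTrack",
          function(x, anchors, flank, step, ...) {
  gb <- genomeBins(x)
  g <- .profileGrid(anchors, flank, step, gb@seqlengths)
  nSkipped <- sum(!g$keep)
  if (nSkipped > 0)
    message(nSkipped, " anchor(s) outside chromosome bounds skipped")
  if (!any(g$keep)) stop("no usable anchors")
  chrom <- g$chrom[g$keep]; pos0 <- g$pos0[g$keep]
  nOff <- length(g$offsets)
  posMat <- outer(pos0, g$offsets, `+`)
  idx <- .binIndex(gb, rep(chrom, nOff), as.vector(posMat))
  M <- matrix(trackValues(x)[idx], nrow = length(pos0), ncol = nOff)
  .profileFromMatrix(M, g$offsets, g$minus[g$keep], nSkipped)
})

#' @describeIn aggregateProfile count fragment midpoints in step-sized
#'   windows around each offset; `normalize = "rpm"` (default) scales by
#'   library size.
#' @param normalize for the `FragmentSet` method: `"rpm"` or `"raw"`.
#' @param chromSizes for the `FragmentSet` method: named chromosome
#'   lengths; defaults to the seqinfo of the fragments.
#' @export
setMethod("aggregateProfile", "FragmentSet",
          function(x, anchors, flank, step, normalize = "rpm",
                   chromSizes = NULL, ...) {
  if (is.null(chromSizes)) {
    chromSizes <- GenomeInfoDb::seqlengths(fragments(x))
    if (any(is.na(chromSizes)))
      stop("supply chromSizes (fragment seqinfo has no lengths)")
  }
  gb <- GenomeBins(chromSizes, binSize = step)
  tr <- binCounts(x, gb, normalize = if (normalize == "rpm") "rpm" else "raw")
  aggregateProfile(tr, anchors, flank, step)
})
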