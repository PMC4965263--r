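# step-resolution midpoint counts per chromosome, then rolling window sums
.windowCounts <- function(frags, seqlen, window, step) {
  gbStep <- GenomeBins(seqlen, binSize = step)
  stepCounts <- trackValues(binCounts(frags, gbStep, "raw"))
  k <- window %/% step
  npc <- .binsPerChrom(gbStep)
  pos <- 0L
  res <- vector("list", length(npc))
  for (ci in seq_along(npc)) {
    n <- npc[ci]
    x <- stepCounts[pos + seq_len(n)]
    nw <- n - k + 1L
    if (nw < 1L) {
      res[[ci]] <- list(start0 = numeric(0), counts = numeric(0))
    } else {
      cs <- cumsum(c(0, x))
      res[[ci]] <- list(start0 = (seq_len(nw) - 1) * step,
                        counts = cs[seq_len(nw) + k] - cs[seq_len(nw)])
    }
    pos <- pos + n
  }
  names(res) <- names(seqlen)
  res
}

#' Negative-binomial sliding-window enrichment scan
#'
#' Scans each chromosome with overlapping windows (`window` bp wide,
#' `step` bp apart), counts fragment midpoints per window in the ChIP and
#' input libraries, and tests each ChIP count against a negative binomial
#' null whose mean is the input count scaled by the library-size ratio
#' (floored at `pseudoMean` so empty input windows cannot produce
#' spuriously tiny p-values). The upper-tail p-value is
#' `P(X >= chipCount)`.
#'
#' The NB size (dispersion) parameter is a free parameter of the method;
#' `nbSize = "auto"` (default) fits it by method of moments on the
#' chip-minus-scaled-input residuals across windows, which absorbs both
#' the counting noise and the uncertainty of the input-derived mean and
#' keeps the null calibrated. `nbSize = "input"` fits on the input window
#' counts alone (anti-conservative when input coverage is low); a positive
#' number fixes the size directly.
#'
#' @param chip,input [FragmentSet]s (non-empty).
#' @param chromSizes named chromosome lengths; defaults to the seqinfo of
#'   the ChIP fragments.
#' @param window window width in bp (default 1000); must be a multiple of
#'   `step`.
#' @param step window step in bp (default 200).
#' @param inputWindow width of the input window used to estimate the local
#'   null mean, in bp (default `5 * window`, scaled down to the test
#'   window); a wider background window suppresses the sampling noise of
#'   the mean estimate, which would otherwise shift the null mean
#'   window-by-window and break calibration. Must be an odd multiple of
#'   `window`. Set equal to `window` for the strictly window-matched
#'   estimate.
#' @param alpha significance cutoff on the NB p-value (default 1e-5).
#' @param nbSize `"auto"`, `"input"`, or a positive number.
#' @param pseudoMean floor on the scaled null mean (default 1 read).
#' @return `GRanges` of windows with metadata columns `chipCount`,
#'   `inputCount`, `pValue`, `significant`; `S4Vectors::metadata()`
#'   records the window/step/alpha/size/scale used.
#' @export
windowScan <- function(chip, input, chromSizes = NULL, window = 1000L,
                       step = 200L, alpha = 1e-5, nbSize = "auto",
                       pseudoMean = 1, inputWindow = 5L * window) {
  if (nFragments(chip) == 0L || nFragments(input) == 0L)
    stop("chip and input must be non-empty")
  if (window %% step != 0L) stop("window must be a multiple of step")
  if (inputWindow %% window != 0L || (inputWindow %/% window) %% 2L != 1L)
    stop("inputWindow must be an odd multiple of window")
  if (is.numeric(nbSize) && nbSize <= 0) stop("nbSize must be > 0")
  if (is.null(chromSizes)) {
    chromSizes <- GenomeInfoDb::seqlengths(fragments(chip))
    if (length(chromSizes) == 0L || any(is.na(chromSizes)))
      stop("supply chromSizes (fragment seqinfo has no lengths)")
  }
  wc <- .windowCounts(chip, chromSizes, window, step)
  wi <- .windowCounts(input, chromSizes, window, step)
  chipCount <- unlist(lapply(wc, `[[`, "counts"), use.names = FALSE)
  inputCount <- unlist(lapply(wi, `[[`, "counts"), use.names = FALSE)
  start0 <- unlist(lapply(wc, `[[`, "start0"), use.names = FALSE)
  chrom <- rep(names(wc), vapply(wc, function(x) length(x$counts),
                                 integer(1)))
  scale <- genomicReads(chip) / genomicReads(input)
  # local null mean: centered running mean of the input window counts,
  # truncated at chromosome ends, scaled to one test window
  half <- (inputWindow %/% window - 1L) %/% 2L
  hw <- half * (window %/% step)
  localInput <- unlist(lapply(wi, function(x) {
    n <- length(x$counts)
    if (n == 0L) return(numeric(0))
    cs <- cumsum(c(0, x$counts))
    i <- seq_len(n)
    lo <- pmax(i - hw, 1L); hi <- pmin(i + hw, n)
    # neighbouring stepped windows overlap; dividing the summed counts by
    # the number of windows keeps the estimate on the one-window scale
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }), use.names = FALSE)
  muRaw <- localInput * scale
  mu <- pmax(muRaw, pseudoMean)
  size <- if (identical(nbSize, "auto")) {
    # Predictive dispersion from the chip-minus-scaled-input residuals:
    # the mu^2/size term absorbs both the chip counting noise beyond
    # Poisson and the sampling noise of the input-based mean. Two-pass
    # robust fit: moments on all windows first, then windows that look
    # enriched at a loose threshold are dropped and the fit repeated so
    # genuine peaks cannot inflate the null variance.
    resid <- chipCount - muRaw
    fitSize <- function(keep) {
      extra <- var(resid[keep]) - mean(chipCount[keep])
      if (is.finite(extra) && extra > 0)
        mean(muRaw[keep])^2 / extra else 1e8
    }
    s1 <- fitSize(rep(TRUE, length(resid)))
    p1 <- pnbinom(chipCount - 1, size = s1, mu = mu, lower.tail = FALSE)
    fitSize(p1 > 1e-3)
  } else if (identical(nbSize, "input")) {
    m <- mean(inputCount); v <- var(inputCount)
    if (v > m) m^2 / (v - m) else 1e8
  } else as.numeric(nbSize)
  p <- pnbinom(chipCount - 1, size = size, mu = mu, lower.tail = FALSE)
  p[chipCount == 0] <- 1
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, width = window),
                seqinfo = Seqinfo(names(chromSizes), unname(chromSizes)))
  S4Vectors::mcols(gr)$chipCount <- chipCount
  S4Vectors::mcols(gr)$inputCount <- inputCount
  S4Vectors::mcols(gr)$pValue <- p
  S4Vectors::mcols(gr)$significant <- p <= alpha
  S4Vectors::metadata(gr) <- list(window = window, step = step,
                                  alpha = alpha, nbSize = size,
                                  scale = scale, pseudoMean = pseudoMean)
  gr
}

#' Merge significant windows into peak regions
#'
#' Unions overlapping significant windows (overlapping stepped windows are
#' resolved here, so `step < window` never double-reports) and then merges
#' resulting intervals separated by at most `maxGap` bp. Each region's
#' score is the minimum p-value among its member windows.
#'
#' @param stats window `GRanges` from [windowScan()].
#' @param maxGap maximum gap to bridge, in bp (default 1000).
#' @return `GRanges` of peak regions with metadata column `pValue`.
#' @export
mergeWindows <- function(stats, maxGap = 1000L) {
  sig <- stats[S4Vectors::mcols(stats)$significant]
  if (length(sig) == 0L)
    return(GRanges(seqinfo = GenomeInfoDb::seqinfo(stats)))
  merged <- GenomicRanges::reduce(sig, min.gapwidth = maxGap + 1L)
  hit <- GenomicRanges::findOverlaps(merged, sig)
  pmin <- tapply(S4Vectors::mcols(sig)$pValue[S4Vectors::subjectHits(hit)],
                 S4Vectors::queryHits(hit), min)
  S4Vectors::mcols(merged)$pValue <- as.numeric(pmin)
  merged
}

#' Intersect peak sets to define joint targets
#'
#' Returns the maximal intervals covered by at least one peak from every
#' supplied set — the rule used to call regions joint targets of several
#' factors (e.g. Polycomb components plus H3K27me3).
#'
#' @param peaksets list of >= 2 peak `GRanges`.
#' @return `GRanges` of the common coverage.
#' @export
intersectTargets <- function(peaksets) {
  if (length(peaksets) < 2L) stop("need >= 2 peak sets")
  Reduce(function(a, b)
    GenomicRanges::intersect(GenomicRanges::granges(a),
                             GenomicRanges::granges(b),
                             ignore.strand = TRUE),
    peaksets)
}

#' Write peak regions as BED
#' @param peaks `GRanges` with optional `pValue` metadata (written to the
#'   score column as -log10 p, capped at 1000).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePeaksBed <- function(peaks, path) {
  p <- S4Vectors::mcols(peaks)$pValue
  score <- if (is.null(p)) rep(0, length(peaks)) else
    pmin(round(-log10(pmax(p, 1e-300)), 2), 1000)
  write.table(data.frame(as.character(GenomeInfoDb::seqnames(peaks)),
                         BiocGenerics::start(peaks) - 1L,
                         BiocGenerics::end(peaks),
                         paste0("peak_", seq_along(peaks)), score),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
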