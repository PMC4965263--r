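#' Smooth a turnover track with a sliding window
#'
#' Centered moving average of TI over `windowBins` bins within each
#' chromosome, so a high bin is only retained when its neighbors also turn
#' over quickly. Edge bins use truncated windows; chromosomes shorter than
#' the window pass through unsmoothed with a warning.
#'
#' @param track a [TurnoverTrack].
#' @param windowBins odd window size in bins (default 3).
#' @return A smoothed [TurnoverTrack] (slope/kendallP unset).
#' @export
smoothTI <- function(track, windowBins = 3L) {
  if (windowBins %% 2L != 1L) stop("windowBins must be odd")
  gb <- genomeBins(track)
  npc <- .binsPerChrom(gb)
  ti <- tiValues(track)
  out <- numeric(length(ti))
  h <- (windowBins - 1L) %/% 2L
  pos <- 0L
  for (ci in seq_along(npc)) {
    n <- npc[ci]
    x <- ti[pos + seq_len(n)]
    if (n < windowBins) {
      warning("chromosome ", names(gb@seqlengths)[ci],
              " shorter than the smoothing window; left unsmoothed")
      out[pos + seq_len(n)] <- x
    } else {
      cs <- cumsum(c(0, x))
      i <- seq_len(n)
      lo <- pmax(i - h, 1L)
      hi <- pmin(i + h, n)
      out[pos + i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    pos <- pos + n
  }
  TurnoverTrack(gb, ti = out, mask = coverageMask(track))
}

#' Select the highest-turnover bins
#'
#' Removes blacklisted and uncovered bins, ranks the remainder by TI
#' (descending; ties broken by ascending chromosome then start so the
#' selection is reproducible), and returns exactly `n` bins. Pass a
#' smoothed track (see [smoothTI()]) to require neighborhood support, as
#' in the standard procedure.
#'
#' @param track a [TurnoverTrack] (typically smoothed).
#' @param n number of bins to select (default 1000).
#' @param blacklist optional `GRanges`; overlapping bins are removed
#'   before ranking (a reproducible stand-in for manual repeat removal).
#' @param mergeAdjacent merge touching selected bins into regions
#'   (score = max member TI).
#' @return `GRanges` of the selected bins in genome order, with metadata
#'   columns `score` (TI) and `rank`.
#' @export
topRegions <- function(track, n = 1000L, blacklist = NULL,
                       mergeAdjacent = FALSE) {
  gb <- genomeBins(track)
  gr <- binRanges(gb)
  eligible <- coverageMask(track)
  if (!is.null(blacklist) && length(blacklist) > 0)
    eligible <- eligible &
      GenomicRanges::countOverlaps(gr, blacklist) == 0L
  if (n > sum(eligible))
    stop("n = ", n, " exceeds the ", sum(eligible), " eligible bins")
  ti <- tiValues(track)
  idx <- which(eligible)
  ord <- idx[order(-ti[idx],
                   as.integer(match(as.character(GenomeInfoDb::seqnames(gr)[idx]),
                                    names(gb@seqlengths))),
                   BiocGenerics::start(gr)[idx])]
  sel <- ord[seq_len(n)]
  out <- gr[sel]
  S4Vectors::mcols(out)$score <- ti[sel]
  S4Vectors::mcols(out)$rank <- seq_len(n)
  out <- out[order(match(as.character(GenomeInfoDb::seqnames(out)),
                         names(gb@seqlengths)), BiocGenerics::start(out))]
  if (mergeAdjacent) {
    red <- GenomicRanges::reduce(out)
    hit <- GenomicRanges::findOverlaps(red, out)
    sc <- tapply(S4Vectors::mcols(out)$score[S4Vectors::subjectHits(hit)],
                 S4Vectors::queryHits(hit), max)
    S4Vectors::mcols(red)$score <- as.numeric(sc)
    out <- red
  }
  out
}

#' Resampling false discovery rate of a top-region selection
#'
#' The detection threshold is the minimum TI in the selected set. In each
#' of `nTests` trials, `nDraw` covered bins are drawn uniformly (without
#' replacement by default) and the fraction exceeding the threshold is
#' recorded; the maximum fraction across trials is returned as the FDR, a
#' deliberately conservative choice.
#'
#' @param track the [TurnoverTrack] the selection was made from (same
#'   smoothing).
#' @param top `GRanges` from [topRegions()] (metadata column `score`).
#' @param nDraw bins per random draw (default 1000).
#' @param nTests number of trials (default 100).
#' @param replace draw with replacement (default `FALSE`).
#' @param seed optional integer seed.
#' @return The FDR (numeric scalar), with attributes `threshold` and
#'   `fractions` (the per-trial fractions).
#' @export
empiricalFdr <- function(track, top, nDraw = 1000L, nTests = 100L,
                         replace = FALSE, seed = NULL) {
  if (length(top) == 0L) stop("top set must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  threshold <- min(S4Vectors::mcols(top)$score)
  pool <- tiValues(track)[coverageMask(track)]
  if (!replace && nDraw > length(pool))
    stop("nDraw exceeds the number of covered bins")
  fractions <- vapply(seq_len(nTests), function(i)
    mean(sample(pool, nDraw, replace = replace) > threshold), numeric(1))
  out <- max(fractions)
  attr(out, "threshold") <- threshold
  attr(out, "fractions") <- fractions
  out
}

#' Feature overrepresentation of a region set
#'
#' For each annotation feature, compares the proportion of the query
#' regions overlapping the feature (>= 1 bp) with the proportion of all
#' genome bins overlapping it, reported as a log2 ratio. Regions may count
#' toward several features. Proportions of zero yield a missing log2
#' ratio, never 0.
#'
#' @param set query `GRanges` (e.g. top-turnover bins).
#' @param features named list of annotation `GRanges`.
#' @param bins [GenomeBins] defining the genome-wide background.
#' @return `data.frame` with columns `feature`, `propInSet`,
#'   `propInGenome`, `log2Ratio`, `countInSet`.
#' @export
featureOverrepresentation <- function(set, features, bins) {
  gr <- binRanges(bins)
  rows <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    cnt <- if (length(f) == 0L) 0L else
      sum(GenomicRanges::countOverlaps(set, f) > 0L)
    pSet <- cnt / length(set)
    pGen <- if (length(f) == 0L) 0 else
      mean(GenomicRanges::countOverlaps(gr, f) > 0L)
    l2 <- if (pSet > 0 && pGen > 0) log2(pSet / pGen) else NA_real_
    data.frame(feature = nm, propInSet = pSet, propInGenome = pGen,
               log2Ratio = l2, countInSet = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# uniform re-placement of regions on the workspace, preserving widths
.randomPlacement <- function(widths, seqlen) {
  avail <- pmax(as.numeric(seqlen) - max(widths) + 1, 0)
  if (all(avail <= 0)) stop("workspace smaller than the widest query region")
  ci <- sample.int(length(seqlen), length(widths), replace = TRUE,
                   prob = as.numeric(seqlen))
  maxS <- unname(seqlen[ci]) - widths
  bad <- maxS < 0
  while (any(bad)) {
    ci[bad] <- sample.int(length(seqlen), sum(bad), replace = TRUE,
                          prob = as.numeric(seqlen))
    maxS <- unname(seqlen[ci]) - widths
    bad <- maxS < 0
  }
  s0 <- floor(runif(length(widths)) * (maxS + 1))
  GRanges(names(seqlen)[ci], IRanges(start = s0 + 1, width = widths))
}

#' Permutation test for query-target proximity
#'
#' Counts the query regions overlapping (or lying within `distanceBp` of,
#' edge-to-edge) any target region, then builds a null by re-placing the
#' query regions uniformly at random on the workspace (widths preserved)
#' `nPerm` times. The p-value uses the add-one correction
#' `p = (1 + #{perm >= observed}) / (1 + nPerm)` so it is never exactly 0.
#'
#' @param query query `GRanges` (e.g. unannotated changed regions).
#' @param targets target `GRanges` (e.g. robustly expressed genes).
#' @param workspace [GenomeBins] supplying the chromosome lengths for
#'   random placement.
#' @param mode `"overlap"` (>= 1 bp intersection) or `"within_distance"`.
#' @param distanceBp edge-to-edge distance for `"within_distance"`
#'   (default 50000).
#' @param nPerm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return List with elements `observed`, `pValue`, `expected` (mean null
#'   count) and `nPerm`.
#' @export
overlapSignificance <- function(query, targets, workspace,
                                mode = c("overlap", "within_distance"),
                                distanceBp = 50000L, nPerm = 1000L,
                                seed = NULL) {
  mode <- match.arg(mode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  seqlen <- workspace@seqlengths
  if (sum(as.numeric(BiocGenerics::width(query))) > sum(as.numeric(seqlen)))
    stop("workspace smaller than the total query length")
  if (!is.null(seed)) set.seed(seed)
  if (length(targets) == 0L || length(query) == 0L)
    return(list(observed = 0L, pValue = 1, expected = 0, nPerm = nPerm))
  # "within distance d" == overlap with targets grown by d on each side
  grown <- if (mode == "overlap") GenomicRanges::granges(targets) else
    suppressWarnings(GenomicRanges::trim(
      GenomicRanges::resize(GenomicRanges::granges(targets),
                            BiocGenerics::width(targets) +
                              2L * (distanceBp + 1L),
                            fix = "center")))
  observed <- sum(GenomicRanges::countOverlaps(query, grown,
                                               ignore.strand = TRUE) > 0L)
  # all permutations placed in one batch, counted per permutation
  w <- BiocGenerics::width(query)
  allW <- rep(w, nPerm)
  perm <- .randomPlacement(allW, seqlen)
  hitAny <- GenomicRanges::countOverlaps(perm, grown,
                                         ignore.strand = TRUE) > 0L
  permId <- rep(seq_len(nPerm), each = length(query))
  nullCounts <- as.integer(rowsum(as.integer(hitAny), permId))
  list(observed = observed,
       pValue = (1 + sum(nullCounts >= observed)) / (1 + nPerm),
       expected = mean(nullCounts), nPerm = nPerm)
}
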