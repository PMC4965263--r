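#' MNase-titration accessibility score (MACC)
#'
#' Per bin, fits an ordinary least-squares line of normalized signal
#' against log2 of the MNase concentration (the titration is geometric:
#' 1, 4, 16, 64 U) and reports minus the slope, so loci whose signal grows
#' as digestion weakens — easily digested, accessible chromatin — score
#' positive. Bins with coverage at fewer than three titration points get a
#' missing value.
#'
#' @param titration named list of [BinnedTrack]s in RPM units, one per
#'   concentration; names must parse as the enzyme units (e.g. `"1"`,
#'   `"4"`, or `"u1"`, `"u4"`).
#' @return A [MaccTrack] with per-bin `macc` and fit `r2`.
#' @examples
#' gb <- GenomeBins(c(chr1 = 1000))
#' tr <- function(v) BinnedTrack(gb, v, "rpm")
#' tit <- list(u1 = tr(10), u4 = tr(8), u16 = tr(6), u64 = tr(4))
#' maccValues(computeMacc(tit))  # exactly +1
#' @export
computeMacc <- function(titration) {
  if (length(titration) < 3L) stop("need >= 3 MNase concentrations")
  units <- suppressWarnings(as.numeric(sub("^[uU]", "", names(titration))))
  if (any(is.na(units)))
    stop("titration names must encode the enzyme units (e.g. u1, u4)")
  b0 <- genomeBins(titration[[1L]])
  for (tr in titration)
    if (!.sameBins(genomeBins(tr), b0)) stop("tracks are on different bins")
  Y <- do.call(cbind, lapply(titration, trackValues))
  x <- log2(units)
  n <- nBins(b0)
  macc <- rep(NA_real_, n)
  r2 <- rep(NA_real_, n)
  covered <- Y > 0
  # group bins by coverage pattern; fit each pattern's bins in one shot
  patt <- covered %*% (2^(seq_along(units) - 1))
  for (pv in unique(patt[, 1L])) {
    use <- which(patt[, 1L] == pv)
    cols <- which(bitwAnd(as.integer(pv), as.integer(2^(seq_along(units) - 1))) > 0)
    if (length(cols) < 3L) next
    xs <- x[cols]
    xc <- xs - mean(xs)
    Ys <- Y[use, cols, drop = FALSE]
    ym <- rowMeans(Ys)
    sxy <- as.numeric((Ys - ym) %*% xc)
    slope <- sxy / sum(xc^2)
    sst <- rowSums((Ys - ym)^2)
    ssr <- slope^2 * sum(xc^2)
    macc[use] <- -slope
    r2[use] <- ifelse(sst > 0, ssr / sst, NA_real_)
  }
  MaccTrack(b0, macc = macc, r2 = r2)
}

#' Correlate turnover and accessibility over a region set
#'
#' Computes the per-region mean of each track over covered bins (TI over
#' coverage-masked bins, MACC over bins with a defined value), drops
#' regions without a usable value in either track, and returns the Pearson
#' correlation across regions.
#'
#' @param ti a [TurnoverTrack].
#' @param macc a [MaccTrack] on identical bins.
#' @param regions `GRanges` of regions (>= 3 usable required).
#' @return List with `r` (Pearson correlation), `nRegions` (used),
#'   `nDropped`, and `regionMeans` (`data.frame` of the paired means).
#' @export
correlateTracks <- function(ti, macc, regions) {
  if (!.sameBins(genomeBins(ti), genomeBins(macc)))
    stop("tracks are on different bins")
  if (length(regions) == 0L) stop("regions must be non-empty")
  gr <- binRanges(genomeBins(ti))
  hit <- GenomicRanges::findOverlaps(regions, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  tiv <- tiValues(ti); tim <- coverageMask(ti)
  mav <- maccValues(macc)
  meanBy <- function(v, ok) {
    keep <- ok[s]
    tapply(v[s[keep]], q[keep], mean)
  }
  mTi <- meanBy(tiv, tim)
  mMa <- meanBy(mav, !is.na(mav))
  common <- intersect(names(mTi), names(mMa))
  nDropped <- length(regions) - length(common)
  if (length(common) < 3L) stop("fewer than 3 regions with usable values")
  df <- data.frame(region = as.integer(common),
                   meanTI = as.numeric(mTi[common]),
                   meanMACC = as.numeric(mMa[common]))
  list(r = cor(df$meanTI, df$meanMACC), nRegions = nrow(df),
       nDropped = nDropped, regionMeans = df)
}
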