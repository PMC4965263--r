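# ---- Kendall trend test ------------------------------------------------
#
# The shrinkage weight of the turnover index is a two-sided Kendall rank
# correlation p-value of signal against chase time. Time points are
# strictly increasing and untied, so the only permutation-varying factor of
# tau-b is the numerator S = sum_{i<j} sign(y_j - y_i); for n <= 8 the
# exact null is enumerated over all n! orderings of the observed values
# (ties handled naturally: the tie multiset, hence the tau-b denominator,
# is permutation invariant). Beyond n = 8 a tie-corrected normal
# approximation is used.

# all permutations of seq_len(n) as an (n! x n) index matrix
.permIndex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permIndex(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

.pairIdx <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ij[, 1L], j = ij[, 2L])
}

# S statistic for rows of a matrix of y-values (x implicit, ascending)
.kendallS <- function(Y) {
  n <- ncol(Y)
  pr <- .pairIdx(n)
  S <- numeric(nrow(Y))
  for (k in seq_along(pr$i))
    S <- S + sign(Y[, pr$j[k]] - Y[, pr$i[k]])
  S
}

# exact two-sided permutation p for one value vector (n <= 8)
.kendallExactP <- function(y) {
  n <- length(y)
  P <- .permIndex(n)
  Sall <- .kendallS(matrix(y[t(P)], nrow(P), n, byrow = TRUE))
  sObs <- .kendallS(matrix(y, 1L, n))
  mean(abs(Sall) >= abs(sObs) - 1e-9)
}

# tie-corrected normal approximation (x untied)
.kendallNormalP <- function(y) {
  n <- length(y)
  sObs <- .kendallS(matrix(y, 1L, n))
  t <- as.numeric(table(y))
  v <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs(sObs) / sqrt(v))
}

#' Two-sided Kendall trend p-value
#'
#' Exact by enumeration of all `n!` orderings for `n <= 8` observations
#' (24 orderings for the standard 4-point chase), tie-corrected normal
#' approximation beyond. The abscissa is assumed strictly increasing
#' (ordered time points), so only the values matter.
#'
#' @param y numeric vector of values at strictly increasing time points.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' kendallTrendP(c(8, 6, 4, 2))  # perfect decreasing trend: 2/24
#' @export
kendallTrendP <- function(y) {
  if (length(y) < 3L) stop("need >= 3 observations")
  if (length(y) <= 8L) .kendallExactP(y) else .kendallNormalP(y)
}

# vectorized p-values for rows of Y, exact path grouped by rank pattern
.kendallPMatrix <- function(Y) {
  n <- ncol(Y)
  if (n > 8L) return(apply(Y, 1L, .kendallNormalP))
  R <- matrixRank(Y)
  key <- do.call(paste, c(as.data.frame(R), sep = ","))
  uk <- unique(key)
  P <- .permIndex(n)
  pr <- .pairIdx(n)
  pLookup <- vapply(uk, function(k) {
    r <- as.numeric(strsplit(k, ",", fixed = TRUE)[[1L]])
    Sall <- .kendallS(matrix(r[t(P)], nrow(P), n, byrow = TRUE))
    sObs <- .kendallS(matrix(r, 1L, n))
    mean(abs(Sall) >= abs(sObs) - 1e-9)
  }, numeric(1))
  unname(pLookup[match(key, uk)])
}

# row-wise midranks of a matrix
matrixRank <- function(Y) {
  n <- ncol(Y)
  R <- matrix(0, nrow(Y), n)
  for (a in seq_len(n)) {
    ra <- rep(1, nrow(Y))
    for (b in seq_len(n)) {
      if (a == b) next
      ra <- ra + (Y[, b] < Y[, a]) + 0.5 * (Y[, b] == Y[, a])
    }
    R[, a] <- ra
  }
  R
}

# ---- spike-in scaling --------------------------------------------------

#' Spike-in consistency scaling across a time course
#'
#' A fixed quantity of exogenous spike-in DNA is added per library, so the
#' ratio of genomic to spike-in reads tracks the amount of labeled genomic
#' material recovered at each chase time. The relative read level of time
#' point t is `(genomic(t)/spike(t)) / (genomic(0)/spike(0))`; a labeled
#' pool decaying globally gives values falling below 1. Non-monotone decay
#' is reported as a QC flag, not an error.
#'
#' @param libraries `data.frame` with columns `timepoint`, `genomicReads`,
#'   `spikeReads`, or a list of [FragmentSet]s together with `timepoints`.
#' @param timepoints hours, required when `libraries` is a list of
#'   [FragmentSet]s.
#' @return `data.frame` with columns `timepoint`, `genomicReads`,
#'   `spikeReads`, `relativeReads`, ordered by time, with attribute
#'   `monotone` (logical QC flag: relative reads non-increasing in time).
#' @examples
#' spikeInScaling(data.frame(timepoint = c(0, 12),
#'                           genomicReads = c(1e6, 2.5e5),
#'                           spikeReads = c(1e4, 1e4)))
#' @export
spikeInScaling <- function(libraries, timepoints = NULL) {
  if (is.list(libraries) && !is.data.frame(libraries)) {
    stopifnot(!is.null(timepoints))
    libraries <- data.frame(
      timepoint = timepoints,
      genomicReads = vapply(libraries, genomicReads, numeric(1)),
      spikeReads = vapply(libraries, spikeInReads, numeric(1)))
  }
  df <- libraries[order(libraries$timepoint), , drop = FALSE]
  if (!any(df$timepoint == 0)) stop("a 0 hr library is required")
  if (any(df$spikeReads <= 0)) stop("spikeReads must be > 0 for all libraries")
  ratio <- df$genomicReads / df$spikeReads
  df$relativeReads <- ratio / ratio[df$timepoint == 0][1L]
  attr(df, "monotone") <- !is.unsorted(rev(df$relativeReads))
  rownames(df) <- NULL
  df
}

# ---- turnover index ----------------------------------------------------

#' Compute the per-bin turnover index from a time course
#'
#' For every genome bin, the input-subtracted RPM signal at the chase time
#' points is fitted by ordinary least squares against time. The slope is
#' shrunk by multiplying with one minus the two-sided Kendall trend
#' p-value, which pulls poorly supported fits toward zero, and the sign is
#' reversed so that decaying signal (fast turnover) scores positive:
#' `TI = -slope * (1 - p)`. Bins with no signal at any time point get
#' `TI = 0`, `p = 1` and are flagged in the coverage mask so genome-wide
#' tracks stay aligned.
#'
#' @param tc a [TimeCourse] (>= 3 time points, hours).
#' @return A [TurnoverTrack] with per-bin `ti`, raw `slope`, `kendallP`
#'   and coverage `mask`.
#' @examples
#' gb <- GenomeBins(c(chr1 = 2000))
#' tr <- function(v) BinnedTrack(gb, v, "rpm_minus_input")
#' tc <- TimeCourse(c(0, 3, 6, 12),
#'                  list(tr(c(8, 5)), tr(c(6, 5)), tr(c(4, 5)), tr(c(2, 5))))
#' tiValues(computeTI(tc))
#' @export
computeTI <- function(tc) {
  stopifnot(is(tc, "TimeCourse"))
  tp <- timepoints(tc)
  Y <- do.call(cbind, lapply(tracks(tc), trackValues))
  xc <- tp - mean(tp)
  slope <- as.numeric(Y %*% xc) / sum(xc^2)
  p <- .kendallPMatrix(Y)
  mask <- rowSums(Y != 0) > 0
  slope[!mask] <- 0
  p[!mask] <- 1
  ti <- -slope * (1 - p)
  TurnoverTrack(genomeBins(tc), ti = ti, slope = slope, kendallP = p,
                mask = mask)
}

#' Average turnover tracks across replicates
#'
#' Per-bin arithmetic mean of TI (and of the raw slope); the Kendall
#' p-value is replicate-specific and is left unset on the averaged track.
#' The coverage mask is the conjunction of the replicate masks, so a bin is
#' considered covered only when every replicate saw signal.
#'
#' @param tracksList list of [TurnoverTrack]s on identical bins.
#' @return A replicate-mean [TurnoverTrack].
#' @export
averageReplicates <- function(tracksList) {
  if (length(tracksList) < 1L) stop("need >= 1 track")
  b0 <- genomeBins(tracksList[[1L]])
  for (tr in tracksList)
    if (!.sameBins(genomeBins(tr), b0)) stop("tracks are on different bins")
  ti <- rowMeans(do.call(cbind, lapply(tracksList, tiValues)))
  slope <- rowMeans(do.call(cbind, lapply(tracksList, slopeValues)))
  mask <- Reduce(`&`, lapply(tracksList, coverageMask))
  TurnoverTrack(b0, ti = ti, slope = slope,
                kendallP = rep(NA_real_, length(ti)), mask = mask)
}

#' Pairwise replicate concordance of turnover tracks
#'
#' Pearson correlation of TI between all pairs of replicates, over bins
#' covered in every replicate (optionally further restricted to bins whose
#' mean absolute TI exceeds `minSignal`). A zero-variance track yields
#' `NA` against all others.
#'
#' @param tracksList list of >= 2 [TurnoverTrack]s on identical bins.
#' @param minSignal minimum mean |TI| for a bin to enter the correlation
#'   (default 0 = all covered bins).
#' @return Symmetric matrix of Pearson r values.
#' @export
replicateConcordance <- function(tracksList, minSignal = 0) {
  if (length(tracksList) < 2L) stop("need >= 2 tracks")
  b0 <- genomeBins(tracksList[[1L]])
  for (tr in tracksList)
    if (!.sameBins(genomeBins(tr), b0)) stop("tracks are on different bins")
  M <- do.call(cbind, lapply(tracksList, tiValues))
  keep <- Reduce(`&`, lapply(tracksList, coverageMask)) &
    rowMeans(abs(M)) >= minSignal
  M <- M[keep, , drop = FALSE]
  k <- ncol(M)
  out <- diag(1, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (sd(M[, i]) == 0 || sd(M[, j]) == 0) {
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      out[i, j] <- out[j, i] <- cor(M[, i], M[, j])
    }
  }
  ids <- paste0("rep", seq_len(k))
  dimnames(out) <- list(ids, ids)
  out
}

#' Write a turnover track as TSV (and optionally BEDGraph)
#'
#' TSV columns: chrom, start (0-based), end, ti, slope, kendall_p, mask.
#'
#' @param track a [TurnoverTrack].
#' @param path TSV output path.
#' @param bedgraph optional BEDGraph path for the TI values.
#' @return Invisibly, `path`.
#' @export
writeTurnoverTsv <- function(track, path, bedgraph = NULL) {
  gr <- binRanges(genomeBins(track))
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    ti = tiValues(track),
    slope = slopeValues(track),
    kendall_p = kendallP(track),
    mask = as.integer(coverageMask(track)))
  data.table::fwrite(dt, path, sep = "\t")
  if (!is.null(bedgraph))
    writeBedGraph(BinnedTrack(genomeBins(track), tiValues(track),
                              "rpm_minus_input"), bedgraph)
  invisible(path)
}
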