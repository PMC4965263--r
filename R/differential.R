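# Newton inversion of the trigamma function (for the method-of-moments
# fit of the variance-prior degrees of freedom)
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated test for differential turnover
#'
#' Per bin, the difference of replicate-mean TI between two conditions is
#' tested with a moderated t statistic: the pooled per-bin sample variance
#' (d = nA + nB - 2 df) is shrunk toward a genome-wide prior variance
#' `s0^2` with prior degrees of freedom `d0`, both estimated by method of
#' moments on the distribution of log pooled variances across covered
#' bins (matching the mean and variance of log s^2 under the scaled-F
#' model). The moderated variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the two-sided p-value comes from a
#' t distribution with `d0 + d` degrees of freedom.
#'
#' Bins lacking coverage in any replicate are excluded from the
#' hyperparameter fit (and flagged `covered = FALSE`); statistics are still
#' reported for them.
#'
#' @param repsA,repsB lists of >= 2 [TurnoverTrack] replicates per
#'   condition, all on identical bins.
#' @param d0,s02 optional fixed hyperparameters overriding the
#'   method-of-moments fit (`d0 = Inf` forces complete shrinkage to
#'   `s02`).
#' @return `data.frame` with one row per bin: `chrom`, `start` (0-based),
#'   `end`, `diff` (mean A - mean B), `t`, `pValue`, `s2`, `covered`;
#'   attribute `hyper` holds `list(d0, s02, dfPooled)`.
#' @export
moderatedTest <- function(repsA, repsB, d0 = NULL, s02 = NULL) {
  if (length(repsA) < 2L || length(repsB) < 2L)
    stop("need >= 2 replicates per condition")
  b0 <- genomeBins(repsA[[1L]])
  for (tr in c(repsA, repsB))
    if (!.sameBins(genomeBins(tr), b0)) stop("tracks are on different bins")
  A <- do.call(cbind, lapply(repsA, tiValues))
  B <- do.call(cbind, lapply(repsB, tiValues))
  nA <- ncol(A); nB <- ncol(B)
  d <- nA + nB - 2L
  mA <- rowMeans(A); mB <- rowMeans(B)
  diff <- mA - mB
  s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / d
  covered <- Reduce(`&`, lapply(c(repsA, repsB), coverageMask))
  if (is.null(d0) || is.null(s02)) {
    z <- log(s2[covered & s2 > 0])
    if (length(z) < 2L)
      stop("cannot fit variance prior: all (covered) bins have zero ",
           "pooled variance")
    evar <- var(z) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0fit <- 2 * .trigammaInverse(evar)
      s02fit <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                      digamma(d0fit / 2) - log(d0fit / 2))
    } else {
      d0fit <- Inf
      s02fit <- exp(mean(z) - digamma(d / 2) + log(d / 2))
    }
    if (is.null(d0)) d0 <- d0fit
    if (is.null(s02)) s02 <- s02fit
  }
  sTilde2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(sTilde2 * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, diff / se, 0)
  p <- 2 * pt(-abs(t), df = d0 + d)
  gr <- binRanges(b0)
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    diff = diff, t = t, pValue = p, s2 = s2,
                    covered = covered, stringsAsFactors = FALSE)
  attr(out, "hyper") <- list(d0 = d0, s02 = s02, dfPooled = d)
  out
}

#' Select bins with changed turnover
#'
#' Joint selection rule: a bin is called changed when its TI difference
#' reaches the extreme quantile of the genome-wide difference distribution
#' AND its moderated p-value is at most `pMax`. `mode = "absolute"`
#' (default) thresholds |diff| at its `1 - q` quantile; `mode = "signed"`
#' uses the `1 - q` upper and `q` lower quantiles of the signed
#' difference. Quantiles are computed over covered bins only.
#'
#' @param result `data.frame` from [moderatedTest()].
#' @param q tail fraction (default 0.025, i.e. the 0.975 quantile).
#' @param pMax p-value cutoff (default 0.01).
#' @param mode `"absolute"` or `"signed"` quantile thresholding.
#' @param quantilePool `"all"` (default) computes the difference quantile
#'   over every bin, uncovered bins contributing their zero difference;
#'   `"covered"` restricts the pool to covered bins. Only covered bins are
#'   ever selected. The genome-wide pool keeps the implied selection
#'   budget at `q` of the genome rather than `q` of the covered subset.
#' @return The input `data.frame` with added columns `selected` (logical)
#'   and `direction` (`"up_in_A"` / `"up_in_B"` / `NA`); attributes
#'   `threshold` and `counts` (selected per direction).
#' @export
selectChanged <- function(result, q = 0.025, pMax = 0.01,
                          mode = c("absolute", "signed"),
                          quantilePool = c("all", "covered")) {
  mode <- match.arg(mode)
  quantilePool <- match.arg(quantilePool)
  dd <- if (quantilePool == "all") result$diff else
    result$diff[result$covered]
  if (mode == "absolute") {
    thr <- quantile(abs(dd), 1 - q, names = FALSE)
    pass <- abs(result$diff) >= thr
    threshold <- c(abs = thr)
  } else {
    hi <- quantile(dd, 1 - q, names = FALSE)
    lo <- quantile(dd, q, names = FALSE)
    pass <- result$diff >= hi | result$diff <= lo
    threshold <- c(upper = hi, lower = lo)
  }
  result$selected <- pass & result$pValue <= pMax & result$covered
  result$direction <- ifelse(result$selected,
                             ifelse(result$diff > 0, "up_in_A", "up_in_B"),
                             NA_character_)
  attr(result, "threshold") <- threshold
  attr(result, "counts") <- c(up_in_A = sum(result$direction == "up_in_A",
                                            na.rm = TRUE),
                              up_in_B = sum(result$direction == "up_in_B",
                                            na.rm = TRUE))
  result
}

#' Selected bins as genomic ranges
#'
#' @param result `data.frame` from [selectChanged()].
#' @return `GRanges` of the selected bins with `diff`, `pValue` and
#'   `direction` metadata.
#' @export
selectedRegions <- function(result) {
  sel <- result[result$selected %in% TRUE, , drop = FALSE]
  gr <- GRanges(sel$chrom, IRanges(start = sel$start + 1L, end = sel$end))
  S4Vectors::mcols(gr)$diff <- sel$diff
  S4Vectors::mcols(gr)$pValue <- sel$pValue
  S4Vectors::mcols(gr)$direction <- sel$direction
  gr
}

#' Regions with no gene or enhancer annotation
#'
#' Returns the subset of changed/selected regions with zero bp overlap
#' with either the (extended) gene set or the enhancer set — the
#' candidates for unannotated regulatory elements.
#'
#' @param changed `GRanges` of changed regions.
#' @param genesExtended `GRanges` of gene bodies (optionally extended).
#' @param enhancers `GRanges` of enhancers.
#' @return The unannotated subset of `changed`.
#' @export
classifyUnannotated <- function(changed, genesExtended, enhancers) {
  anno <- c(GenomicRanges::granges(genesExtended),
            GenomicRanges::granges(enhancers))
  if (length(anno) == 0L) return(changed)
  changed[GenomicRanges::countOverlaps(changed, anno,
                                       ignore.strand = TRUE) == 0L]
}
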