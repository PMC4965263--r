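#' Fixed-width partition of a genome into bins
#'
#' Bins are half-open `[i*binSize, (i+1)*binSize)` intervals in 0-based
#' coordinates, tiled per chromosome; the last bin of each chromosome is
#' truncated at the chromosome end. The bin count is a deterministic
#' function of the chromosome sizes and the bin width.
#'
#' @slot seqlengths named integer vector of chromosome lengths (bp).
#' @slot binSize integer bin width in bp.
#' @export
setClass("GenomeBins",
         representation(seqlengths = "integer", binSize = "integer"))

setValidity("GenomeBins", function(object) {
  sl <- object@seqlengths
  if (length(sl) == 0L) return("seqlengths must be non-empty")
  if (is.null(names(sl)) || anyDuplicated(names(sl)) || any(!nzchar(names(sl))))
    return("seqlengths must have unique non-empty names")
  if (any(is.na(sl)) || any(sl < 1L)) return("chromosome lengths must be >= 1")
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    return("binSize must be a positive integer scalar")
  TRUE
})

#' @param seqlengths named vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 1000, the resolution used for
#'   genome-wide turnover; 300 bp is supported for finer-scale work).
#' @return A `GenomeBins` object.
#' @rdname GenomeBins-class
#' @examples
#' gb <- GenomeBins(c(chr1 = 10000, chr2 = 5500), binSize = 1000)
#' nBins(gb)
#' @export
GenomeBins <- function(seqlengths, binSize = 1000L) {
  sl <- setNames(as.integer(seqlengths), names(seqlengths))
  new("GenomeBins", seqlengths = sl, binSize = as.integer(binSize))
}

# bins per chromosome, in seqlengths order
.binsPerChrom <- function(gb) {
  as.integer(ceiling(gb@seqlengths / as.numeric(gb@binSize)))
}

# 0-based global index offset of each chromosome's first bin
.binOffsets <- function(gb) {
  n <- .binsPerChrom(gb)
  setNames(cumsum(c(0L, n[-length(n)])), names(gb@seqlengths))
}

# global 1-based bin index for 0-based positions; NA for unknown chrom
.binIndex <- function(gb, chrom, pos0) {
  off <- .binOffsets(gb)
  unname(off[chrom]) + pos0 %/% gb@binSize + 1L
}

#' @rdname binSize
#' @export
setMethod("binSize", "GenomeBins", function(x) x@binSize)

#' @rdname nBins
#' @export
setMethod("nBins", "GenomeBins", function(x) sum(.binsPerChrom(x)))

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths Seqinfo
#' @rdname binRanges
#' @export
setMethod("binRanges", "GenomeBins", function(x) {
  npc <- .binsPerChrom(x)
  chrom <- rep(names(x@seqlengths), npc)
  s0 <- unlist(lapply(npc, function(n) seq_len(n) - 1L), use.names = FALSE) *
    x@binSize
  e <- pmin(s0 + x@binSize, rep(unname(x@seqlengths), npc))
  GRanges(chrom, IRanges(start = s0 + 1L, end = e),
          seqinfo = Seqinfo(names(x@seqlengths), unname(x@seqlengths)))
})

#' @rdname GenomeBins-class
#' @param object a `GenomeBins`.
#' @export
setMethod("show", "GenomeBins", function(object) {
  cat("GenomeBins:", length(object@seqlengths), "chromosome(s),",
      "bin size", object@binSize, "bp,", nBins(object), "bins\n")
})

setMethod("seqlengths", "GenomeBins", function(x) x@seqlengths)


#' Fragment intervals from one sequencing library
#'
#' Aligned fragment (paired-end insert) intervals from a single pulldown or
#' input library, kept unstranded. Reads mapping to spike-in contigs are
#' held apart from the genomic records: they enter `totalReads` and
#' `spikeInReads` but never the genomic fragment ranges, and the RPM
#' denominator is `totalReads - spikeInReads` so genomic signal stays
#' comparable across time points before any spike-in scaling.
#'
#' @slot fragments `GRanges` of genomic fragments (1-based closed, the
#'   Bioconductor convention; BED I/O converts from/to 0-based half-open).
#' @slot spikeFragments `GRanges` of spike-in contig fragments (may be
#'   empty even when `spikeInReads > 0`).
#' @slot totalReads numeric; total mapped reads (>= number of records).
#' @slot spikeInReads numeric; reads on spike-in contigs (0 if absent).
#' @slot label character; library label.
#' @export
setClass("FragmentSet",
         representation(fragments = "GRanges", spikeFragments = "GRanges",
                        totalReads = "numeric", spikeInReads = "numeric",
                        label = "character"))

setValidity("FragmentSet", function(object) {
  if (length(object@totalReads) != 1L || object@totalReads < 0)
    return("totalReads must be a non-negative scalar")
  if (length(object@spikeInReads) != 1L || object@spikeInReads < 0)
    return("spikeInReads must be a non-negative scalar")
  if (object@totalReads < length(object@fragments) + object@spikeInReads)
    return("totalReads must be >= genomic records + spikeInReads")
  TRUE
})

#' @param fragments `GRanges` of genomic fragments.
#' @param totalReads total mapped reads; defaults to
#'   `length(fragments) + spikeInReads`.
#' @param spikeInReads spike-in read count (default 0).
#' @param spikeFragments optional `GRanges` of spike-in fragments.
#' @param label library label.
#' @return A `FragmentSet`.
#' @rdname FragmentSet-class
#' @export
FragmentSet <- function(fragments, totalReads = NULL, spikeInReads = 0,
                        spikeFragments = GRanges(), label = "") {
  if (is.null(totalReads))
    totalReads <- length(fragments) + spikeInReads
  new("FragmentSet", fragments = fragments, spikeFragments = spikeFragments,
      totalReads = as.numeric(totalReads),
      spikeInReads = as.numeric(spikeInReads), label = label)
}

#' @rdname fragments
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)
#' @rdname totalReads
#' @export
setMethod("totalReads", "FragmentSet", function(x) x@totalReads)
#' @rdname spikeInReads
#' @export
setMethod("spikeInReads", "FragmentSet", function(x) x@spikeInReads)
#' @rdname genomicReads
#' @export
setMethod("genomicReads", "FragmentSet",
          function(x) x@totalReads - x@spikeInReads)

#' @rdname FragmentSet-class
#' @param object a `FragmentSet`.
#' @export
setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet", if (nzchar(object@label)) sQuote(object@label) else "",
      ": ", length(object@fragments), " genomic fragments, ",
      object@spikeInReads, " spike-in reads, ", object@totalReads,
      " total reads\n", sep = "")
})

#' Number of genomic fragment records
#' @param x a [FragmentSet].
#' @return Integer count of genomic fragments.
#' @export
nFragments <- function(x) length(fragments(x))


#' Per-bin numeric signal track
#'
#' One value per genome bin for a single sample: raw midpoint counts,
#' reads-per-million, or input-subtracted RPM.
#'
#' @slot bins the [GenomeBins] partition.
#' @slot values numeric vector, one value per bin.
#' @slot units `"raw"`, `"rpm"` or `"rpm_minus_input"`.
#' @export
setClass("BinnedTrack",
         representation(bins = "GenomeBins", values = "numeric",
                        units = "character"))

setValidity("BinnedTrack", function(object) {
  if (length(object@values) != nBins(object@bins))
    return("length(values) must equal the bin count")
  if (!object@units %in% c("raw", "rpm", "rpm_minus_input"))
    return("units must be raw, rpm or rpm_minus_input")
  if (object@units == "raw") {
    v <- object@values
    if (any(v < 0) || any(v != floor(v)))
      return("raw units require non-negative integer values")
  }
  TRUE
})

#' @param bins a [GenomeBins].
#' @param values numeric vector of per-bin values.
#' @param units value units.
#' @return A `BinnedTrack`.
#' @rdname BinnedTrack-class
#' @export
BinnedTrack <- function(bins, values, units = c("raw", "rpm",
                                                "rpm_minus_input")) {
  new("BinnedTrack", bins = bins, values = as.numeric(values),
      units = match.arg(units))
}

#' @rdname trackValues
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)
#' @rdname trackUnits
#' @export
setMethod("trackUnits", "BinnedTrack", function(x) x@units)
#' @rdname genomeBins
#' @export
setMethod("genomeBins", "BinnedTrack", function(x) x@bins)

#' @rdname BinnedTrack-class
#' @param object a `BinnedTrack`.
#' @export
setMethod("show", "BinnedTrack", function(object) {
  cat("BinnedTrack [", object@units, "]: ", nBins(object@bins), " bins, ",
      "mean ", signif(mean(object@values), 4), "\n", sep = "")
})

.sameBins <- function(a, b) {
  identical(a@binSize, b@binSize) && identical(a@seqlengths, b@seqlengths)
}


#' Input-subtracted time course for one replicate
#'
#' Ordered chase time points (hours, starting at 0) with one
#' input-subtracted RPM track per time point, all on identical bins. This
#' is the direct input to [computeTI()].
#'
#' @slot timepoints numeric hours, ascending, first element 0.
#' @slot tracks list of [BinnedTrack] (units `rpm_minus_input`).
#' @slot replicateId character replicate label.
#' @export
setClass("TimeCourse",
         representation(timepoints = "numeric", tracks = "list",
                        replicateId = "character"))

setValidity("TimeCourse", function(object) {
  tp <- object@timepoints
  if (length(tp) < 3L) return("need >= 3 time points")
  if (is.unsorted(tp, strictly = TRUE)) return("timepoints must be ascending")
  if (tp[1L] != 0) return("first time point must be 0 hr")
  if (length(object@tracks) != length(tp))
    return("one track per time point required")
  if (!all(vapply(object@tracks, is, logical(1), class2 = "BinnedTrack")))
    return("tracks must be BinnedTrack objects")
  b0 <- object@tracks[[1L]]@bins
  for (tr in object@tracks) {
    if (!.sameBins(tr@bins, b0)) return("all tracks must share the same bins")
    if (tr@units != "rpm_minus_input")
      return("tracks must be input-subtracted RPM (units rpm_minus_input)")
  }
  TRUE
})

#' @param timepoints numeric hours.
#' @param tracks list of input-subtracted [BinnedTrack]s.
#' @param replicateId replicate label.
#' @return A `TimeCourse`.
#' @rdname TimeCourse-class
#' @export
TimeCourse <- function(timepoints, tracks, replicateId = "rep1") {
  new("TimeCourse", timepoints = as.numeric(timepoints), tracks = tracks,
      replicateId = replicateId)
}

#' @rdname timepoints
#' @export
setMethod("timepoints", "TimeCourse", function(x) x@timepoints)
#' @rdname tracks
#' @export
setMethod("tracks", "TimeCourse", function(x) x@tracks)
#' @rdname genomeBins
#' @export
setMethod("genomeBins", "TimeCourse", function(x) x@tracks[[1L]]@bins)

#' @rdname TimeCourse-class
#' @param object a `TimeCourse`.
#' @export
setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse", sQuote(object@replicateId), ":",
      paste(object@timepoints, collapse = "/"), "hr,",
      nBins(object@tracks[[1L]]@bins), "bins\n")
})


#' Per-bin turnover index track
#'
#' Holds the turnover index `ti = -slope * (1 - kendallP)` per bin, the raw
#' least-squares slope of signal against chase time, the two-sided Kendall
#' trend p-value used as the shrinkage weight, and a coverage mask. Derived
#' tracks (smoothed, replicate-averaged) carry `NA` slope/p since the raw
#' fit no longer applies bin-wise.
#'
#' @slot bins the [GenomeBins] partition.
#' @slot ti numeric turnover index per bin (positive = fast turnover).
#' @slot slope numeric raw OLS slope per bin (signal per hour), or `NA`.
#' @slot kendallP numeric two-sided Kendall p-value per bin, or `NA`.
#' @slot mask logical; `TRUE` where the bin had any signal.
#' @export
setClass("TurnoverTrack",
         representation(bins = "GenomeBins", ti = "numeric",
                        slope = "numeric", kendallP = "numeric",
                        mask = "logical"))

setValidity("TurnoverTrack", function(object) {
  n <- nBins(object@bins)
  if (length(object@ti) != n || length(object@slope) != n ||
      length(object@kendallP) != n || length(object@mask) != n)
    return("ti, slope, kendallP and mask must all have one entry per bin")
  ok <- !is.na(object@slope) & !is.na(object@kendallP)
  if (any(ok)) {
    expect <- -object@slope[ok] * (1 - object@kendallP[ok])
    if (max(abs(object@ti[ok] - expect)) > 1e-8)
      return("ti must equal -slope * (1 - kendallP) wherever both are set")
  }
  TRUE
})

#' @param bins a [GenomeBins].
#' @param ti per-bin turnover index.
#' @param slope per-bin OLS slope (or `NA`).
#' @param kendallP per-bin Kendall p-value (or `NA`).
#' @param mask logical coverage mask (default: all `TRUE`).
#' @return A `TurnoverTrack`.
#' @rdname TurnoverTrack-class
#' @export
TurnoverTrack <- function(bins, ti, slope = rep(NA_real_, length(ti)),
                          kendallP = rep(NA_real_, length(ti)),
                          mask = rep(TRUE, length(ti))) {
  new("TurnoverTrack", bins = bins, ti = as.numeric(ti),
      slope = as.numeric(slope), kendallP = as.numeric(kendallP),
      mask = mask)
}

#' @rdname tiValues
#' @export
setMethod("tiValues", "TurnoverTrack", function(x) x@ti)
#' @rdname slopeValues
#' @export
setMethod("slopeValues", "TurnoverTrack", function(x) x@slope)
#' @rdname kendallP
#' @export
setMethod("kendallP", "TurnoverTrack", function(x) x@kendallP)
#' @rdname coverageMask
#' @export
setMethod("coverageMask", "TurnoverTrack", function(x) x@mask)
#' @rdname genomeBins
#' @export
setMethod("genomeBins", "TurnoverTrack", function(x) x@bins)

#' @rdname TurnoverTrack-class
#' @param object a `TurnoverTrack`.
#' @export
setMethod("show", "TurnoverTrack", function(object) {
  cat("TurnoverTrack: ", nBins(object@bins), " bins (",
      sum(object@mask), " covered), TI range [",
      signif(min(object@ti), 3), ", ", signif(max(object@ti), 3), "]\n",
      sep = "")
})


#' Ground truth of a synthetic genome
#'
#' Full per-bin truth for a simulated genome: the region class each bin
#' belongs to, its true exponential decay rate of labeled histone (per
#' hour), its 0 hr enrichment over background, its true accessibility
#' slope, and its factor-ChIP fold enrichment; plus the placed regions per
#' class and a synthetic expression table. Exactly reproducible from
#' (class specs, seed).
#'
#' @slot bins the [GenomeBins] partition (genomic contigs only; the
#'   spike-in contig is separate).
#' @slot classLabel character class name per bin.
#' @slot k numeric true decay rate per bin (per hour).
#' @slot enrichment numeric 0 hr enrichment per bin (fold over background).
#' @slot accessibility numeric true accessibility slope per bin.
#' @slot chipFold numeric factor-ChIP fold enrichment per bin.
#' @slot regions named `GRangesList`, placed intervals per class.
#' @slot expression `data.frame` with columns gene, class, fpkmA, fpkmB.
#' @slot classSpecs the `data.frame` of class specifications used.
#' @slot seed integer RNG seed the truth was built from.
#' @export
setClass("SyntheticTruth",
         representation(bins = "GenomeBins", classLabel = "character",
                        k = "numeric", enrichment = "numeric",
                        accessibility = "numeric", chipFold = "numeric",
                        regions = "GRangesList", expression = "data.frame",
                        classSpecs = "data.frame", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  n <- nBins(object@bins)
  for (sl in c("classLabel", "k", "enrichment", "accessibility", "chipFold"))
    if (length(slot(object, sl)) != n)
      return(paste0(sl, " must have one entry per bin"))
  if (any(object@k < 0)) return("decay rates must be >= 0")
  if (any(object@enrichment < 0)) return("enrichment must be >= 0")
  TRUE
})

#' @rdname genomeBins
#' @export
setMethod("genomeBins", "SyntheticTruth", function(x) x@bins)

#' @rdname SyntheticTruth-class
#' @param object a `SyntheticTruth`.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@classLabel)
  cat("SyntheticTruth: ", nBins(object@bins), " bins, seed ", object@seed,
      "\n  classes: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})


#' MNase-accessibility (MACC) track
#'
#' Per-bin accessibility score from an MNase titration: minus the OLS slope
#' of normalized signal against log2 enzyme units, so that loci releasing
#' more signal at gentler digestion score positive ("accessible"). `NA`
#' where fewer than three titration points had coverage.
#'
#' @slot bins the [GenomeBins] partition.
#' @slot macc numeric MACC value per bin (`NA` allowed).
#' @slot r2 numeric goodness-of-fit of the per-bin linear fit.
#' @export
setClass("MaccTrack",
         representation(bins = "GenomeBins", macc = "numeric",
                        r2 = "numeric"))

setValidity("MaccTrack", function(object) {
  n <- nBins(object@bins)
  if (length(object@macc) != n || length(object@r2) != n)
    return("macc and r2 must have one entry per bin")
  TRUE
})

#' @param bins a [GenomeBins].
#' @param macc per-bin MACC values.
#' @param r2 per-bin fit r-squared.
#' @return A `MaccTrack`.
#' @rdname MaccTrack-class
#' @export
MaccTrack <- function(bins, macc, r2 = rep(NA_real_, length(macc))) {
  new("MaccTrack", bins = bins, macc = as.numeric(macc),
      r2 = as.numeric(r2))
}

#' @rdname maccValues
#' @export
setMethod("maccValues", "MaccTrack", function(x) x@macc)
#' @rdname genomeBins
#' @export
setMethod("genomeBins", "MaccTrack", function(x) x@bins)

#' @rdname MaccTrack-class
#' @param object a `MaccTrack`.
#' @export
setMethod("show", "MaccTrack", function(object) {
  ok <- !is.na(object@macc)
  cat("MaccTrack: ", nBins(object@bins), " bins (", sum(ok),
      " with MACC), mean ", signif(mean(object@macc[ok]), 3), "\n", sep = "")
})
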