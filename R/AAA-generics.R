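#' @import methods
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importFrom stats var sd rnbinom rpois rnorm runif quantile pnbinom dnbinom
#'   pt cor setNames median
#' @importFrom utils head tail write.table read.table
NULL

#' Bin size of a genome partition
#' @param x a [GenomeBins] or an object carrying one.
#' @return Integer scalar, bin width in bp.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' Number of bins in a genome partition
#' @param x a [GenomeBins] or an object carrying one.
#' @return Integer scalar.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Bins as genomic ranges
#' @param x a [GenomeBins] or an object carrying one.
#' @return A `GRanges` with one range per bin, in genome order.
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Genome bins underlying an object
#' @param x an object with a `bins` slot.
#' @return The [GenomeBins].
#' @export
setGeneric("genomeBins", function(x) standardGeneric("genomeBins"))

#' Genomic fragment records
#' @param x a [FragmentSet].
#' @return `GRanges` of the genomic (non-spike-in) fragments.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Total mapped reads in a library
#' @param x a [FragmentSet].
#' @return Numeric scalar (genomic + spike-in reads).
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Spike-in read count of a library
#' @param x a [FragmentSet].
#' @return Numeric scalar.
#' @export
setGeneric("spikeInReads", function(x) standardGeneric("spikeInReads"))

#' Genomic (non-spike-in) read count of a library
#' @param x a [FragmentSet].
#' @return Numeric scalar, `totalReads(x) - spikeInReads(x)`; the RPM
#'   denominator.
#' @export
setGeneric("genomicReads", function(x) standardGeneric("genomicReads"))

#' Per-bin values of a track
#' @param x a [BinnedTrack].
#' @return Numeric vector, one value per bin.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Units of a binned track
#' @param x a [BinnedTrack].
#' @return One of `"raw"`, `"rpm"`, `"rpm_minus_input"`.
#' @export
setGeneric("trackUnits", function(x) standardGeneric("trackUnits"))

#' Chase time points of a time course
#' @param x a [TimeCourse].
#' @return Numeric vector of hours, ascending, starting at 0.
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))

#' Per-timepoint tracks of a time course
#' @param x a [TimeCourse].
#' @return List of [BinnedTrack] objects, one per time point.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' Per-bin turnover index
#' @param x a [TurnoverTrack].
#' @return Numeric vector of TI values (one per bin).
#' @export
setGeneric("tiValues", function(x) standardGeneric("tiValues"))

#' Per-bin raw regression slope
#' @param x a [TurnoverTrack].
#' @return Numeric vector (signal units per hour); `NA` for derived tracks
#'   (smoothed or replicate-averaged) where the raw fit no longer applies.
#' @export
setGeneric("slopeValues", function(x) standardGeneric("slopeValues"))

#' Per-bin Kendall trend p-value
#' @param x a [TurnoverTrack].
#' @return Numeric vector of two-sided Kendall p-values.
#' @export
setGeneric("kendallP", function(x) standardGeneric("kendallP"))

#' Coverage mask of a turnover track
#' @param x a [TurnoverTrack].
#' @return Logical vector; `TRUE` where the bin had signal in at least one
#'   time point and TI is interpretable.
#' @export
setGeneric("coverageMask", function(x) standardGeneric("coverageMask"))

#' Per-bin MACC accessibility values
#' @param x a [MaccTrack].
#' @return Numeric vector (`NA` where fewer than 3 titration points had
#'   coverage).
#' @export
setGeneric("maccValues", function(x) standardGeneric("maccValues"))

#' Aggregate signal around anchor positions
#'
#' Samples signal at fixed offsets around a set of anchor points (for
#' example transcription start sites) and averages across anchors, the
#' standard metagene/TSS profile. Minus-strand anchors are mirrored so that
#' negative offsets always mean "upstream".
#'
#' @param x a [BinnedTrack] or [FragmentSet].
#' @param anchors `GRanges` of anchor points; the start coordinate is the
#'   anchor position and the strand orients the profile.
#' @param flank half-width of the profile in bp; must be a multiple of
#'   `step`.
#' @param step sampling step in bp.
#' @param ... method-specific arguments.
#' @return A `data.frame` with columns `offset` (bp relative to anchor) and
#'   `meanSignal`, with attributes `nAnchors` (anchors used) and `nSkipped`
#'   (anchors dropped because the window exceeded chromosome bounds).
#' @export
setGeneric("aggregateProfile",
           function(x, anchors, flank, step, ...)
             standardGeneric("aggregateProfile"))
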