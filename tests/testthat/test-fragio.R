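test_that("readFragments parses BED and partitions spike-in records", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t150", "chr1\t500\t650", "chr1\t900\t1050"), bed)
  fs <- readFragments(bed)
  expect_s4_class(fs, "FragmentSet")
  expect_equal(nFragments(fs), 3L)
  expect_equal(spikeInReads(fs), 0)
  expect_equal(totalReads(fs), 3)

  writeLines(c("chr1\t0\t150", "spike_001\t5\t155", "chr2\t10\t160",
               "spike_002\t0\t150", "chr1\t300\t450"), bed)
  fs <- readFragments(bed, spikeInPrefix = "spike_")
  expect_equal(nFragments(fs), 3L)
  expect_equal(spikeInReads(fs), 2)
  expect_equal(totalReads(fs), 5)
  # records sorted by (chrom, start)
  expect_equal(as.character(GenomeInfoDb::seqnames(fragments(fs))),
               c("chr1", "chr1", "chr2"))
  expect_equal(BiocGenerics::start(fragments(fs)), c(1L, 301L, 11L))
})

test_that("readFragments matches a naive line-scan oracle on random input", {
  set.seed(41)
  bed <- withr::local_tempfile(fileext = ".bed")
  sizes <- c(chr1 = 2e5, chr2 = 1e5, chr3 = 5e4)
  df <- writeRandomBed(bed, 1000, sizes)
  fs <- readFragments(bed)
  expect_equal(nFragments(fs), nrow(df))
  got <- table(as.character(GenomeInfoDb::seqnames(fragments(fs))))
  want <- table(df$chrom)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
})

test_that("readFragments reports malformed lines by number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t150", "chr1\tzz\t650"), bed)
  expect_error(readFragments(bed), "line 2")
  writeLines(c("chr1\t0\t150", "chr1\t700\t650"), bed)
  expect_error(readFragments(bed), "line 2")
  writeLines(c("chr1\t0\t150", "chr1\t100"), bed)
  expect_error(readFragments(bed), "line 2")
})

test_that("readFragments reconstructs fragments from minimal SAM text", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 99, "chr1", 101, 60, "50M", "=", 251, 200, "*", "*",
          sep = "\t"),
    paste("r1", 147, "chr1", 251, 60, "50M", "=", 101, -200, "*", "*",
          sep = "\t"),
    paste("r2", 99, "chr1", 501, 60, "50M", "=", 551, 100, "*", "*",
          sep = "\t")), sam)
  fs <- readFragments(sam, format = "sam")
  # only leftmost mates (tlen > 0) become fragments
  expect_equal(nFragments(fs), 2L)
  expect_equal(BiocGenerics::start(fragments(fs)), c(101L, 501L))
  expect_equal(BiocGenerics::end(fragments(fs)), c(300L, 600L))
})

test_that("anomalous-position filter removes only extreme pileups", {
  gb <- c(chr1 = 1e6)
  # every position exactly once: zero variance path, nothing removed
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = seq(1, 5000, by = 50), width = 150))
  fs <- FragmentSet(gr)
  expect_warning(out <- filterAnomalousPositions(fs), "zero variance")
  expect_equal(nFragments(out), nFragments(fs))

  # one position with a huge pileup among many singletons
  pile <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = rep(777, 1000), width = 150))
  single <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = sample.int(9e5, 10000), width = 150))
  fs <- FragmentSet(c(single, pile))
  # oracle: z of the pileup position
  cnt <- c(rep(1, length(unique(BiocGenerics::start(single)))), 1000)
  expect_gt((1000 - mean(cnt)) / sd(cnt), 7)
  out <- filterAnomalousPositions(fs)
  expect_false(777 %in% BiocGenerics::start(fragments(out)))
  expect_equal(nFragments(out), length(single))
  expect_equal(totalReads(out), totalReads(fs) - 1000)

  # infinite threshold: identity
  out <- filterAnomalousPositions(fs, zThreshold = Inf)
  expect_equal(nFragments(out), nFragments(fs))
})

test_that("binCounts assigns by midpoint and normalizes to RPM", {
  gb <- GenomeBins(c(chr1 = 3000))
  fs <- FragmentSet(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(401, 1401), end = c(600, 1600))))
  raw <- binCounts(fs, gb, "raw")
  expect_equal(trackValues(raw), c(1, 1, 0))
  rpm <- binCounts(fs, gb, "rpm")
  expect_equal(trackValues(rpm), c(5e5, 5e5, 0))

  # empty set -> all zero
  empty <- FragmentSet(GenomicRanges::GRanges(), totalReads = 10)
  expect_equal(trackValues(binCounts(empty, gb, "raw")), c(0, 0, 0))

  # unknown chromosome is an error naming the offender
  bad <- FragmentSet(GenomicRanges::GRanges("chrX",
    IRanges::IRanges(start = 1, end = 100)))
  expect_error(binCounts(bad, gb), "chrX")
})

test_that("binCounts matches a brute-force midpoint histogram", {
  set.seed(7)
  sizes <- c(chr1 = 1e5, chr2 = 63500)
  n <- 10000
  chrom <- sample(names(sizes), n, replace = TRUE)
  w <- sample(50:300, n, replace = TRUE)
  start0 <- floor(runif(n) * (unname(sizes[chrom]) - w))
  fs <- FragmentSet(GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1, width = w)))
  gb <- GenomeBins(sizes, 1000)
  got <- trackValues(binCounts(fs, gb, "raw"))
  want <- midpointHistOracle(chrom, start0, start0 + w, sizes, 1000)
  expect_equal(got, want)
  # conservation: every genomic record lands in exactly one bin
  expect_equal(sum(got), n)
  # rpm sums to 1e6 * genomic records / genomic reads
  fs2 <- FragmentSet(fragments(fs), totalReads = n + 500, spikeInReads = 500)
  expect_equal(sum(trackValues(binCounts(fs2, gb, "rpm"))),
               1e6 * n / (n + 500 - 500))
})

test_that("input subtraction floors at zero and preserves bins", {
  gb <- GenomeBins(c(chr1 = 4000))
  chip <- BinnedTrack(gb, c(3, 5, 0, 2), "rpm")
  input <- BinnedTrack(gb, c(5, 2, 1, 2), "rpm")
  out <- subtractInput(chip, input)
  expect_equal(trackValues(out), c(0, 3, 0, 0))
  expect_equal(trackUnits(out), "rpm_minus_input")
  expect_equal(trackValues(subtractInput(chip, chip)), rep(0, 4))

  set.seed(1)
  a <- BinnedTrack(gb, runif(4, 0, 10), "rpm")
  b <- BinnedTrack(gb, runif(4, 0, 10), "rpm")
  out <- trackValues(subtractInput(a, b))
  expect_equal(out, pmax(trackValues(a) - trackValues(b), 0))
  expect_true(all(out >= 0 & out <= trackValues(a)))

  other <- BinnedTrack(GenomeBins(c(chr1 = 8000), 2000), rep(1, 4), "rpm")
  expect_error(subtractInput(chip, other), "different bins")
  expect_error(subtractInput(binCounts(FragmentSet(GenomicRanges::GRanges(),
                                                   totalReads = 1), gb, "raw"),
                             input), "rpm")
})

test_that("aggregateProfile averages anchored windows with mirroring", {
  gb <- GenomeBins(c(chr1 = 20000), 100)
  # uniform signal: flat profile at the constant
  tr <- BinnedTrack(gb, rep(4.2, nBins(gb)), "rpm")
  anchors <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(5001, 9001), width = 1), strand = c("+", "-"))
  pr <- aggregateProfile(tr, anchors, flank = 1000, step = 100)
  expect_equal(pr$meanSignal, rep(4.2, 21))
  expect_equal(pr$offset, seq(-1000, 1000, 100))

  # minus-strand anchor sees the mirrored window
  v <- seq_len(nBins(gb))
  tr <- BinnedTrack(gb, v, "rpm")
  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, width = 1),
                                 strand = "+")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9001, width = 1),
                                  strand = "-")
  pp <- aggregateProfile(tr, plus, 500, 100)$meanSignal
  pm <- aggregateProfile(tr, minus, 500, 100)$meanSignal
  expect_equal(pm, rev(pp))

  # 50 anchors vs brute-force extraction
  set.seed(11)
  vals <- runif(nBins(gb))
  tr <- BinnedTrack(gb, vals, "rpm")
  pos <- sample(3000:17000, 50)
  str <- sample(c("+", "-"), 50, replace = TRUE)
  anchors <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1),
                                    strand = str)
  pr <- aggregateProfile(tr, anchors, 1000, 100)
  offs <- seq(-1000, 1000, 100)
  M <- matrix(0, 50, length(offs))
  for (i in 1:50) {
    p0 <- pos[i] - 1
    row <- vals[(p0 + offs) %/% 100 + 1]
    if (str[i] == "-") row <- rev(row)
    M[i, ] <- row
  }
  expect_equal(pr$meanSignal, colMeans(M))
  expect_equal(attr(pr, "nAnchors"), 50L)

  # out-of-bounds anchors are skipped and counted
  anchors <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(50, 10000), width = 1))
  expect_message(pr <- aggregateProfile(tr, anchors, 1000, 100), "skipped")
  expect_equal(attr(pr, "nSkipped"), 1L)
})
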