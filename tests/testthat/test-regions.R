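test_that("sliding-window smoothing is a truncated centered mean", {
  gb <- GenomeBins(c(chr1 = 10000))
  tt <- TurnoverTrack(gb, rep(2.5, 10))
  expect_equal(tiValues(smoothTI(tt)), rep(2.5, 10))

  imp <- rep(0, 10); imp[5] <- 3
  expect_equal(tiValues(smoothTI(TurnoverTrack(gb, imp))),
               c(0, 0, 0, 1, 1, 1, 0, 0, 0, 0))

  set.seed(2)
  gb2 <- GenomeBins(c(chr1 = 8000, chr2 = 5000))
  v <- runif(13)
  sm <- tiValues(smoothTI(TurnoverTrack(gb2, v), 3))
  # brute force within each chromosome, truncated at the edges
  want <- numeric(13)
  for (i in 1:8) want[i] <- mean(v[max(1, i - 1):min(8, i + 1)])
  for (i in 9:13) want[i] <- mean(v[max(9, i - 1):min(13, i + 1)])
  expect_equal(sm, want)

  expect_error(smoothTI(TurnoverTrack(gb, rep(1, 10)), 4), "odd")
  # chromosome shorter than the window passes through with a warning
  gb3 <- GenomeBins(c(chr1 = 8000, chr2 = 2000))
  expect_warning(out <- smoothTI(TurnoverTrack(gb3, rep(1, 10)), 5),
                 "unsmoothed")
  expect_equal(tiValues(out), rep(1, 10))
})

test_that("top-region selection ranks, breaks ties and honors blacklists", {
  gb <- GenomeBins(c(chr1 = 5000, chr2 = 5000))
  v <- c(5, 1, 9, 9, 2, 9, 0, 3, 4, 8)
  tt <- TurnoverTrack(gb, v)
  all10 <- topRegions(tt, n = 10)
  expect_equal(length(all10), 10L)

  # three bins tied at the max: lexicographically first (chrom, start) wins
  top1 <- topRegions(tt, n = 1)
  expect_equal(as.character(GenomeInfoDb::seqnames(top1)), "chr1")
  expect_equal(BiocGenerics::start(top1), 2001L)
  top3 <- topRegions(tt, n = 3)
  expect_equal(S4Vectors::mcols(top3)$score, rep(9, 3))
  expect_equal(BiocGenerics::start(top3), c(2001L, 3001L, 1L))
  expect_equal(as.character(GenomeInfoDb::seqnames(top3)),
               c("chr1", "chr1", "chr2"))

  # blacklist removal precedes ranking
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000))
  topBl <- topRegions(tt, n = 1, blacklist = bl)
  expect_equal(as.character(GenomeInfoDb::seqnames(topBl)), "chr2")
  expect_equal(BiocGenerics::start(topBl), 1L)

  expect_error(topRegions(tt, n = 11), "exceeds")

  # adjacent top bins can be merged on request
  merged <- topRegions(tt, n = 2, mergeAdjacent = TRUE)
  expect_equal(length(merged), 1L)
  expect_equal(BiocGenerics::width(merged), 2000L)
})

test_that("resampling FDR behaves at the extremes and is monotone", {
  set.seed(4)
  gb <- GenomeBins(c(chr1 = 1e6))
  v <- rnorm(1000)
  tt <- TurnoverTrack(gb, v)
  gr <- binRanges(gb)[1:5]

  # threshold above the global max: FDR 0
  S4Vectors::mcols(gr)$score <- max(v) + 1
  expect_equal(as.numeric(empiricalFdr(tt, gr, nDraw = 100, seed = 1)), 0)

  # threshold below the global min: every drawn bin exceeds it
  S4Vectors::mcols(gr)$score <- min(v) - 1
  expect_equal(as.numeric(empiricalFdr(tt, gr, nDraw = 100, seed = 1)), 1)

  # non-increasing in the threshold
  fdrs <- vapply(quantile(v, c(0.2, 0.5, 0.8, 0.95)), function(thr) {
    S4Vectors::mcols(gr)$score <- thr
    as.numeric(empiricalFdr(tt, gr, nDraw = 200, nTests = 50, seed = 7))
  }, numeric(1))
  expect_true(all(diff(fdrs) <= 0))
  expect_error(empiricalFdr(tt, gr[0]), "non-empty")
})

test_that("feature overrepresentation matches analytic and brute-force values", {
  gb <- GenomeBins(c(chr1 = 1e5))  # 100 bins
  # feature covering 5 of 100 bins; query set of 10 bins, 5 inside
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
  set <- binRanges(gb)[c(1:5, 51:55)]
  rep <- featureOverrepresentation(set, list(f = feat), gb)
  expect_equal(rep$propInSet, 0.5)
  expect_equal(rep$propInGenome, 0.05)
  expect_equal(rep$log2Ratio, log2(10))
  expect_equal(rep$countInSet, 5L)

  # equal proportions: log2 ratio 0
  repAll <- featureOverrepresentation(binRanges(gb), list(f = feat), gb)
  expect_equal(repAll$log2Ratio, 0)

  # empty feature: proportion 0, ratio missing (never 0)
  repE <- featureOverrepresentation(set, list(f = GenomicRanges::GRanges()),
                                    gb)
  expect_equal(repE$propInSet, 0)
  expect_true(is.na(repE$log2Ratio))

  # random sets agree with the double-loop oracle
  set.seed(12)
  qs <- sort(sample(0:(1e5 - 200), 30))
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(qs + 1, qs + 150))
  fs <- sort(sample(0:(1e5 - 500), 10))
  f <- GenomicRanges::GRanges("chr1", IRanges::IRanges(fs + 1, fs + 400))
  got <- featureOverrepresentation(q, list(f = f), gb)
  want <- anyOverlapCountOracle(rep("chr1", 30), qs, qs + 150,
                                rep("chr1", 10), fs, fs + 400)
  expect_equal(got$countInSet, want)
})

test_that("proximity permutation test separates planted from independent", {
  gb <- GenomeBins(c(chr1 = 1e6, chr2 = 1e6))
  targets <- GenomicRanges::GRanges(rep(c("chr1", "chr2"), each = 10),
    IRanges::IRanges(rep(seq(1e4, 9.1e5, length.out = 10), 2), width = 2000))

  # query a subset of the targets: observed = |query|, minimal p
  q <- targets[c(2, 5, 12)]
  ov <- overlapSignificance(q, targets, gb, nPerm = 99, seed = 3)
  expect_equal(ov$observed, 3L)
  expect_equal(ov$pValue, 1 / 100)

  # empty targets: observed 0, p 1
  ov <- overlapSignificance(q, GenomicRanges::GRanges(), gb, nPerm = 9)
  expect_equal(ov$observed, 0L)
  expect_equal(ov$pValue, 1)

  # planted near targets vs independent placement
  set.seed(5)
  near <- GenomicRanges::shift(targets[1:15], 3000)
  pNear <- overlapSignificance(near, targets, gb, mode = "within_distance",
                               distanceBp = 5000, nPerm = 199, seed = 5)$pValue
  far <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(9e5, 15), width = 1000))
  pFar <- overlapSignificance(far, targets, gb, mode = "within_distance",
                              distanceBp = 5000, nPerm = 199, seed = 5)$pValue
  expect_lt(pNear, 0.01)
  expect_gt(pFar, pNear)

  expect_error(overlapSignificance(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e6)), targets, gb),
    "workspace")
})

test_that("permutation p-values are approximately uniform under independence", {
  # the add-one p is discrete, so the check needs enough queries/targets
  # for the attainable p grid to be reasonably fine
  set.seed(21)
  gb <- GenomeBins(c(chr1 = 4e6))
  targets <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(3.9e6, 60), width = 5000))
  ps <- vapply(1:150, function(i) {
    q <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(sample.int(3.99e6, 80), width = 1000))
    overlapSignificance(q, targets, gb, mode = "within_distance",
                        distanceBp = 2000, nPerm = 199)$pValue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
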