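test_that("genome construction is deterministic and overlap-free", {
  # empty spec: everything background
  empty <- escLikeSpecs()[0, ]
  truth <- buildGenome(empty, nChroms = 1, chromLen = 1e5, seed = 4)
  expect_true(all(truth@classLabel == "background"))

  # same (specs, seed) twice: identical truth
  t1 <- buildGenome(escLikeSpecs(0.3), nChroms = 2, chromLen = 1.5e6, seed = 9)
  t2 <- buildGenome(escLikeSpecs(0.3), nChroms = 2, chromLen = 1.5e6, seed = 9)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  # 100 x 1 kb enhancers on 10 Mb: exactly 100 intervals, no pairwise overlap
  sp <- regionClassSpec("enhancer", 100, 1000, 0.2, 5)
  truth <- buildGenome(sp, nChroms = 1, chromLen = 1e7, seed = 2)
  gr <- truth@regions[["enhancer"]]
  expect_equal(length(gr), 100L)
  s0 <- BiocGenerics::start(gr) - 1
  e0 <- BiocGenerics::end(gr)
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- 0L
  for (i in 1:99) for (j in (i + 1):100)
    if (overlapsOracle(ch[i], s0[i], e0[i], ch[j], s0[j], e0[j]))
      bad <- bad + 1L
  expect_equal(bad, 0L)
  expect_equal(sum(truth@classLabel == "enhancer"), 100L)

  # impossible placement errors out with advice
  sp <- regionClassSpec("huge", 3, 50000, 0.1, 5)
  expect_error(buildGenome(sp, nChroms = 1, chromLen = 1.2e5, seed = 1),
               "smaller|reduce")
})

test_that("time-course totals follow the exponential decay of the pool", {
  truth <- buildGenome(escLikeSpecs()[0, ], nChroms = 1, chromLen = 2e6,
                       seed = 3)
  # uniform half-life of 6 hr everywhere
  truth@k[] <- log(2) / 6
  sim <- simulateTimecourse(truth, depth = 5e5, replicateSd = 0,
                            seed = 5)
  tot <- vapply(sim$timecourse, nFragments, numeric(1))
  expect_equal(tot[["t6"]] / tot[["t0"]], 0.5, tolerance = 0.02)
  expect_equal(tot[["t12"]] / tot[["t0"]], 0.25, tolerance = 0.04)
  # spike-in stays flat while the genomic pool decays
  spk <- vapply(sim$timecourse, spikeInReads, numeric(1))
  expect_equal(max(spk) / min(spk), 1, tolerance = 0.1)

  # k = 0 everywhere: per-timepoint totals statistically equal
  truth@k[] <- 0
  sim <- simulateTimecourse(truth, depth = 5e5, replicateSd = 0, seed = 6)
  tot <- vapply(sim$timecourse, nFragments, numeric(1))
  expect_equal(max(tot) / min(tot), 1, tolerance = 0.03)

  # determinism
  s1 <- simulateTimecourse(truth, depth = 1e4, seed = 11)
  s2 <- simulateTimecourse(truth, depth = 1e4, seed = 11)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("per-class decay tracks the analytic curve", {
  sp <- rbind(regionClassSpec("fast", 100, 2000, 0.25, 5),
              regionClassSpec("slow", 100, 2000, 0.02, 5))
  truth <- buildGenome(sp, nChroms = 1, chromLen = 2e6, seed = 7,
                       rateJitterSd = 0)
  sim <- simulateTimecourse(truth, depth = 1e6, replicateSd = 0, seed = 8)
  gb <- genomeBins(truth)
  cnt <- function(fs) trackValues(binCounts(fs, gb, "raw"))
  c0 <- cnt(sim$timecourse$t0); c12 <- cnt(sim$timecourse$t12)
  for (cls in c("fast", "slow")) {
    sel <- truth@classLabel == cls
    k <- sp$k[sp$name == cls]
    ratio <- sum(c12[sel]) / sum(c0[sel])
    want <- exp(-k * 12)
    # binomial-scale tolerance: 3 sd of the ratio estimate
    tol <- 3 * sqrt(1 / sum(c12[sel]) + 1 / sum(c0[sel]))
    expect_lt(abs(ratio / want - 1), tol + 0.05)
  }
  # monotonicity: the faster class has the smaller 12 hr / 0 hr ratio
  fast <- truth@classLabel == "fast"; slow <- truth@classLabel == "slow"
  expect_lt(sum(c12[fast]) / sum(c0[fast]), sum(c12[slow]) / sum(c0[slow]))
})

test_that("MNase titration responds log-linearly to enzyme units", {
  truth <- buildGenome(escLikeSpecs()[0, ], nChroms = 1, chromLen = 1e6,
                       seed = 2, accessibilityJitterSd = 0)
  # a = 0 everywhere: totals equal across concentrations
  truth@accessibility[] <- 0
  tit <- simulateMnaseTitration(truth, depth = 2e5, seed = 3)
  tot <- vapply(tit, nFragments, numeric(1))
  expect_equal(max(tot) / min(tot), 1, tolerance = 0.03)
  expect_error(simulateMnaseTitration(truth, units = c(1, 4)), ">= 3")

  # same seed: identical output
  t1 <- simulateMnaseTitration(truth, depth = 1e4, seed = 5)
  t2 <- simulateMnaseTitration(truth, depth = 1e4, seed = 5)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))

  # per-bin OLS on realized counts recovers the relative slope ordering
  truth@accessibility[] <- rep(c(0, 0.1), length.out = 1000)
  tit <- simulateMnaseTitration(truth, depth = 2e6, seed = 6)
  gb <- genomeBins(truth)
  macc <- maccValues(computeMacc(lapply(tit, binCounts, bins = gb,
                                        normalize = "rpm")))
  hi <- truth@accessibility == 0.1
  expect_gt(mean(macc[hi], na.rm = TRUE), mean(macc[!hi], na.rm = TRUE))
})

test_that("factor ChIP enrichment matches the requested fold", {
  sp <- regionClassSpec("pcg_target", 50, 2000, 0.05, 5, chipFold = 8)
  truth <- buildGenome(sp, nChroms = 1, chromLen = 2e6, seed = 4)
  pair <- simulateChip(truth, "pcg_target", chipDepth = 1e6,
                       inputDepth = 1e6, seed = 5)
  gb <- genomeBins(truth)
  chip <- trackValues(binCounts(pair$chip, gb, "raw"))
  sel <- truth@classLabel == "pcg_target"
  foldHat <- mean(chip[sel]) / mean(chip[!sel])
  expect_equal(foldHat, 8, tolerance = 0.15)

  # fold 1: chip statistically indistinguishable from input
  truth@chipFold[] <- 1
  pair <- simulateChip(truth, "pcg_target", chipDepth = 1e6,
                       inputDepth = 1e6, seed = 6)
  chip <- trackValues(binCounts(pair$chip, gb, "raw"))
  input <- trackValues(binCounts(pair$input, gb, "raw"))
  expect_equal(mean(chip[sel]) / mean(input[sel]), 1, tolerance = 0.1)

  expect_error(simulateChip(truth, "nope"), "not present")
  s1 <- simulateChip(truth, "pcg_target", chipDepth = 1e4, inputDepth = 1e4,
                     seed = 7)
  s2 <- simulateChip(truth, "pcg_target", chipDepth = 1e4, inputDepth = 1e4,
                     seed = 7)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("written fixtures round-trip through the BED reader", {
  truth <- buildGenome(escLikeSpecs(0.1), nChroms = 1, chromLen = 1e6,
                       seed = 10)
  sim <- simulateTimecourse(truth, depth = 2e4, seed = 11)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeFragmentsBed(sim$timecourse$t0, bed)
  back <- readFragments(bed, spikeInPrefix = "spike_")
  expect_equal(nFragments(back), nFragments(sim$timecourse$t0))
  expect_equal(spikeInReads(back), spikeInReads(sim$timecourse$t0))
  # truth tables and annotations land on disk as plain text
  dir <- withr::local_tempdir()
  paths <- writeTruth(truth, dir)
  expect_true(all(file.exists(paths)))
  sizes <- readChromSizes(file.path(dir, "genome.chrom.sizes"))
  expect_true("spike_001" %in% names(sizes))
})
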