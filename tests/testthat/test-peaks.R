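# deterministic FragmentSet with one 150 bp fragment centred in given bins
fsFromBins <- function(binIdx, counts, chromLen = 1e5, binSize = 1000) {
  start0 <- rep((binIdx - 1) * binSize + 400, counts)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = start0 + 1, width = 150),
    seqinfo = GenomeInfoDb::Seqinfo("chr1", chromLen))
  FragmentSet(gr)
}

test_that("window scan computes NB tail p-values against scaled input", {
  # window = step = 1000 so window counts equal bin counts
  # input scaled so the null mean in window 1 is exactly 10 reads
  chip <- fsFromBins(c(1, 2, 3), c(100, 0, 10))
  input <- fsFromBins(c(1, 2, 3), c(3, 15, 15))
  ws <- windowScan(chip, input, window = 1000, step = 1000, alpha = 1e-5,
                   nbSize = 5, inputWindow = 1000)
  md <- S4Vectors::metadata(ws)
  expect_equal(md$scale, 110 / 33)
  mu <- 10
  # upper-tail probability matches an explicit pmf sum to 1e-10
  pmfTail <- function(q, size, mu) {
    1 - sum(dnbinom(0:(q - 1), size = size, mu = mu))
  }
  w1 <- which(BiocGenerics::start(ws) == 1)
  expect_equal(S4Vectors::mcols(ws)$pValue[w1], pmfTail(100, 5, mu),
               tolerance = 1e-10)
  # zero chip count: p = 1, never significant
  w2 <- which(BiocGenerics::start(ws) == 1001)
  expect_equal(S4Vectors::mcols(ws)$pValue[w2], 1)
  expect_false(S4Vectors::mcols(ws)$significant[w2])
  # enriched window is significant at alpha
  expect_true(S4Vectors::mcols(ws)$significant[w1])

  expect_error(windowScan(chip, input, nbSize = -1), "nbSize")
  expect_error(windowScan(chip, input, window = 1000, step = 300), "multiple")
})

test_that("lowering alpha never adds significant windows", {
  set.seed(8)
  chip <- fsFromBins(sample.int(100, 3000, replace = TRUE),
                     rep(1, 3000))
  input <- fsFromBins(sample.int(100, 3000, replace = TRUE),
                      rep(1, 3000))
  nSig <- vapply(c(0.1, 0.01, 1e-3, 1e-4), function(a)
    sum(S4Vectors::mcols(windowScan(chip, input, alpha = a,
                                    nbSize = 10))$significant),
    numeric(1))
  expect_true(all(diff(nSig) <= 0))
})

test_that("overlapping windows merge across gaps of at most 1 kb", {
  gb <- GenomeInfoDb::Seqinfo("chr1", 1e5)
  mk <- function(starts, sig) {
    gr <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = starts, width = 1000), seqinfo = gb)
    S4Vectors::mcols(gr)$pValue <- ifelse(sig, 1e-8, 0.5)
    S4Vectors::mcols(gr)$significant <- sig
    gr
  }
  # nothing significant: empty result
  expect_equal(length(mergeWindows(mk(c(1, 2001), c(FALSE, FALSE)))), 0L)

  # significant windows [1000,2000) and [2800,3800): gap 800 <= 1 kb merges
  ws <- mk(c(1001, 2801), c(TRUE, TRUE))
  merged <- mergeWindows(ws, maxGap = 1000)
  expect_equal(length(merged), 1L)
  expect_equal(BiocGenerics::start(merged), 1001L)
  expect_equal(BiocGenerics::end(merged), 3800L)
  # the same pair with a larger gap stays apart
  ws <- mk(c(1001, 3101), c(TRUE, TRUE))
  expect_equal(length(mergeWindows(ws, maxGap = 1000)), 2L)

  # random significance pattern vs a brute-force union-then-merge oracle
  set.seed(9)
  starts <- seq(1, 90001, by = 200)
  sig <- runif(length(starts)) < 0.07
  ws <- mk(starts, sig)
  merged <- mergeWindows(ws, maxGap = 1000)
  # oracle: mark covered bp, close gaps <= 1000, read off runs
  cov <- rep(FALSE, 1e5)
  for (s in starts[sig]) cov[s:(s + 999)] <- TRUE
  runs <- rle(cov)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  iv <- cbind(begins[runs$values], ends[runs$values])
  if (nrow(iv) > 1) {
    out <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - out[nrow(out), 2] - 1 <= 1000) out[nrow(out), 2] <- iv[i, 2]
      else out <- rbind(out, iv[i, ])
    }
    iv <- out
  }
  expect_equal(cbind(BiocGenerics::start(merged), BiocGenerics::end(merged)),
               iv, ignore_attr = TRUE)
  # merged regions are pairwise separated by more than the gap
  if (length(merged) > 1) {
    gaps <- BiocGenerics::start(merged)[-1] -
      BiocGenerics::end(merged)[-length(merged)] - 1
    expect_true(all(gaps > 1000))
  }
  # region score is the smallest member p-value
  expect_true(all(S4Vectors::mcols(merged)$pValue == 1e-8))
})

test_that("joint-target intersection equals bp-level common coverage", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5001),
                                                       width = 2000))
  expect_equal(intersectTargets(list(a, a)), GenomicRanges::granges(a))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, width = 500))
  expect_equal(length(intersectTargets(list(a, b))), 0L)
  expect_error(intersectTargets(list(a)), ">= 2")

  set.seed(10)
  sets <- lapply(1:3, function(i) {
    s <- sort(sample(seq(1, 48001, by = 1200), 20))
    GenomicRanges::reduce(GenomicRanges::GRanges("chr1",
      IRanges::IRanges(s, width = sample(300:1500, 20, replace = TRUE))))
  })
  got <- intersectTargets(sets)
  # oracle: per-bp coverage by all three sets
  cov <- rep(0L, 6e4)
  for (s in sets) {
    hit <- rep(FALSE, 6e4)
    for (i in seq_along(s))
      hit[BiocGenerics::start(s)[i]:BiocGenerics::end(s)[i]] <- TRUE
    cov <- cov + hit
  }
  runs <- rle(cov == 3L)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  expect_equal(BiocGenerics::start(got), begins[runs$values])
  expect_equal(BiocGenerics::end(got), ends[runs$values])
})
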