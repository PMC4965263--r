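# Independent oracles used across the suite. Deliberately naive
# implementations (loops, full enumeration) that share no code with the
# package internals.

# all permutations of a vector, plain recursion
permuteAll <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permuteAll(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Kendall S for paired (x, y) by double loop
kendallSOracle <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s
}

# exact two-sided Kendall trend p by enumerating every ordering of y
kendallPOracle <- function(y, x = seq_along(y)) {
  sObs <- kendallSOracle(x, y)
  perms <- permuteAll(y)
  hits <- vapply(perms, function(p) abs(kendallSOracle(x, p)) >= abs(sObs) - 1e-9,
                 logical(1))
  mean(hits)
}

# closed-form OLS slope
olsSlopeOracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# turnover index by the definition, via the oracles above
tiOracle <- function(y, x = c(0, 3, 6, 12)) {
  -olsSlopeOracle(x, y) * (1 - kendallPOracle(y, x))
}

# brute-force midpoint histogram over bins of one chromosome set
midpointHistOracle <- function(chrom, start0, end0, chromSizes, binSize) {
  nbins <- sum(ceiling(chromSizes / binSize))
  offsets <- cumsum(c(0, head(ceiling(chromSizes / binSize), -1)))
  names(offsets) <- names(chromSizes)
  counts <- numeric(nbins)
  for (i in seq_along(chrom)) {
    mid <- (start0[i] + end0[i]) %/% 2
    idx <- offsets[[chrom[i]]] + mid %/% binSize + 1
    counts[idx] <- counts[idx] + 1
  }
  counts
}

# naive interval overlap: does [s1,e1) overlap [s2,e2) on same chrom
overlapsOracle <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# fraction of query intervals overlapping any target, double loop
anyOverlapCountOracle <- function(qc, qs, qe, tc, ts, te) {
  n <- 0
  for (i in seq_along(qc)) {
    hit <- FALSE
    for (j in seq_along(tc))
      if (overlapsOracle(qc[i], qs[i], qe[i], tc[j], ts[j], te[j])) {
        hit <- TRUE; break
      }
    n <- n + hit
  }
  n
}

# build a small GenomeBins + rpm_minus_input track from a value matrix
# (rows = bins on one chromosome, cols = timepoints)
tcFromMatrix <- function(Y, timepoints = c(0, 3, 6, 12), binSize = 1000) {
  gb <- GenomeBins(c(chrT = nrow(Y) * binSize), binSize)
  trks <- lapply(seq_len(ncol(Y)), function(j)
    BinnedTrack(gb, Y[, j], "rpm_minus_input"))
  TimeCourse(timepoints, trks)
}

# random BED file content on given chromosomes; returns the data frame too
writeRandomBed <- function(path, n, chromSizes, width = 150) {
  chrom <- sample(names(chromSizes), n, replace = TRUE)
  start0 <- floor(runif(n) * (unname(chromSizes[chrom]) - width))
  df <- data.frame(chrom = chrom, start0 = start0, end0 = start0 + width,
                   stringsAsFactors = FALSE)
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start0, df$end0), path)
  df
}
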