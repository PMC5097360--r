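sl1 <- c(c1 = 1000L)

test_that("qfrag coverage stacks closed intervals with multiplicity", {
  hs <- HitSet(chrom = c("c1", "c1"), pos = c(100L, 115L),
               strand = c("f", "r"), seqlengths = sl1)
  v <- as.numeric(qfragCoverage(hs, 13L, 23L)$c1)
  expect_equal(which(v > 0), 100:115)
  expect_true(all(v[100:115] == 1))

  # below qMin: no qfrag
  hs <- HitSet(chrom = c("c1", "c1"), pos = c(100L, 112L),
               strand = c("f", "r"), seqlengths = sl1)
  expect_equal(sum(as.numeric(qfragCoverage(hs, 13L, 23L)$c1)), 0)

  # two forward, one reverse: depths 1 and 2
  hs <- HitSet(chrom = rep("c1", 3), pos = c(100L, 105L, 118L),
               strand = c("f", "f", "r"), seqlengths = sl1)
  v <- as.numeric(qfragCoverage(hs, 13L, 23L)$c1)
  expect_true(all(v[100:104] == 1))
  expect_true(all(v[105:118] == 2))
  expect_equal(sum(v > 0), 19)
})

test_that("qfrag coverage equals the interval-stacking oracle", {
  for (seed in 1:8) {
    hs <- randomHitSet(seed, n = sample(50:300, 1), l = 500L,
                       chroms = c("c1", "c2"))
    got <- qfragCoverage(hs, 13L, 23L)
    want <- oracleQfragCoverage(hs, 13L, 23L)
    for (ch in names(want))
      expect_equal(as.numeric(got[[ch]]), want[[ch]])
  }
})

test_that("summits are free-standing maxima, leftmost of each plateau", {
  mkcov <- function(v) methods::as(list(c1 = S4Vectors::Rle(v)),
                                   "SimpleRleList")
  # triangular profile: unique maximum
  v <- c(rep(0, 139), 1:10, 11, 10:1, rep(0, 100))
  s <- findSummits(mkcov(v), 13L)
  expect_identical(GenomicRanges::start(s), 150L)
  expect_identical(s$qfragDepth, 11)

  # flat plateau: leftmost position reported once
  v <- c(rep(0, 139), rep(3, 21), rep(0, 40))
  s <- findSummits(mkcov(v), 13L)
  expect_identical(GenomicRanges::start(s), 140L)

  # two maxima further apart than qMin: both reported
  v <- rep(0, 200); v[95:105] <- 1; v[100] <- 3
  v[125:135] <- 1; v[130] <- 3
  s <- findSummits(mkcov(v), 13L)
  expect_identical(GenomicRanges::start(s), c(100L, 130L))

  # all-zero profile: empty result
  expect_identical(length(findSummits(mkcov(rep(0, 50)), 13L)), 0L)
})

test_that("reported summits satisfy the free-standing definition verbatim", {
  for (seed in 1:6) {
    hs <- randomHitSet(seed, n = 250L, l = 400L)
    cov <- qfragCoverage(hs, 13L, 23L)
    got <- findSummits(cov, 13L)
    want <- oracleSummits(as.numeric(cov$c1), 13L)
    expect_identical(GenomicRanges::start(got), want)
    # every summit lies inside a covered region
    expect_true(all(got$qfragDepth >= 1))
  }
})

test_that("the Poisson background rate follows the printed formula", {
  expect_equal(summitLambda(1000, 1e6, 23), 0.046)
  expect_equal(summitLambda(0, 1e6, 23), 0)
  expect_equal(summitLambda(1000, 1e6, 46), 2 * summitLambda(1000, 1e6, 23))
  expect_error(summitLambda(10, 0, 23), "positive")
})

test_that("upper-tail Poisson p-values match a high-precision series", {
  expect_equal(poissonPvalue(0, 0.5), 1)
  expect_equal(poissonPvalue(0, 0), 1)
  expect_equal(poissonPvalue(1, 1), 1 - exp(-1), tolerance = 1e-12)
  for (case in list(c(5, 0.046), c(3, 1.4), c(12, 2.3), c(1, 1e-4))) {
    want <- oraclePoissonUpper(case[1], case[2])
    got <- poissonPvalue(case[1], case[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # monotone non-increasing in k at fixed lambda
  p <- poissonPvalue(0:20, 1.3)
  expect_true(all(diff(p) <= 0))
  expect_error(poissonPvalue(-1, 1), "non-negative")
  expect_error(poissonPvalue(1, -1), "non-negative")
})

test_that("BH adjustment matches the hand-written step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(99)
  for (i in 1:5) {
    p <- runif(sample(5:50, 1))
    q <- bhAdjust(p)
    expect_equal(q, oracleBH(p))
    # invariance under permutation of the input order
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), q[perm])
    # q-values are non-decreasing in the sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("an idealized site yields one summit at the plateau start", {
  # forward pile-up at s-9, reverse at s+9, w=18, x=5
  s <- 500L
  nf <- 12L; nr <- 14L
  hs <- HitSet(chrom = rep("c1", nf + nr),
               pos = c(rep(s - 9L, nf), rep(s + 9L, nr)),
               strand = c(rep("f", nf), rep("r", nr)),
               seqlengths = sl1, readLength = 42L)
  peaks <- callPeaks(hs, width = 18L)
  expect_identical(length(peaks), 1L)
  expect_identical(GenomicRanges::start(peaks), s - 9L)
  expect_equal(peaks$qfragDepth, nf * nr)
  # k counts the 5' ends of both pile-ups
  expect_identical(peaks$k, nf + nr)
  expect_equal(peaks$lambda, summitLambda(nf + nr, 1000, 23))
  expect_equal(peaks$pValue, poissonPvalue(nf + nr, peaks$lambda))
})

test_that("peak list is ranked by p, ties by k, and truncated to topN", {
  sim <- simulateHits(SimConfig(seed = 17L, nSites = 30L))
  hits <- deduplicateHits(sim$hits)$hits
  peaks <- callPeaks(hits, width = 18L)
  p <- peaks$pValue
  expect_true(all(diff(p) >= 0))
  ties <- which(diff(p) == 0)
  expect_true(all(peaks$k[ties] >= peaks$k[ties + 1L]))
  expect_equal(peaks$qValue, bhAdjust(p)[seq_along(p)], tolerance = 0)
  top <- callPeaks(hits, params = PeakCallParams(width = 18L, topN = 5L))
  expect_identical(length(top), 5L)
  expect_equal(GenomicRanges::start(top), GenomicRanges::start(peaks)[1:5])
})

test_that("empty input produces an empty, well-formed peak set", {
  hs <- HitSet(seqlengths = sl1)
  peaks <- callPeaks(hs, width = 18L)
  expect_identical(length(peaks), 0L)
  expect_true(all(c("qfragDepth", "k", "lambda", "pValue", "qValue") %in%
                    names(S4Vectors::mcols(peaks))))
})

test_that("qMin is floored at 2 for very small widths", {
  expect_message(params <- PeakCallParams(width = 4L, deviation = 5L),
                 "floored")
  expect_identical(params@qMin, 2L)
  expect_identical(params@qMax, 9L)
})

test_that("peak writers emit BED, narrowPeak and TSV consistently", {
  sim <- simulateHits(SimConfig(seed = 23L, nSites = 10L))
  peaks <- callPeaks(deduplicateHits(sim$hits)$hits, width = 18L)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "summits.bed")
  np <- file.path(dir, "peaks.narrowPeak")
  tsv <- file.path(dir, "summits.tsv")
  writeSummitBed(peaks, bed)
  writeNarrowPeak(peaks, np, extension = 2L)
  writeSummitTable(peaks, tsv)

  b <- utils::read.table(bed, sep = "\t")
  expect_identical(nrow(b), length(peaks))
  # 0-based half-open single-base intervals around the 1-based summit
  expect_equal(b$V2, GenomicRanges::start(peaks) - 1L)
  expect_equal(b$V3, GenomicRanges::start(peaks))

  n <- utils::read.table(np, sep = "\t")
  expect_equal(n$V3 - n$V2, rep(5L, length(peaks)))  # 2 + 1 + 2 bp
  expect_equal(n$V7, peaks$k)
  expect_equal(n$V10, rep(2L, length(peaks)))        # summit offset
  expect_equal(n$V8, round(-log10(peaks$pValue), 5))

  t <- utils::read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(t$pos, GenomicRanges::start(peaks))
  expect_equal(t$qValue, peaks$qValue)
})
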