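sl1 <- c(c1 = 1000L)

test_that("qfrag lengths count ordered forward-reverse pairs from delta=2", {
  hs <- HitSet(chrom = rep("c1", 3), pos = c(10L, 15L, 20L),
               strand = c("f", "r", "r"), seqlengths = sl1)
  q <- qfragCounts(qfragLengthDistribution(hs, 20L))
  expect_equal(unname(q["5"]), 1)
  expect_equal(unname(q["10"]), 1)
  expect_equal(sum(q), 2)

  # multiplicity: two forward reads at one position double the count
  hs <- HitSet(chrom = rep("c1", 3), pos = c(10L, 10L, 15L),
               strand = c("f", "f", "r"), seqlengths = sl1)
  q <- qfragCounts(qfragLengthDistribution(hs, 20L))
  expect_equal(unname(q["5"]), 2)

  # delta starts at 2: a pair at distance 1 contributes nothing
  hs <- HitSet(chrom = rep("c1", 2), pos = c(10L, 11L),
               strand = c("f", "r"), seqlengths = sl1)
  expect_equal(sum(qfragCounts(qfragLengthDistribution(hs, 20L))), 0)

  # reverse upstream of forward (negative distance) contributes nothing
  hs <- HitSet(chrom = rep("c1", 2), pos = c(20L, 10L),
               strand = c("f", "r"), seqlengths = sl1)
  expect_equal(sum(qfragCounts(qfragLengthDistribution(hs, 20L))), 0)
})

test_that("qfrag-length distribution equals the all-pairs oracle", {
  for (seed in 1:8) {
    hs <- randomHitSet(seed, n = sample(50:400, 1), l = 600L,
                       chroms = c("c1", "c2"))
    expect_equal(qfragCounts(qfragLengthDistribution(hs, 110L)),
                 oracleQfragDist(hs, 110L))
  }
})

test_that("pseudo-control applies the strand-swap/shift formulas", {
  hs <- HitSet(chrom = "c1", pos = 100L, strand = "f",
               seqlengths = sl1, readLength = 42L)
  pc <- hitGRanges(pseudoControl(hs))
  expect_identical(GenomicRanges::start(pc), 141L)
  expect_identical(as.character(GenomicRanges::strand(pc)), "-")

  hs <- HitSet(chrom = "c1", pos = 141L, strand = "r",
               seqlengths = sl1, readLength = 42L)
  pc <- hitGRanges(pseudoControl(hs))
  expect_identical(GenomicRanges::start(pc), 100L)
  expect_identical(as.character(GenomicRanges::strand(pc)), "+")
})

test_that("double pseudo-control is the identity away from boundaries", {
  for (seed in 1:6) {
    hs <- randomHitSet(seed, n = 200L, l = 3000L,
                       posRange = c(100L, 2900L), rl = 42L)
    pc2 <- pseudoControl(pseudoControl(hs))
    key <- function(x) {
      gr <- hitGRanges(x)
      sort(paste(GenomicRanges::start(gr),
                 as.character(GenomicRanges::strand(gr))))
    }
    expect_identical(key(pc2), key(hs))
    # single application swaps the strand totals
    sc <- strandCounts(hs); scp <- strandCounts(pseudoControl(hs))
    expect_identical(scp$nForward, sc$nReverse)
    expect_identical(scp$nReverse, sc$nForward)
  }
})

test_that("control distribution is the data distribution reflected at rl-1", {
  rl <- 42L
  for (seed in 1:6) {
    hs <- randomHitSet(seed, n = 150L, l = 3000L,
                       posRange = c(200L, 2800L), rl = rl)
    qt <- qfragCounts(qfragLengthDistribution(hs, 110L))
    qp <- qfragCounts(qfragLengthDistribution(pseudoControl(hs), 110L))
    # a data pair at distance delta becomes a control pair at 2(rl-1)-delta
    for (delta in 2:110) {
      mirror <- 2L * (rl - 1L) - delta
      if (mirror >= 2L && mirror <= 110L)
        expect_equal(unname(qp[as.character(delta)]),
                     unname(qt[as.character(mirror)]))
    }
    # and both must equal the brute-force oracle on the transformed hits
    expect_equal(qp, oracleQfragDist(pseudoControl(hs), 110L))
  }
})

test_that("boundary hits whose control position leaves the chromosome drop", {
  hs <- HitSet(chrom = rep("c1", 2), pos = c(5L, 990L),
               strand = c("r", "f"), seqlengths = sl1, readLength = 42L)
  expect_message(pc <- pseudoControl(hs), "dropped")
  # (5,r) -> (5-41) < 1 dropped; (990,f) -> (1031,-) > 1000 dropped
  expect_identical(nHits(pc), 0L)
})

test_that("width signature peaks at the planted width, not the phantom", {
  simp <- simulateHits(SimConfig(seed = 5L, nSites = 0L,
                                 backgroundRate = 0,
                                 nPhantomLoci = 40L))
  qt <- qfragCounts(qfragLengthDistribution(simp$hits, 110L))
  rl <- readLength(simp$hits)
  # raw distribution is dominated by the artifact at one read length - 1
  expect_identical(as.integer(names(qt)[which.max(qt)]), rl - 1L)
  # the transform leaves the artifact invariant, so it cancels exactly
  ws <- suppressMessages(estimateProtectedWidth(simp$hits))
  expect_true(ws@degenerate)
  expect_false(widthEstimate(ws) == rl - 1L)
  expect_equal(max(signatureTable(ws)$difference), 0)
})

test_that("constant signature falls back to delta=2 and is flagged", {
  # a perfectly phantom-like pair: data and control distributions agree
  hs <- HitSet(chrom = rep("c1", 2), pos = c(100L, 141L),
               strand = c("f", "r"), seqlengths = sl1, readLength = 42L)
  ws <- suppressMessages(estimateProtectedWidth(hs, deltaMax = 60L))
  expect_true(ws@degenerate)
  expect_identical(widthEstimate(ws), 2L)
})

test_that("width estimation requires hits on both strands", {
  hs <- HitSet(chrom = rep("c1", 3), pos = c(10L, 20L, 30L),
               strand = rep("f", 3), seqlengths = sl1, readLength = 42L)
  expect_error(estimateProtectedWidth(hs), "no qfrags")
})

test_that("signature is additive across chromosomes", {
  hsBoth <- randomHitSet(21L, n = 300L, l = 3000L,
                         chroms = c("c1", "c2"),
                         posRange = c(200L, 2800L))
  gr <- hitGRanges(hsBoth)
  one <- function(ch) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    HitSet(chrom = rep(ch, sum(sel)),
           pos = GenomicRanges::start(gr)[sel],
           strand = ifelse(as.character(
             GenomicRanges::strand(gr)[sel]) == "+", "f", "r"),
           seqlengths = stats::setNames(3000L, ch), readLength = 42L)
  }
  dAll <- signatureTable(estimateProtectedWidth(hsBoth))$difference
  d1 <- signatureTable(estimateProtectedWidth(one("c1")))$difference
  d2 <- signatureTable(estimateProtectedWidth(one("c2")))$difference
  expect_equal(dAll, d1 + d2)
})

test_that("signature TSV records the table and estimate", {
  sim <- simulateHits(SimConfig(seed = 2L, nSites = 30L))
  ws <- estimateProtectedWidth(sim$hits)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignatureTable(ws, path)
  hdr <- readLines(path, n = 1L)
  expect_identical(hdr, sprintf("#widthEstimate\t%d", widthEstimate(ws)))
  back <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#")
  expect_equal(back$difference, signatureTable(ws)$difference)
})
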