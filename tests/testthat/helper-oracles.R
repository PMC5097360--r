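suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# random barcoded/unbarcoded hit set; positions confined to posRange so
# boundary-free algebraic identities can be exercised
randomHitSet <- function(seed, n = 200L, l = 3000L, chroms = "c1",
                         barcode = FALSE, posRange = c(1L, NA),
                         rl = 42L) {
  set.seed(seed)
  if (is.na(posRange[2])) posRange[2] <- l
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- sample(seq.int(posRange[1], posRange[2]), n, replace = TRUE)
  strand <- sample(c("f", "r"), n, replace = TRUE)
  bc <- NULL
  if (barcode)
    bc <- replicate(n, paste0(sample(c("A", "C", "G", "T"), 3L,
                                     replace = TRUE), collapse = ""))
  HitSet(chrom = chrom, pos = pos, strand = strand, barcode = bc,
         seqlengths = stats::setNames(rep(l, length(chroms)), chroms),
         readLength = rl)
}

.split_strand_positions <- function(hs) {
  gr <- hitGRanges(hs)
  lapply(GenomeInfoDb::seqlevels(gr), function(ch) {
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    s <- as.character(GenomicRanges::strand(gr))[sel]
    p <- GenomicRanges::start(gr)[sel]
    list(chrom = ch, f = p[s == "+"], r = p[s == "-"])
  })
}

# O(n^2) all-pairs qfrag-length oracle
oracleQfragDist <- function(hs, deltaMax) {
  counts <- stats::setNames(numeric(deltaMax - 1L), 2:deltaMax)
  for (tab in .split_strand_positions(hs)) {
    if (!length(tab$f) || !length(tab$r)) next
    d <- as.vector(outer(tab$r, tab$f, "-"))
    d <- d[d >= 2L & d <= deltaMax]
    if (length(d)) {
      t <- table(d)
      counts[names(t)] <- counts[names(t)] + as.numeric(t)
    }
  }
  counts
}

# O(n^2) interval-stacking qfrag coverage oracle (plain integer vectors)
oracleQfragCoverage <- function(hs, qMin, qMax) {
  sl <- chromLengths(hs)
  tabs <- .split_strand_positions(hs)
  out <- lapply(tabs, function(tab) {
    v <- numeric(sl[[tab$chrom]])
    for (f in tab$f) for (r in tab$r) {
      d <- r - f
      if (d >= qMin && d <= qMax) v[f:r] <- v[f:r] + 1
    }
    v
  })
  names(out) <- vapply(tabs, `[[`, character(1), "chrom")
  out
}

# verbatim free-standing summit definition on a plain coverage vector:
# depth >= 1, no higher depth within +/- qMin, leftmost of each plateau
oracleSummits <- function(v, qMin) {
  l <- length(v)
  out <- integer(0)
  for (p in seq_len(l)) {
    if (v[p] < 1) next
    lo <- max(1L, p - qMin); hi <- min(l, p + qMin)
    if (any(v[lo:hi] > v[p])) next
    if (p > 1L && v[p - 1L] == v[p]) next  # not leftmost of its plateau
    out <- c(out, p)
  }
  out
}

# brute-force adapter clip: try every suffix/prefix overlap, leftmost
# qualifying (= largest overlap) wins; returns clip index or 0
oracleClipIndex <- function(seq, adapter, minOverlap = 3L) {
  n <- nchar(seq)
  maxOv <- min(n, nchar(adapter))
  if (maxOv < minOverlap) return(0L)
  for (ov in seq.int(maxOv, minOverlap)) {  # large overlap = leftmost match
    i <- n - ov + 1L
    if (substr(seq, i, n) == substr(adapter, 1L, ov)) return(i)
  }
  0L
}

# step-up BH, written out by hand
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# upper-tail Poisson by direct series summation of the tail (no
# subtraction from 1, so small tails keep full relative precision)
oraclePoissonUpper <- function(k, lambda) {
  if (k == 0L) return(1)
  i <- k
  term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  total <- 0
  while (term > total * 1e-18 || i < k + 60L) {
    total <- total + term
    i <- i + 1L
    term <- term * lambda / i
    if (i > k + 1e4L) break
  }
  total
}

# minimal single-end SAM writer for loadHits fixtures
writeTestSam <- function(path, aln, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  qw <- vapply(aln$cigar, function(cg) {
    if (cg == "*") return(10L)
    len <- as.integer(regmatches(cg, gregexpr("\\d+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
    sum(len[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   aln$qname, aln$flag, aln$rname, aln$pos,
                   if (is.null(aln$mapq)) rep(42L, nrow(aln)) else aln$mapq,
                   aln$cigar, strrep("A", qw), strrep("I", qw))
  writeLines(c(hdr, lines), path)
  path
}

# 4-line FASTQ writer for preprocess fixtures
writeTestFastq <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(ids))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  path
}
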