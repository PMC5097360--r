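#' @include AllClasses.R HitSet-methods.R qfrag.R
NULL

#' Construct peak-calling parameters
#'
#' @param width Protected-region width in bp (estimated via
#'   [estimateProtectedWidth()] or user-set).
#' @param deviation Allowed deviation x from the width; qfrags are formed
#'   for lengths in `[width - deviation, width + deviation]` (default 5).
#' @param topN Maximum number of peaks reported (default 200000).
#' @param summitExtension Summit extension in bp for interval output
#'   (default 2).
#' @param qValueCutoff Optional q-value cutoff (default `NA`, off).
#' @param poolLambda Use one genome-pooled Poisson rate instead of
#'   per-chromosome rates (default `FALSE`).
#' @return A [PeakCallParams-class]. `qMin` is floored at 2 (with a
#'   message) for very small widths.
#' @export
PeakCallParams <- function(width, deviation = 5L, topN = 200000L,
                           summitExtension = 2L, qValueCutoff = NA_real_,
                           poolLambda = FALSE) {
  width <- as.integer(width)
  deviation <- as.integer(deviation)
  qMin <- width - deviation
  if (qMin < 2L) {
    message("qMin floored at 2 (width - deviation = ", qMin, ")")
    qMin <- 2L
  }
  new("PeakCallParams", width = width, deviation = deviation,
      qMin = qMin, qMax = width + deviation, topN = as.integer(topN),
      summitExtension = as.integer(summitExtension),
      qValueCutoff = as.numeric(qValueCutoff),
      poolLambda = isTRUE(poolLambda))
}

setMethod("show", "PeakCallParams", function(object) {
  cat("PeakCallParams\n")
  cat("  width", object@width, "bp, qfrag lengths [", object@qMin, ",",
      object@qMax, "]\n")
  cat("  topN", object@topN, ", summit extension", object@summitExtension,
      "bp\n")
})

#' qfrag coverage profile
#'
#' Every forward/reverse hit pair (f, r) on one chromosome with
#' `qMin <= r - f <= qMax` forms a qfrag covering the closed interval
#' `[f, r]`; the qfrag depth at a position is the number of qfrags
#' covering it, counted with read multiplicity. Regions flanked by paired
#' 5'-end pile-ups on opposite strands are thereby selectively emphasised
#' relative to plain read or 5'-end coverage.
#'
#' @param x A [HitSet-class].
#' @param qMin,qMax Inclusive qfrag length bounds (`qMin >= 2`).
#' @return A named `RleList` (one numeric run-length vector per
#'   chromosome, full chromosome length).
#' @examples
#' hs <- HitSet(chrom = c("chr1", "chr1"), pos = c(100L, 115L),
#'              strand = c("f", "r"), seqlengths = c(chr1 = 200L))
#' cov <- qfragCoverage(hs, 13L, 23L)
#' which(as.integer(cov$chr1) > 0)  # 100..115
#' @export
qfragCoverage <- function(x, qMin, qMax) {
  stopifnot(is(x, "HitSet"), qMin >= 2L, qMax >= qMin)
  qMin <- as.integer(qMin); qMax <- as.integer(qMax)
  sl <- chromLengths(x)
  tabs <- .strand_count_tables(x)
  covs <- lapply(names(sl), function(ch) {
    tab <- tabs[[ch]]
    l <- sl[[ch]]
    if (!length(tab$fPos) || !length(tab$rPos))
      return(S4Vectors::Rle(0, l))
    starts <- integer(0); ends <- integer(0); weights <- numeric(0)
    for (delta in qMin:qMax) {
      j <- match(tab$fPos + delta, tab$rPos)
      ok <- !is.na(j)
      if (any(ok)) {
        starts <- c(starts, tab$fPos[ok])
        ends <- c(ends, tab$fPos[ok] + delta)
        weights <- c(weights, tab$fCount[ok] * tab$rCount[j[ok]])
      }
    }
    if (!length(starts))
      return(S4Vectors::Rle(0, l))
    IRanges::coverage(IRanges::IRanges(start = starts, end = ends),
                      weight = weights, width = l)
  })
  names(covs) <- names(sl)
  methods::as(covs, "SimpleRleList")
}

#' Free-standing local maxima of a qfrag coverage profile
#'
#' A summit is a covered position whose qfrag depth is not exceeded
#' anywhere within a radius of `qMin`; for a plateau (maximal run of
#' equal depth) the leftmost position is reported.
#'
#' @param coverage `RleList` from [qfragCoverage()].
#' @param qMin Free-standing radius in bp.
#' @return `GRanges` of width-1 summit positions with metadata column
#'   `qfragDepth`.
#' @export
findSummits <- function(coverage, qMin) {
  qMin <- as.integer(qMin)
  sl <- vapply(coverage, length, numeric(1))
  out <- lapply(names(coverage), function(ch) {
    cov <- coverage[[ch]]
    l <- length(cov)
    rv <- S4Vectors::runValue(cov)
    starts <- cumsum(c(1L, S4Vectors::runLength(cov)))
    starts <- starts[-length(starts)]
    cand <- which(rv >= 1)
    if (!length(cand)) return(NULL)
    s <- starts[cand]
    win <- IRanges::Views(cov, start = pmax(1L, s - qMin),
                          end = pmin(l, s + qMin))
    ok <- IRanges::viewMaxs(win) <= rv[cand]
    if (!any(ok)) return(NULL)
    data.frame(chrom = ch, pos = s[ok], depth = rv[cand][ok])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(GRanges(seqinfo = Seqinfo(names(coverage),
                                     as.integer(sl))))
  gr <- GRanges(seqnames = factor(out$chrom, levels = names(coverage)),
                ranges = IRanges::IRanges(start = out$pos, width = 1L),
                strand = "*",
                seqinfo = Seqinfo(names(coverage), as.integer(sl)))
  mcols(gr)$qfragDepth <- out$depth
  gr
}

#' Poisson background rate for summit testing
#'
#' Under a null in which reads are evenly distributed along the
#' chromosome, the expected number of 5' ends near a summit is
#' `lambda = 2 * qMax * (nF + nR) / l`, where `nF + nR` is the total hit
#' count of the chromosome of length `l`.
#'
#' @param nHits Total hits (both strands) on the chromosome; vectorised.
#' @param chromLength Chromosome length in bp.
#' @param qMax Maximum qfrag length.
#' @return Numeric lambda (vectorised over `nHits`/`chromLength`).
#' @examples
#' summitLambda(1000, 1e6, 23)  # 0.046
#' @export
summitLambda <- function(nHits, chromLength, qMax) {
  if (any(chromLength <= 0)) stop("chromosome length must be positive")
  if (any(nHits < 0)) stop("hit counts must be non-negative")
  2 * qMax * nHits / chromLength
}

#' Upper-tail Poisson p-value
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, computed via the survival
#' function for numerical stability; `P(X >= 0) = 1`.
#'
#' @param k Observed count (non-negative integer; vectorised).
#' @param lambda Poisson mean (non-negative; vectorised).
#' @return Numeric p-value(s) in `[0, 1]`.
#' @examples
#' poissonPvalue(1, 1)  # 1 - exp(-1)
#' @export
poissonPvalue <- function(k, lambda) {
  if (any(k < 0)) stop("k must be non-negative")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control across all tested summits genome-wide.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call ChIP-nexus/ChIP-exo peaks from deduplicated hits
#'
#' Pipeline: form qfrags within `[qMin, qMax]` ([qfragCoverage()]), detect
#' free-standing summits ([findSummits()]), count for each summit the 5'
#' ends of both strands within `[s - qMax, s + qMax]` (k), compute the
#' per-chromosome background rate ([summitLambda()]), test every summit in
#' a covered region ([poissonPvalue()]), correct genome-wide
#' ([bhAdjust()]), sort by p-value (ties: larger k first, then
#' coordinate) and truncate to `topN`.
#'
#' For ChIP-nexus the input should be the deduplicated (IMUB) hit set; for
#' ChIP-exo deduplication is skipped upstream and all mapped hits are
#' passed directly.
#'
#' @param x A [HitSet-class].
#' @param params A [PeakCallParams-class], or `NULL` to build one from
#'   `width`/`deviation`.
#' @param width Protected-region width; when `NULL` (default) it is
#'   estimated internally via [estimateProtectedWidth()].
#' @param deviation Allowed deviation x (default 5), used when `params`
#'   is `NULL`.
#' @param deltaMax Passed to the internal width estimation (default 110).
#' @param ... Further arguments to [PeakCallParams()].
#' @return `GRanges` of width-1 summits ordered by significance, with
#'   metadata columns `qfragDepth`, `k`, `lambda`, `pValue`, `qValue`.
#'   Empty input yields an empty `GRanges`.
#' @examples
#' sim <- simulateHits(SimConfig(seed = 7L, nSites = 20L))
#' hits <- deduplicateHits(sim$hits)$hits
#' peaks <- callPeaks(hits, width = 18L)
#' head(peaks)
#' @export
callPeaks <- function(x, params = NULL, width = NULL, deviation = 5L,
                      deltaMax = 110L, ...) {
  stopifnot(is(x, "HitSet"))
  if (is.null(params)) {
    if (is.null(width)) {
      width <- widthEstimate(estimateProtectedWidth(x, deltaMax = deltaMax))
      message("estimated protected-region width: ", width, " bp")
    }
    params <- PeakCallParams(width = width, deviation = deviation, ...)
  }
  stopifnot(is(params, "PeakCallParams"))
  sl <- chromLengths(x)
  emptyResult <- function() {
    gr <- GRanges(seqinfo = Seqinfo(names(sl), unname(sl)))
    mcols(gr) <- S4Vectors::DataFrame(qfragDepth = integer(),
                                      k = integer(), lambda = numeric(),
                                      pValue = numeric(),
                                      qValue = numeric())
    gr
  }
  if (!nHits(x)) return(emptyResult())
  cov <- qfragCoverage(x, params@qMin, params@qMax)
  summits <- findSummits(cov, params@qMin)
  if (!length(summits)) return(emptyResult())

  # k: 5' ends of both strands, with multiplicity, in [s - qMax, s + qMax]
  hitPos <- hitGRanges(x)
  win <- GRanges(seqnames = seqnames(summits),
                 ranges = IRanges::IRanges(
                   start = pmax(1L, BiocGenerics::start(summits) - params@qMax),
                   end = pmin(sl[as.character(seqnames(summits))],
                              BiocGenerics::start(summits) + params@qMax)),
                 seqinfo = GenomeInfoDb::seqinfo(summits))
  k <- GenomicRanges::countOverlaps(win, hitPos, ignore.strand = TRUE)

  sc <- strandCounts(x)
  lam <- if (params@poolLambda) {
    rep(summitLambda(sum(sc$nForward + sc$nReverse), sum(sl), params@qMax),
        length(summits))
  } else {
    perChrom <- summitLambda(sc$nForward + sc$nReverse, sl[sc$chrom],
                             params@qMax)
    names(perChrom) <- sc$chrom
    unname(perChrom[as.character(seqnames(summits))])
  }
  p <- poissonPvalue(k, lam)
  q <- bhAdjust(p)

  mcols(summits)$k <- as.integer(k)
  mcols(summits)$lambda <- lam
  mcols(summits)$pValue <- p
  mcols(summits)$qValue <- q
  ord <- order(p, -k, as.integer(seqnames(summits)),
               BiocGenerics::start(summits), method = "radix")
  summits <- summits[ord]
  if (length(summits) > params@topN)
    summits <- summits[seq_len(params@topN)]
  if (!is.na(params@qValueCutoff))
    summits <- summits[mcols(summits)$qValue <= params@qValueCutoff]
  mcols(summits) <- mcols(summits)[, c("qfragDepth", "k", "lambda",
                                       "pValue", "qValue")]
  summits
}

.bed_score <- function(q) {
  as.integer(pmin(1000, round(-10 * log10(pmax(q, 1e-300)))))
}

#' Write summits as BED
#'
#' 0-based half-open single-base intervals, score column
#' `min(1000, round(-10 log10 q))`.
#'
#' @param peaks Summit `GRanges` from [callPeaks()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeSummitBed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::start(peaks),
    name = if (length(peaks)) paste0("summit_", seq_along(peaks))
           else character(),
    score = .bed_score(mcols(peaks)$qValue),
    strand = rep(".", length(peaks)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks in narrowPeak format
#'
#' Each summit is extended by `extension` bp on both sides (clipped at
#' chromosome boundaries); columns 7-10 carry the 5'-end count k,
#' -log10 p, -log10 q and the summit offset within the interval.
#'
#' @param peaks Summit `GRanges` from [callPeaks()].
#' @param path Output narrowPeak path.
#' @param extension bp added on each side of the summit (default 2).
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path, extension = 2L) {
  sl <- seqlengths(peaks)
  s <- BiocGenerics::start(peaks)
  left <- pmax(1L, s - extension)
  right <- pmin(sl[as.character(seqnames(peaks))], s + extension)
  q <- mcols(peaks)$qValue
  p <- mcols(peaks)$pValue
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = left - 1L,
    end = right,
    name = if (length(peaks)) paste0("peak_", seq_along(peaks))
           else character(),
    score = .bed_score(q),
    strand = rep(".", length(peaks)),
    signalValue = mcols(peaks)$k,
    pValue = round(-log10(pmax(p, 1e-300)), 5),
    qValue = round(-log10(pmax(q, 1e-300)), 5),
    peak = s - left)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the full summit table as TSV
#'
#' @param peaks Summit `GRanges` from [callPeaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSummitTable <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    pos = BiocGenerics::start(peaks),
    qfragDepth = mcols(peaks)$qfragDepth,
    k = mcols(peaks)$k,
    lambda = mcols(peaks)$lambda,
    pValue = mcols(peaks)$pValue,
    qValue = mcols(peaks)$qValue)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
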