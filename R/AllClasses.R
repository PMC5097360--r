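#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom GenomeInfoDb seqlengths seqnames seqlevels Seqinfo
#' @importFrom S4Vectors mcols mcols<-
NULL

#' HitSet: strand-aware 5'-end mapping events
#'
#' The atom of all downstream computation is a *hit*: the 5'-end position
#' and strand of a uniquely mapped single-end read. A `HitSet` stores one
#' width-1 `GRanges` row per read (so identically mapped reads appear with
#' multiplicity), the chromosome lengths in its `seqinfo`, an optional
#' per-read random barcode, and the modal mapped read length `rl`.
#'
#' Coordinates are 1-based and fully closed throughout the package; BED
#' output converts to 0-based half-open at the boundary.
#'
#' @slot hits `GRanges`, width-1 ranges (5' ends) with strand `+`
#'   (forward) or `-` (reverse) and a `barcode` metadata column
#'   (`character`, `NA` when absent).
#' @slot readLength Integer scalar or `NA`: modal mapped read length.
#'
#' @seealso [HitSet()] for construction, [loadHits()] to build one from
#'   SAM/BAM, [deduplicateHits()], [qfragLengthDistribution()],
#'   [callPeaks()].
#' @export
setClass("HitSet",
  slots = c(hits = "GRanges", readLength = "integer"))

setValidity("HitSet", function(object) {
  gr <- object@hits
  msg <- character()
  if (length(gr)) {
    if (any(BiocGenerics::width(gr) != 1L))
      msg <- c(msg, "all hit ranges must have width 1")
    if (any(as.character(BiocGenerics::strand(gr)) == "*"))
      msg <- c(msg, "hit strand must be '+' or '-', not '*'")
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
      msg <- c(msg, "all chromosome lengths must be defined in seqinfo")
    else {
      lens <- sl[as.character(seqnames(gr))]
      if (any(BiocGenerics::start(gr) < 1L) ||
          any(BiocGenerics::start(gr) > lens))
        msg <- c(msg, "hit positions must lie within [1, chromosome length]")
    }
    if (is.null(mcols(gr)$barcode))
      msg <- c(msg, "hits must carry a 'barcode' metadata column")
  }
  if (length(object@readLength) != 1L)
    msg <- c(msg, "readLength must be a single integer (possibly NA)")
  else if (!is.na(object@readLength) && object@readLength < 1L)
    msg <- c(msg, "readLength must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BarcodeConfig: geometry of the ChIP-nexus read prefix
#'
#' Raw ChIP-nexus reads start with a random barcode of `randomLen`
#' nucleotides followed immediately by a fixed barcode. The fixed barcode
#' acts as a ligation-fidelity check: reads whose observed fixed barcode
#' differs from the expected one in more than `maxFixedMismatch`
#' nucleotides are discarded. Neither the random-barcode length nor the
#' fixed-barcode sequence is a universal protocol constant, so
#' `fixedBarcode` must be supplied explicitly.
#'
#' @slot randomLen Integer, length of the random (UMI) barcode (default 5).
#' @slot fixedBarcode Character, expected fixed barcode over A/C/G/T.
#' @slot maxFixedMismatch Integer, maximum Hamming distance tolerated in
#'   the fixed barcode (default 1).
#' @slot adapter Character, 3' adapter sequence to clip.
#' @slot minLenAfterClip Integer, minimum insert length after clipping
#'   (default 1).
#' @slot minAdapterOverlap Integer, minimum exact suffix/prefix overlap
#'   for adapter clipping (default 3).
#' @slot idTagPrefix Character, tag prefix used when writing the random
#'   barcode into the read ID (fixed to `"TL:"`).
#'
#' @seealso [BarcodeConfig()], [preprocessFastq()]
#' @export
setClass("BarcodeConfig",
  slots = c(randomLen = "integer", fixedBarcode = "character",
            maxFixedMismatch = "integer", adapter = "character",
            minLenAfterClip = "integer", minAdapterOverlap = "integer",
            idTagPrefix = "character"))

setValidity("BarcodeConfig", function(object) {
  msg <- character()
  if (object@randomLen < 1L) msg <- c(msg, "randomLen must be >= 1")
  if (!nzchar(object@fixedBarcode) ||
      grepl("[^ACGT]", object@fixedBarcode))
    msg <- c(msg, "fixedBarcode must be a non-empty string over {A,C,G,T}")
  if (object@maxFixedMismatch < 0L)
    msg <- c(msg, "maxFixedMismatch must be >= 0")
  if (!nzchar(object@adapter) || grepl("[^ACGT]", object@adapter))
    msg <- c(msg, "adapter must be a non-empty string over {A,C,G,T}")
  if (object@minLenAfterClip < 1L)
    msg <- c(msg, "minLenAfterClip must be >= 1")
  if (object@minAdapterOverlap < 1L)
    msg <- c(msg, "minAdapterOverlap must be >= 1")
  if (length(msg)) msg else TRUE
})

#' QfragLengthDistribution: qfrag counts per candidate length
#'
#' A qfrag is the genomic interval between an ordered pair of hits
#' (forward-strand hit upstream of reverse-strand hit). For each candidate
#' length delta = 2..deltaMax this class stores the number of qfrags of
#' exactly that length, counted with read multiplicity and summed over
#' chromosomes.
#'
#' @slot delta Integer vector `2:deltaMax`.
#' @slot counts Numeric vector of qfrag counts, parallel to `delta`.
#' @slot source Character, `"data"` or `"pseudo_control"`.
#'
#' @seealso [qfragLengthDistribution()], [estimateProtectedWidth()]
#' @export
setClass("QfragLengthDistribution",
  slots = c(delta = "integer", counts = "numeric", source = "character"))

setValidity("QfragLengthDistribution", function(object) {
  msg <- character()
  if (length(object@delta) != length(object@counts))
    msg <- c(msg, "delta and counts must have equal length")
  if (length(object@delta) && object@delta[1L] != 2L)
    msg <- c(msg, "delta must start at 2")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (!object@source %in% c("data", "pseudo_control"))
    msg <- c(msg, "source must be 'data' or 'pseudo_control'")
  if (length(msg)) msg else TRUE
})

#' WidthSignature: protected-region width estimate
#'
#' The difference D(delta) between the qfrag-length distribution of the
#' data and that of its pseudo-control is the width signature; the smallest
#' delta attaining the maximum of D is the protected-region width estimate.
#'
#' @slot table `data.frame` with columns `delta`, `qData`, `qControl`,
#'   `difference`.
#' @slot estimate Integer, the width estimate.
#' @slot readLength Integer, read length used for the pseudo-control.
#' @slot degenerate Logical, `TRUE` when the signature is constant (for
#'   example identically zero) and the estimate is only the tie-break
#'   default.
#'
#' @seealso [estimateProtectedWidth()]
#' @export
setClass("WidthSignature",
  slots = c(table = "data.frame", estimate = "integer",
            readLength = "integer", degenerate = "logical"))

setValidity("WidthSignature", function(object) {
  msg <- character()
  need <- c("delta", "qData", "qControl", "difference")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must have columns delta, qData, qControl, difference")
  else if (nrow(object@table)) {
    d <- object@table
    if (!object@estimate %in% d$delta)
      msg <- c(msg, "estimate must be one of the tabulated delta values")
    else if (d$difference[match(object@estimate, d$delta)] !=
             max(d$difference))
      msg <- c(msg, "estimate must attain the maximum of the signature")
  }
  if (length(msg)) msg else TRUE
})

#' DuplicationProfile: IM/IMIB/IMUB duplication-level statistics
#'
#' Identically mapped (IM) reads share a 5'-end position and strand; IMIB
#' reads additionally share the random barcode (presumed PCR duplicates);
#' IMUB reads are the retained one-per-barcode representatives. For each
#' class the profile records the proportion of that class's reads at each
#' duplication level, and an overall duplication level defined as the
#' proportion of reads with 5'-end depth greater than one.
#'
#' @slot levels `data.frame` with columns `class`, `level`, `nReads`,
#'   `proportion`; `level` values at `levelCap` aggregate all higher
#'   levels.
#' @slot overall Named numeric, overall duplication level per class.
#' @slot nReads Named integer, number of reads per class.
#' @slot levelCap Integer, aggregation ceiling used in `levels`.
#' @slot empty Logical, `TRUE` when the input had no reads.
#'
#' @seealso [duplicationProfile()], [duplicationPlot()]
#' @export
setClass("DuplicationProfile",
  slots = c(levels = "data.frame", overall = "numeric", nReads = "integer",
            levelCap = "integer", empty = "logical"))

setValidity("DuplicationProfile", function(object) {
  msg <- character()
  if (!all(c("class", "level", "nReads", "proportion") %in%
           names(object@levels)))
    msg <- c(msg, "levels must have columns class, level, nReads, proportion")
  if (!all(c("IM", "IMIB", "IMUB") %in% names(object@overall)))
    msg <- c(msg, "overall must be named IM, IMIB, IMUB")
  if (!object@empty) {
    for (cl in unique(object@levels$class)) {
      p <- object@levels$proportion[object@levels$class == cl]
      if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, sprintf("proportions for class %s must sum to 1", cl))
    }
  }
  if (length(msg)) msg else TRUE
})

#' PeakCallParams: tuning of the qfrag-coverage peak caller
#'
#' qfrags are formed from forward/reverse hit pairs whose 5'-end distance
#' lies in `[qMin, qMax] = [width - deviation, width + deviation]`. The
#' candidate list is truncated to the `topN` most significant summits and
#' summits are extended by `summitExtension` bp on both sides in the
#' narrowPeak output.
#'
#' @slot width Integer, protected-region width (estimated or user-set).
#' @slot deviation Integer, allowed deviation x from the width (default 5).
#' @slot qMin,qMax Integer, derived qfrag length bounds (`qMin` floored
#'   at 2).
#' @slot topN Integer, maximum number of peaks reported (default 200000).
#' @slot summitExtension Integer, bp added on each side of a summit in
#'   interval output (default 2).
#' @slot qValueCutoff Numeric or `NA`: optional q-value cutoff applied to
#'   the reported list.
#' @slot poolLambda Logical, use a genome-pooled Poisson rate instead of
#'   per-chromosome rates (default `FALSE`).
#'
#' @seealso [PeakCallParams()], [callPeaks()]
#' @export
setClass("PeakCallParams",
  slots = c(width = "integer", deviation = "integer", qMin = "integer",
            qMax = "integer", topN = "integer", summitExtension = "integer",
            qValueCutoff = "numeric", poolLambda = "logical"))

setValidity("PeakCallParams", function(object) {
  msg <- character()
  if (object@qMin < 2L) msg <- c(msg, "qMin must be >= 2")
  if (object@qMax < object@qMin) msg <- c(msg, "qMax must be >= qMin")
  if (object@width < 2L) msg <- c(msg, "width must be >= 2")
  if (object@topN < 1L) msg <- c(msg, "topN must be >= 1")
  if (object@summitExtension < 0L)
    msg <- c(msg, "summitExtension must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimConfig: study conditions for the ChIP-nexus read simulator
#'
#' Defines a ground-truthed synthetic experiment: binding sites whose
#' protected regions produce strand-paired 5'-end pile-ups separated by
#' `protectedWidth`, barcoded molecules with PCR duplication, uniform
#' background reads, and optional repeat-driven phantom loci whose
#' forward/reverse 5' ends are exactly one read length minus one apart.
#'
#' @slot seed Integer RNG seed; all randomness derives from it.
#' @slot genome Named integer vector of chromosome lengths.
#' @slot nSites Integer, number of planted binding sites.
#' @slot protectedWidth Integer bp, planted forward/reverse 5' distance
#'   (plays the role of the protected-region width).
#' @slot jitterSd Numeric bp, SD of the rounded-Gaussian jitter applied to
#'   each molecule's 5' end.
#' @slot moleculesPerSite Integer, independent molecules per site (split
#'   between strands).
#' @slot pcrDuplicationMean Numeric, Poisson mean of extra PCR copies per
#'   molecule.
#' @slot backgroundRate Numeric, background hits per bp (both strands
#'   combined).
#' @slot readLength Integer bp, sequencing read length `rl`.
#' @slot fragmentLength Integer bp, pre-digestion fragment length
#'   (cosmetic; not used by any estimator).
#' @slot barcodeLen Integer nt, random-barcode length.
#' @slot fixedBarcode Character, fixed barcode emitted in raw reads.
#' @slot adapter Character, adapter sequence appended to short inserts.
#' @slot nPhantomLoci Integer, number of artifact clusters.
#' @slot moleculesPerPhantom Integer, molecules per phantom locus.
#'
#' @seealso [SimConfig()], [simulateHits()], [emitFastq()]
#' @export
setClass("SimConfig",
  slots = c(seed = "integer", genome = "integer", nSites = "integer",
            protectedWidth = "integer", jitterSd = "numeric",
            moleculesPerSite = "integer", pcrDuplicationMean = "numeric",
            backgroundRate = "numeric", readLength = "integer",
            fragmentLength = "integer", barcodeLen = "integer",
            fixedBarcode = "character", adapter = "character",
            nPhantomLoci = "integer", moleculesPerPhantom = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (is.null(names(object@genome)) || any(!nzchar(names(object@genome))))
    msg <- c(msg, "genome must be a named vector of chromosome lengths")
  if (any(object@genome < 1L)) msg <- c(msg, "chromosome lengths must be >= 1")
  if (object@protectedWidth < 2L) msg <- c(msg, "protectedWidth must be >= 2")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (object@backgroundRate < 0) msg <- c(msg, "backgroundRate must be >= 0")
  if (object@pcrDuplicationMean < 0)
    msg <- c(msg, "pcrDuplicationMean must be >= 0")
  if (object@readLength < 2L) msg <- c(msg, "readLength must be >= 2")
  if (object@barcodeLen < 1L) msg <- c(msg, "barcodeLen must be >= 1")
  if (length(msg)) msg else TRUE
})
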