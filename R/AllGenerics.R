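#' @include AllClasses.R
NULL

#' Extract the per-read hit ranges of a HitSet
#'
#' @param x A [HitSet-class] object.
#' @return A `GRanges` with one width-1 range per retained read (5' end),
#'   strand `+`/`-`, and a `barcode` metadata column (may be `NA`).
#' @export
setGeneric("hitGRanges", function(x) standardGeneric("hitGRanges"))

#' Read length associated with a hit set
#'
#' The modal mapped read length, used to construct the pseudo-control.
#'
#' @param x A [HitSet-class] object.
#' @return Integer scalar (may be `NA` if never set).
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname readLength
#' @param value Replacement integer read length.
#' @export
setGeneric("readLength<-", function(x, value) standardGeneric("readLength<-"))

#' Chromosome lengths of a HitSet
#'
#' @param x A [HitSet-class] object.
#' @return Named integer vector of chromosome lengths.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' Number of hits (reads) in a HitSet
#'
#' @param x A [HitSet-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nHits", function(x) standardGeneric("nHits"))

#' Per-chromosome, per-strand hit totals
#'
#' @param x A [HitSet-class] object.
#' @return A `data.frame` with columns `chrom`, `nForward`, `nReverse`.
#' @export
setGeneric("strandCounts", function(x) standardGeneric("strandCounts"))

#' Strand-swap / read-length-shift pseudo-control transform
#'
#' Swaps the strand of every hit and shifts its position by one read length
#' towards the new 5' direction; the transform leaves repeat-driven phantom
#' configurations (forward/reverse 5' ends one read length apart) invariant
#' while destroying genuine short-footprint signal, so that subtracting the
#' pseudo-control qfrag-length distribution cancels the phantom peak.
#'
#' @param x A [HitSet-class] object.
#' @param readLength Read length `rl` used for the shift; defaults to
#'   `readLength(x)`.
#' @return A [HitSet-class] with transformed hits. Hits whose shifted
#'   position falls outside `[1, l]` are dropped (a message reports how
#'   many).
#' @examples
#' hs <- HitSet(chrom = "chr1", pos = c(100L, 141L), strand = c("f", "r"),
#'              seqlengths = c(chr1 = 1000L), readLength = 42L)
#' pc <- pseudoControl(hs)
#' hitGRanges(pc)
#' @export
setGeneric("pseudoControl", function(x, readLength = NULL)
  standardGeneric("pseudoControl"))

#' Counts of a qfrag-length distribution
#'
#' @param x A [QfragLengthDistribution-class] object.
#' @return Named numeric vector of qfrag counts for delta = 2..deltaMax.
#' @export
setGeneric("qfragCounts", function(x) standardGeneric("qfragCounts"))

#' Estimated protected-region width
#'
#' @param x A [WidthSignature-class] object.
#' @return Integer scalar: the width estimate (smallest delta maximizing the
#'   data-minus-control signature).
#' @export
setGeneric("widthEstimate", function(x) standardGeneric("widthEstimate"))

#' Full signature table of a width estimate
#'
#' @param x A [WidthSignature-class] object.
#' @return `data.frame` with columns `delta`, `qData`, `qControl`,
#'   `difference`.
#' @export
setGeneric("signatureTable", function(x) standardGeneric("signatureTable"))

#' Duplication-level table of a DuplicationProfile
#'
#' @param x A [DuplicationProfile-class] object.
#' @return `data.frame` with columns `class` (IM/IMIB/IMUB), `level`,
#'   `nReads`, `proportion`. Levels at or above the cap are aggregated.
#' @export
setGeneric("levelTable", function(x) standardGeneric("levelTable"))

#' Overall duplication levels
#'
#' Proportion of reads of each class with 5'-end depth greater than one.
#'
#' @param x A [DuplicationProfile-class] object.
#' @return Named numeric vector with entries `IM`, `IMIB`, `IMUB`.
#' @export
setGeneric("overallLevels", function(x) standardGeneric("overallLevels"))
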