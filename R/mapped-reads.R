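#' @include AllClasses.R HitSet-methods.R
NULL

.barcode_from_qname <- function(qname) {
  m <- regmatches(qname, regexpr("TL:[ACGTN]+", qname))
  bc <- rep(NA_character_, length(qname))
  hit <- regexpr("TL:[ACGTN]+", qname)
  ok <- hit > 0L
  bc[ok] <- substring(qname[ok], hit[ok] + 3L,
                      hit[ok] + attr(hit, "match.length")[ok] - 1L)
  bc
}

#' Reduce a mapped alignment to its 5'-end hit
#'
#' The 5' end of a forward-strand alignment is its leftmost aligned
#' reference base; for a reverse-strand alignment it is the rightmost
#' aligned base. Evidence for the exonuclease stop is the aligned 5'
#' terminus, so soft-clipped bases are not extrapolated through.
#'
#' @param pos Leftmost aligned reference position (POS field).
#' @param cigar CIGAR string.
#' @param strand `"+"` or `"-"`.
#' @param qname Query name; a `TL:<barcode>` token, if present, is parsed
#'   into the barcode.
#' @return `data.frame` with columns `pos` (5' end), `strand`, `barcode`.
#' @examples
#' fivePrimePosition(100L, "36M", "+", "READ7:TL:ATGCC")
#' fivePrimePosition(100L, "36M", "-", "READ8")
#' @export
fivePrimePosition <- function(pos, cigar, strand, qname = NA_character_) {
  refWidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  p5 <- ifelse(strand == "+", pos, pos + refWidth - 1L)
  data.frame(pos = as.integer(p5), strand = as.character(strand),
             barcode = .barcode_from_qname(as.character(qname)),
             stringsAsFactors = FALSE)
}

#' Load mapped reads from SAM/BAM into a HitSet
#'
#' Retains mapped, primary, non-supplementary single-end alignments and
#' reduces each to a strand-aware 5'-end hit with multiplicity. Chromosome
#' lengths come from the header. The mapper is trusted to have emitted
#' only uniquely mapped reads; an optional MAPQ floor is available.
#'
#' @param file SAM or BAM path (SAM is converted on the fly).
#' @param includeChrom Optional character vector: keep only these
#'   chromosomes.
#' @param excludeChrom Optional character vector: drop these chromosomes
#'   (e.g. repeat-rich scaffolds that drive phantom artifacts).
#' @param minMapq Optional minimum MAPQ (default `NULL`, off).
#' @param readLength Override for the modal read length; by default the
#'   modal query width of retained alignments.
#' @return A [HitSet-class]. An input without mapped reads yields an empty
#'   (valid) HitSet.
#' @export
loadHits <- function(file, includeChrom = NULL, excludeChrom = NULL,
                     minMapq = NULL, readLength = NULL) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(file)[[1L]]
  sl <- hdr$targets
  if (is.null(sl) || !length(sl))
    stop("BAM header defines no chromosome lengths")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth",
             "cigar", "mapq"))
  b <- Rsamtools::scanBam(file, param = param)[[1L]]
  flag <- b$flag
  keep <- !is.na(b$pos) &
    bitwAnd(flag, 0x4L) == 0L &     # mapped
    bitwAnd(flag, 0x100L) == 0L &   # primary
    bitwAnd(flag, 0x800L) == 0L     # not supplementary
  nSkipped <- sum(!keep)
  if (nSkipped)
    message(nSkipped, " unmapped/secondary/supplementary record(s) skipped")
  if (!is.null(minMapq))
    keep <- keep & !is.na(b$mapq) & b$mapq >= minMapq
  strand <- as.character(b$strand[keep])
  fp <- fivePrimePosition(b$pos[keep], b$cigar[keep], strand,
                          b$qname[keep])
  chrom <- as.character(b$rname[keep])
  sel <- rep(TRUE, nrow(fp))
  if (!is.null(includeChrom)) sel <- sel & chrom %in% includeChrom
  if (!is.null(excludeChrom)) sel <- sel & !chrom %in% excludeChrom
  keepLv <- names(sl)
  if (!is.null(includeChrom)) keepLv <- intersect(keepLv, includeChrom)
  if (!is.null(excludeChrom)) keepLv <- setdiff(keepLv, excludeChrom)
  rl <- if (!is.null(readLength)) as.integer(readLength) else {
    qw <- b$qwidth[keep]
    if (length(qw)) {
      tab <- table(qw)
      as.integer(names(tab)[which.max(tab)])
    } else NA_integer_
  }
  HitSet(chrom = chrom[sel], pos = fp$pos[sel], strand = fp$strand[sel],
         barcode = fp$barcode[sel], seqlengths = sl[keepLv],
         readLength = rl)
}

#' Restrict a HitSet to a subset of chromosomes
#'
#' @param x A [HitSet-class].
#' @param includeChrom Optional chromosomes to keep.
#' @param excludeChrom Optional chromosomes to drop.
#' @return A [HitSet-class] whose seqinfo is restricted accordingly.
#' @export
filterChromosomes <- function(x, includeChrom = NULL, excludeChrom = NULL) {
  stopifnot(is(x, "HitSet"))
  keepLv <- seqlevels(x@hits)
  if (!is.null(includeChrom)) keepLv <- intersect(keepLv, includeChrom)
  if (!is.null(excludeChrom)) keepLv <- setdiff(keepLv, excludeChrom)
  gr <- x@hits[as.character(seqnames(x@hits)) %in% keepLv]
  gr <- GenomeInfoDb::keepSeqlevels(gr, keepLv, pruning.mode = "coarse")
  .hitset_from_granges(gr, x@readLength)
}
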