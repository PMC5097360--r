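#' @include AllClasses.R AllGenerics.R
NULL

.strand_to_plus_minus <- function(strand) {
  s <- as.character(strand)
  s[s == "f"] <- "+"
  s[s == "r"] <- "-"
  if (any(!s %in% c("+", "-")))
    stop("strand must be 'f'/'r' or '+'/'-'")
  s
}

#' Construct a HitSet from parallel vectors
#'
#' @param chrom Character vector of chromosome names (one per read).
#' @param pos Integer vector of 1-based 5'-end positions.
#' @param strand Character vector, `"f"`/`"r"` or `"+"`/`"-"`.
#' @param barcode Optional character vector of random barcodes; `NULL`
#'   stores `NA` for every read.
#' @param seqlengths Named integer vector of chromosome lengths; must cover
#'   every chromosome in `chrom`.
#' @param readLength Modal mapped read length (integer or `NA`).
#' @return A [HitSet-class] object.
#' @examples
#' hs <- HitSet(chrom = c("chr1", "chr1"), pos = c(10L, 15L),
#'              strand = c("f", "r"), seqlengths = c(chr1 = 1000L))
#' nHits(hs)
#' @export
HitSet <- function(chrom = character(), pos = integer(),
                   strand = character(), barcode = NULL,
                   seqlengths = integer(), readLength = NA_integer_) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  if (is.null(barcode)) barcode <- rep(NA_character_, length(pos))
  stopifnot(length(barcode) == length(pos))
  sl <- as.integer(seqlengths)
  names(sl) <- names(seqlengths)
  gr <- GRanges(
    seqnames = factor(chrom, levels = names(sl)),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    strand = .strand_to_plus_minus(strand),
    seqinfo = Seqinfo(seqnames = names(sl), seqlengths = sl))
  mcols(gr)$barcode <- as.character(barcode)
  new("HitSet", hits = gr, readLength = as.integer(readLength)[1L])
}

.hitset_from_granges <- function(gr, readLength) {
  if (is.null(mcols(gr)$barcode))
    mcols(gr)$barcode <- rep(NA_character_, length(gr))
  new("HitSet", hits = gr, readLength = as.integer(readLength)[1L])
}

#' @rdname hitGRanges
#' @export
setMethod("hitGRanges", "HitSet", function(x) x@hits)

#' @rdname readLength
#' @export
setMethod("readLength", "HitSet", function(x) x@readLength)

#' @rdname readLength
#' @export
setMethod("readLength<-", "HitSet", function(x, value) {
  x@readLength <- as.integer(value)[1L]
  validObject(x)
  x
})

#' @rdname chromLengths
#' @export
setMethod("chromLengths", "HitSet", function(x) seqlengths(x@hits))

#' @rdname nHits
#' @export
setMethod("nHits", "HitSet", function(x) length(x@hits))

#' @rdname strandCounts
#' @export
setMethod("strandCounts", "HitSet", function(x) {
  chroms <- seqlevels(x@hits)
  s <- as.character(BiocGenerics::strand(x@hits))
  cn <- as.character(seqnames(x@hits))
  data.frame(
    chrom = chroms,
    nForward = as.integer(table(factor(cn[s == "+"], levels = chroms))),
    nReverse = as.integer(table(factor(cn[s == "-"], levels = chroms))),
    row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "HitSet", function(object) {
  sc <- strandCounts(object)
  cat("HitSet with", nHits(object), "hits on", nrow(sc),
      "chromosome(s)\n")
  cat("  forward:", sum(sc$nForward), " reverse:", sum(sc$nReverse), "\n")
  nbc <- sum(!is.na(mcols(object@hits)$barcode))
  cat("  barcoded hits:", nbc, "\n")
  cat("  read length:", object@readLength, "\n")
})

#' @rdname pseudoControl
#' @export
setMethod("pseudoControl", "HitSet", function(x, readLength = NULL) {
  rl <- if (is.null(readLength)) x@readLength else as.integer(readLength)
  if (is.na(rl) || rl < 2L)
    stop("a read length >= 2 is required for the pseudo-control")
  gr <- x@hits
  s <- as.character(BiocGenerics::strand(gr))
  pos <- BiocGenerics::start(gr)
  newStrand <- ifelse(s == "+", "-", "+")
  # shift towards the new 5' direction: new '-' hits move right, new '+' left
  newPos <- ifelse(newStrand == "-", pos + rl - 1L, pos - rl + 1L)
  lens <- seqlengths(gr)[as.character(seqnames(gr))]
  keep <- newPos >= 1L & newPos <= lens
  if (any(!keep))
    message(sum(!keep), " hit(s) dropped: pseudo-control position outside ",
            "the chromosome")
  out <- GRanges(
    seqnames = seqnames(gr)[keep],
    ranges = IRanges::IRanges(start = as.integer(newPos[keep]), width = 1L),
    strand = newStrand[keep],
    seqinfo = GenomeInfoDb::seqinfo(gr))
  mcols(out)$barcode <- mcols(gr)$barcode[keep]
  new("HitSet", hits = out, readLength = x@readLength)
})

#' Write a HitSet to a TSV hit table
#'
#' Plain-text exchange format (chrom, pos, strand, barcode, one row per
#' read, `f`/`r` strand codes) used by the analytic modules and as a
#' deterministic, diffable record of a deduplicated hit set. A header line
#' starting with `#` carries the chromosome lengths and read length.
#'
#' @param x A [HitSet-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readHitTable()]
#' @export
writeHitTable <- function(x, path) {
  stopifnot(is(x, "HitSet"))
  gr <- hitGRanges(x)
  ord <- order(as.integer(seqnames(gr)), BiocGenerics::start(gr),
               as.character(BiocGenerics::strand(gr)),
               mcols(gr)$barcode, method = "radix")
  gr <- gr[ord]
  sl <- chromLengths(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#seqlengths\t",
                    paste(names(sl), sl, sep = ":", collapse = ",")), con)
  writeLines(paste0("#readLength\t", x@readLength), con)
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    pos = BiocGenerics::start(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "+", "f", "r"),
    barcode = ifelse(is.na(mcols(gr)$barcode), ".", mcols(gr)$barcode))
  writeLines("chrom\tpos\tstrand\tbarcode", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a HitSet from a TSV hit table
#'
#' @param path File written by [writeHitTable()].
#' @return A [HitSet-class] object.
#' @export
readHitTable <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!startsWith(hdr[1L], "#seqlengths") || !startsWith(hdr[2L], "#readLength"))
    stop("not a hit table: missing #seqlengths/#readLength header")
  slSpec <- strsplit(sub("^#seqlengths\t", "", hdr[1L]), ",", fixed = TRUE)[[1L]]
  parts <- strsplit(slSpec, ":", fixed = TRUE)
  sl <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  names(sl) <- vapply(parts, `[`, character(1), 1L)
  rl <- as.integer(sub("^#readLength\t", "", hdr[2L]))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  bc <- df$barcode
  bc[bc == "."] <- NA_character_
  HitSet(chrom = df$chrom, pos = df$pos, strand = df$strand, barcode = bc,
         seqlengths = sl, readLength = rl)
}
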