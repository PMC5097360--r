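#' @include AllClasses.R
NULL

#' Construct a BarcodeConfig
#'
#' @param fixedBarcode Expected fixed barcode (required; there is no
#'   universal default — it is protocol-specific).
#' @param adapter 3' adapter sequence (required).
#' @param randomLen Random-barcode length in nt (default 5).
#' @param maxFixedMismatch Maximum Hamming distance tolerated in the fixed
#'   barcode (default 1).
#' @param minLenAfterClip Minimum insert length surviving adapter clipping
#'   (default 1).
#' @param minAdapterOverlap Minimum exact adapter-prefix/read-suffix
#'   overlap for clipping (default 3).
#' @return A [BarcodeConfig-class] object.
#' @examples
#' cfg <- BarcodeConfig(fixedBarcode = "CTGA",
#'                      adapter = "AGATCGGAAGAGCACACGTCTGGATCCACGACG")
#' @export
BarcodeConfig <- function(fixedBarcode, adapter, randomLen = 5L,
                          maxFixedMismatch = 1L, minLenAfterClip = 1L,
                          minAdapterOverlap = 3L) {
  if (missing(fixedBarcode))
    stop("fixedBarcode must be supplied; it is protocol-specific and has ",
         "no default")
  if (missing(adapter))
    stop("adapter must be supplied")
  new("BarcodeConfig",
      randomLen = as.integer(randomLen),
      fixedBarcode = toupper(as.character(fixedBarcode)),
      maxFixedMismatch = as.integer(maxFixedMismatch),
      adapter = toupper(as.character(adapter)),
      minLenAfterClip = as.integer(minLenAfterClip),
      minAdapterOverlap = as.integer(minAdapterOverlap),
      idTagPrefix = "TL:")
}

setMethod("show", "BarcodeConfig", function(object) {
  cat("BarcodeConfig\n")
  cat("  random barcode:", object@randomLen, "nt\n")
  cat("  fixed barcode :", object@fixedBarcode,
      sprintf("(<= %d mismatch)\n", object@maxFixedMismatch))
  cat("  adapter       :", object@adapter, "\n")
})

.hamming <- function(a, b) {
  # N never matches: conservative for the fixed-barcode check
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(av != bv)
}

#' Extract the random barcode of a raw ChIP-nexus read
#'
#' The first `randomLen` bases are the random barcode and the following
#' `nchar(fixedBarcode)` bases the fixed barcode. If the observed fixed
#' barcode is within `maxFixedMismatch` of the expected one, both prefixes
#' are removed (from sequence and qualities alike) and `TL:<barcode>` is
#' appended to the read ID after a single space; otherwise the read is
#' rejected.
#'
#' @param read List with elements `id`, `seq`, `qual` (equal-length
#'   sequence and quality strings).
#' @param cfg A [BarcodeConfig-class].
#' @return On acceptance, `list(status = "ok", read = <trimmed read>)`;
#'   on rejection, `list(status = <reason>)` with reason one of
#'   `"too_short"`, `"bad_sequence"`, `"fixed_barcode"`.
#' @examples
#' cfg <- BarcodeConfig("CTGA", "AGATCGGAAGAGC")
#' r <- list(id = "READ1", seq = "ATGCCCTGAACGTACGT",
#'           qual = "IIIIIIIIIIIIIIIII")
#' parseBarcode(r, cfg)
#' @export
parseBarcode <- function(read, cfg) {
  stopifnot(is(cfg, "BarcodeConfig"))
  seq <- toupper(read$seq)
  fixedLen <- nchar(cfg@fixedBarcode)
  need <- cfg@randomLen + fixedLen + cfg@minLenAfterClip
  if (nchar(seq) < need)
    return(list(status = "too_short"))
  if (grepl("[^ACGTN]", seq))
    return(list(status = "bad_sequence"))
  barcode <- substr(seq, 1L, cfg@randomLen)
  observedFixed <- substr(seq, cfg@randomLen + 1L, cfg@randomLen + fixedLen)
  if (.hamming(observedFixed, cfg@fixedBarcode) > cfg@maxFixedMismatch)
    return(list(status = "fixed_barcode"))
  drop <- cfg@randomLen + fixedLen
  list(status = "ok",
       read = list(
         id = paste(read$id, paste0(cfg@idTagPrefix, barcode)),
         seq = substr(seq, drop + 1L, nchar(seq)),
         qual = substr(read$qual, drop + 1L, nchar(read$qual))))
}

.adapter_clip_at <- function(seq, adapter, minOverlap) {
  # leftmost i such that seq[i..n] equals adapter[1..(n-i+1)] with
  # overlap >= minOverlap; 0 when no qualifying match
  n <- nchar(seq)
  for (i in seq_len(n - minOverlap + 1L)) {
    ov <- n - i + 1L
    if (substr(seq, i, n) == substr(adapter, 1L, ov))
      return(i)
  }
  0L
}

#' Clip the 3' adapter from a barcode-trimmed read
#'
#' Exonuclease digestion leaves many inserts shorter than the read length,
#' so reads commonly run into the adapter. The leftmost exact match of an
#' adapter prefix as a read suffix (minimum overlap
#' `cfg@minAdapterOverlap`) is removed together with everything 3' of it.
#' Reads that begin with adapter, or whose clipped length falls below
#' `minLenAfterClip`, are rejected.
#'
#' @param read List with `id`, `seq`, `qual` (after [parseBarcode()]).
#' @param cfg A [BarcodeConfig-class].
#' @return `list(status = "ok", read = ...)` or `list(status = reason)`
#'   with reason `"all_adapter"` or `"too_short"`.
#' @export
clipAdapter <- function(read, cfg) {
  stopifnot(is(cfg, "BarcodeConfig"))
  seq <- toupper(read$seq)
  i <- .adapter_clip_at(seq, cfg@adapter, cfg@minAdapterOverlap)
  if (i == 0L)
    return(list(status = "ok", read = read))
  if (i == 1L)
    return(list(status = "all_adapter"))
  if (i - 1L < cfg@minLenAfterClip)
    return(list(status = "too_short"))
  list(status = "ok",
       read = list(id = read$id,
                   seq = substr(read$seq, 1L, i - 1L),
                   qual = substr(read$qual, 1L, i - 1L)))
}

#' Preprocess a raw ChIP-nexus FASTQ file
#'
#' Applies [parseBarcode()] then [clipAdapter()] to every read, streams
#' surviving reads (in input order) to `fastqOut`, and returns per-reason
#' counts. Input and output may be gzipped (by extension).
#'
#' @param fastqIn Input FASTQ path (plain or `.gz`).
#' @param fastqOut Output FASTQ path (plain or `.gz`).
#' @param cfg A [BarcodeConfig-class].
#' @return Named list of counts: `nInput`, `nDiscardedFixedBarcode`,
#'   `nDiscardedAllAdapter`, `nDiscardedTooShort`,
#'   `nDiscardedBadSequence`, `nOutput`. Conservation
#'   `nInput = nOutput + sum(discards)` always holds.
#' @examples
#' \dontrun{
#' cfg <- BarcodeConfig("CTGA", "AGATCGGAAGAGC")
#' stats <- preprocessFastq("raw.fastq.gz", "clean.fastq.gz", cfg)
#' }
#' @export
preprocessFastq <- function(fastqIn, fastqOut, cfg) {
  stopifnot(is(cfg, "BarcodeConfig"))
  reads <- Biostrings::readDNAStringSet(fastqIn, format = "fastq",
                                        with.qualities = TRUE)
  n <- length(reads)
  ids <- names(reads)
  seqs <- as.character(reads)
  quals <- as.character(mcols(reads)$qualities)

  counts <- c(fixed_barcode = 0L, all_adapter = 0L, too_short = 0L,
              bad_sequence = 0L)
  keep <- logical(n)
  outId <- character(n); outSeq <- character(n); outQual <- character(n)
  for (k in seq_len(n)) {
    r <- list(id = ids[k], seq = seqs[k], qual = quals[k])
    p <- parseBarcode(r, cfg)
    if (p$status != "ok") {
      counts[p$status] <- counts[p$status] + 1L
      next
    }
    cl <- clipAdapter(p$read, cfg)
    if (cl$status != "ok") {
      counts[cl$status] <- counts[cl$status] + 1L
      next
    }
    keep[k] <- TRUE
    outId[k] <- cl$read$id
    outSeq[k] <- cl$read$seq
    outQual[k] <- cl$read$qual
  }
  out <- Biostrings::DNAStringSet(outSeq[keep])
  names(out) <- outId[keep]
  Biostrings::writeXStringSet(
    out, fastqOut, format = "fastq",
    qualities = Biostrings::BStringSet(outQual[keep]),
    compress = grepl("\\.gz$", fastqOut))
  stats <- list(nInput = n,
                nDiscardedFixedBarcode = unname(counts["fixed_barcode"]),
                nDiscardedAllAdapter = unname(counts["all_adapter"]),
                nDiscardedTooShort = unname(counts["too_short"]),
                nDiscardedBadSequence = unname(counts["bad_sequence"]),
                nOutput = sum(keep))
  stopifnot(stats$nInput == stats$nOutput + sum(unlist(counts)))
  stats
}

#' Write preprocessing statistics as TSV
#'
#' @param stats Return value of [preprocessFastq()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writePreprocessStats <- function(stats, path) {
  df <- data.frame(metric = names(stats),
                   count = unlist(stats, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
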