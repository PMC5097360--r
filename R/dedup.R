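#' @include AllClasses.R HitSet-methods.R
NULL

.dedup_key <- function(gr, withBarcode = TRUE) {
  base <- paste(as.character(seqnames(gr)), BiocGenerics::start(gr),
                as.character(BiocGenerics::strand(gr)), sep = "\r")
  if (withBarcode) paste(base, mcols(gr)$barcode, sep = "\r") else base
}

#' Selective PCR-duplicate removal using random barcodes
#'
#' Reads whose 5' terminus maps to the same genomic position and strand
#' *and* that carry an identical random barcode are presumed PCR
#' duplicates; exactly one read is retained per (chrom, pos, strand,
#' barcode). Since only the 5' end is used downstream it does not matter
#' which read of a duplicate set is kept; the first in coordinate-sorted
#' order is retained for reproducible output.
#'
#' The retained multiset is the IMUB read set. Reads at the same position
#' with *different* barcodes are independent molecules digested to the
#' same exonuclease stop and are all kept — this is what distinguishes
#' ChIP-nexus deduplication from naive positional deduplication.
#'
#' @param x A [HitSet-class] whose hits carry barcodes.
#' @param onMissingBarcode What to do with `NA` barcodes: `"abort"`
#'   (default) or `"distinct"` (treat each as unique, with a warning).
#' @return `list(hits = <retained HitSet>, nRemoved = <integer>)`.
#' @examples
#' hs <- HitSet(chrom = rep("chr1", 3), pos = rep(100L, 3),
#'              strand = rep("f", 3), barcode = c("AA", "AA", "AB"),
#'              seqlengths = c(chr1 = 1000L))
#' deduplicateHits(hs)$nRemoved  # 1
#' @export
deduplicateHits <- function(x, onMissingBarcode = c("abort", "distinct")) {
  stopifnot(is(x, "HitSet"))
  onMissingBarcode <- match.arg(onMissingBarcode)
  gr <- x@hits
  if (!length(gr))
    return(list(hits = x, nRemoved = 0L))
  missing <- is.na(mcols(gr)$barcode)
  if (any(missing)) {
    if (onMissingBarcode == "abort")
      stop(sum(missing), " hit(s) lack a random barcode; rerun with ",
           "onMissingBarcode = \"distinct\" to keep them all")
    warning(sum(missing), " hit(s) without barcode treated as distinct ",
            "molecules")
  }
  ord <- order(as.integer(seqnames(gr)), BiocGenerics::start(gr),
               as.character(BiocGenerics::strand(gr)),
               method = "radix")
  gr <- gr[ord]
  key <- .dedup_key(gr)
  keep <- !duplicated(key) | is.na(mcols(gr)$barcode)
  out <- .hitset_from_granges(gr[keep], x@readLength)
  list(hits = out, nRemoved = sum(!keep))
}

#' Duplication-level profile with respect to random barcodes
#'
#' Classifies all mapped reads (pre-deduplication) into the three classes:
#' identically mapped (IM: same chrom, 5' position and strand), IM with
#' identical barcode (IMIB), and IM with unique barcode (IMUB: the
#' retained one-per-barcode representatives). Each read's duplication
#' level is the size of its group under the respective definition:
#' \itemize{
#'   \item IM level of a read = number of reads at its (pos, strand);
#'   \item IMIB level of a read = number of reads sharing its (pos,
#'     strand, barcode);
#'   \item IMUB level of a retained read = number of distinct barcodes at
#'     its (pos, strand), i.e. its post-deduplication 5'-end depth.
#' }
#' Per-class level histograms are normalised to proportions of that
#' class's reads, and the overall duplication level of a class is the
#' proportion of its reads at level two or more.
#'
#' @param x A [HitSet-class] with barcodes (all mapped reads, pre-dedup).
#' @param levelCap Histogram ceiling: levels `>= levelCap` are aggregated
#'   into one open-ended bin (default 10).
#' @return A [DuplicationProfile-class].
#' @examples
#' hs <- HitSet(chrom = rep("chr1", 4), pos = c(100L, 100L, 100L, 200L),
#'              strand = rep("f", 4), barcode = c("AA", "AA", "AB", "CC"),
#'              seqlengths = c(chr1 = 1000L))
#' overallLevels(duplicationProfile(hs))  # IM 0.75, IMIB 0.50, IMUB 2/3
#' @export
duplicationProfile <- function(x, levelCap = 10L) {
  stopifnot(is(x, "HitSet"), levelCap >= 2L)
  gr <- x@hits
  if (!length(gr)) {
    lv <- data.frame(class = character(), level = integer(),
                     nReads = integer(), proportion = numeric())
    return(new("DuplicationProfile", levels = lv,
               overall = c(IM = 0, IMIB = 0, IMUB = 0),
               nReads = c(IM = 0L, IMIB = 0L, IMUB = 0L),
               levelCap = as.integer(levelCap), empty = TRUE))
  }
  if (anyNA(mcols(gr)$barcode))
    stop("duplication profiling requires a barcode on every read")
  posKey <- .dedup_key(gr, withBarcode = FALSE)
  bcKey <- .dedup_key(gr, withBarcode = TRUE)

  imLevel <- as.integer(ave(seq_along(posKey), posKey, FUN = length))
  imibLevel <- as.integer(ave(seq_along(bcKey), bcKey, FUN = length))
  # distinct barcodes per position group, looked up per read
  firstOfBarcode <- !duplicated(bcKey)
  imubDepth <- tapply(firstOfBarcode, posKey, sum)
  imubPerRead <- as.integer(imubDepth[posKey])
  # IMUB class = retained reads only
  imubLevel <- imubPerRead[firstOfBarcode]

  levels <- list(IM = imLevel, IMIB = imibLevel, IMUB = imubLevel)
  lvTab <- do.call(rbind, lapply(names(levels), function(cl) {
    lv <- pmin(levels[[cl]], levelCap)
    tab <- table(factor(lv, levels = seq_len(levelCap)))
    data.frame(class = cl, level = seq_len(levelCap),
               nReads = as.integer(tab),
               proportion = as.integer(tab) / length(lv))
  }))
  lvTab <- lvTab[lvTab$nReads > 0L, , drop = FALSE]
  rownames(lvTab) <- NULL
  overall <- vapply(levels, function(lv) mean(lv >= 2L), numeric(1))
  new("DuplicationProfile", levels = lvTab, overall = overall,
      nReads = vapply(levels, length, integer(1)),
      levelCap = as.integer(levelCap), empty = FALSE)
}

#' @rdname levelTable
#' @export
setMethod("levelTable", "DuplicationProfile", function(x) x@levels)

#' @rdname overallLevels
#' @export
setMethod("overallLevels", "DuplicationProfile", function(x) x@overall)

setMethod("show", "DuplicationProfile", function(object) {
  cat("DuplicationProfile\n")
  if (object@empty) {
    cat("  (no reads)\n")
    return(invisible(NULL))
  }
  ov <- object@overall
  cat(sprintf("  overall duplication levels: IM %.1f%%  IMIB %.1f%%  IMUB %.1f%%\n",
              100 * ov["IM"], 100 * ov["IMIB"], 100 * ov["IMUB"]))
  cat("  reads: IM", object@nReads["IM"], " IMUB",
      object@nReads["IMUB"], "\n")
})

#' Duplication-level plot
#'
#' One curve per read class (IM, IMIB, IMUB) of the proportion of reads at
#' each duplication level; the final bin is open-ended. Overall
#' duplication levels are annotated in the legend.
#'
#' @param profile A [DuplicationProfile-class].
#' @return A `ggplot` object.
#' @export
duplicationPlot <- function(profile) {
  stopifnot(is(profile, "DuplicationProfile"))
  if (profile@empty) stop("cannot plot an empty profile")
  df <- profile@levels
  cap <- profile@levelCap
  df$levelBin <- factor(ifelse(df$level >= cap,
                               paste0(cap, "+"), df$level),
                        levels = c(seq_len(cap - 1L), paste0(cap, "+")))
  ov <- profile@overall
  labs <- sprintf("%s (overall %.0f%%)", names(ov), 100 * ov)
  df$class <- factor(df$class, levels = names(ov), labels = labs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$levelBin,
                                   y = .data$proportion,
                                   colour = .data$class,
                                   group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = stats::setNames(c("red3", "blue3", "black"), labs)) +
    ggplot2::labs(x = "duplication level", y = "proportion of reads",
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Write a duplication profile as TSV
#'
#' Emits the plot data (class, level, nReads, proportion) plus overall
#' levels as comment header lines, for regression testing and records.
#'
#' @param profile A [DuplicationProfile-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeDuplicationProfile <- function(profile, path) {
  stopifnot(is(profile, "DuplicationProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  ov <- profile@overall
  writeLines(sprintf("#overall\t%s\t%.10g", names(ov), ov), con)
  writeLines("class\tlevel\tnReads\tproportion", con)
  utils::write.table(profile@levels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
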