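#' @include AllClasses.R HitSet-methods.R
NULL

#' Construct simulator study conditions
#'
#' Defaults describe a desk-scale experiment with the statistical
#' structure of a strongly enriched transcription-factor ChIP-nexus
#' library: one 1-Mb chromosome, 200 sites with an 18-bp protected region
#' (a typical factor footprint), 50 molecules per site with 1-bp 5'-end
#' jitter, a mean of one PCR copy per molecule, sparse uniform background,
#' 42-bp reads and a 5-nt random barcode.
#'
#' @param seed Integer RNG seed (required; all randomness derives from it).
#' @param genome Named integer vector of chromosome lengths.
#' @param nSites Number of planted binding sites (default 200).
#' @param protectedWidth Planted protected-region width in bp (default 18).
#' @param jitterSd SD of the per-molecule 5'-end jitter in bp (default 1).
#' @param moleculesPerSite Independent molecules per site, split between
#'   strands (default 50).
#' @param pcrDuplicationMean Poisson mean of extra PCR copies per molecule
#'   (default 1).
#' @param backgroundRate Background hits per bp, both strands combined
#'   (default 0.001).
#' @param readLength Read length in bp (default 42).
#' @param fragmentLength Pre-digestion fragment length, cosmetic
#'   (default 150).
#' @param barcodeLen Random-barcode length in nt (default 5).
#' @param fixedBarcode Fixed barcode written into raw reads
#'   (default "CTGA").
#' @param adapter Adapter appended to inserts shorter than the read
#'   length.
#' @param nPhantomLoci Number of repeat-driven artifact clusters whose
#'   forward/reverse 5' ends are exactly `readLength - 1` apart
#'   (default 0).
#' @param moleculesPerPhantom Molecules per phantom locus (default 50).
#' @return A [SimConfig-class].
#' @export
SimConfig <- function(seed,
                      genome = c(chrS1 = 1000000L),
                      nSites = 200L,
                      protectedWidth = 18L,
                      jitterSd = 1,
                      moleculesPerSite = 50L,
                      pcrDuplicationMean = 1,
                      backgroundRate = 0.001,
                      readLength = 42L,
                      fragmentLength = 150L,
                      barcodeLen = 5L,
                      fixedBarcode = "CTGA",
                      adapter = "AGATCGGAAGAGCACACGTCTGGATCCACGACGCTCTTCC",
                      nPhantomLoci = 0L,
                      moleculesPerPhantom = 50L) {
  if (missing(seed)) stop("a seed is required")
  g <- as.integer(genome)
  names(g) <- names(genome)
  new("SimConfig", seed = as.integer(seed), genome = g,
      nSites = as.integer(nSites),
      protectedWidth = as.integer(protectedWidth),
      jitterSd = as.numeric(jitterSd),
      moleculesPerSite = as.integer(moleculesPerSite),
      pcrDuplicationMean = as.numeric(pcrDuplicationMean),
      backgroundRate = as.numeric(backgroundRate),
      readLength = as.integer(readLength),
      fragmentLength = as.integer(fragmentLength),
      barcodeLen = as.integer(barcodeLen),
      fixedBarcode = toupper(fixedBarcode),
      adapter = toupper(adapter),
      nPhantomLoci = as.integer(nPhantomLoci),
      moleculesPerPhantom = as.integer(moleculesPerPhantom))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome:", paste(names(object@genome), object@genome,
                         sep = ":", collapse = ", "), "\n")
  cat("  sites:", object@nSites, "x", object@moleculesPerSite,
      "molecules, width", object@protectedWidth, "bp, jitter sd",
      object@jitterSd, "\n")
  cat("  background:", object@backgroundRate, "hits/bp; phantom loci:",
      object@nPhantomLoci, "\n")
})

.random_barcodes <- function(n, len) {
  if (!n) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# evaluate expr with a private, seed-determined RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# site placement: random draw from a coarse grid so neighbouring sites
# stay well separated (distinct free-standing summits)
.place_sites <- function(l, n, margin, minGap = 200L) {
  grid <- seq.int(as.integer(margin), as.integer(l - margin), by = minGap)
  if (length(grid) < n)
    stop("infeasible placement: chromosome too short for ", n, " sites")
  sort(sample(grid, n)) + sample.int(minGap %/% 2L, n, replace = TRUE)
}

#' Simulate a ground-truthed ChIP-nexus hit set
#'
#' Generates barcoded 5'-end hits with the structure the method assumes:
#' \itemize{
#'   \item per site, molecules split between strands with forward 5' ends
#'     at `s - ceiling(w/2) + jitter` and reverse 5' ends at
#'     `s + floor(w/2) + jitter` (rounded Gaussian jitter), so the
#'     planted forward/reverse 5' distance is the protected width `w`;
#'   \item each molecule carries a uniform random barcode and appears as
#'     `1 + Poisson(pcrDuplicationMean)` identical PCR copies;
#'   \item uniform background hits on both strands with fresh barcodes;
#'   \item optional phantom loci: paired forward/reverse clusters exactly
#'     `readLength - 1` apart with distinct barcodes, emulating
#'     repeat-driven mapping artifacts.
#' }
#' All randomness derives from `cfg@seed`; the caller's RNG state is
#' untouched.
#'
#' @param cfg A [SimConfig-class].
#' @return `list(hits = <HitSet with barcodes>, truth = <list>)` where
#'   `truth` has elements `sites` (data.frame chrom, pos,
#'   expectedSummit), `molecules` (one row per molecule: chrom, origin,
#'   strand, pos, barcode, copies) and `phantoms` (data.frame chrom,
#'   pos). `expectedSummit` is the rightmost forward 5' end of the
#'   site's molecules — the start of the site's maximal qfrag-coverage
#'   plateau and hence the position a leftmost-of-plateau summit caller
#'   should report; `NA` when a site lacks hits on either strand.
#' @examples
#' sim <- simulateHits(SimConfig(seed = 1L, nSites = 10L))
#' sim$hits
#' head(sim$truth$sites)
#' @export
simulateHits <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  .with_seed(cfg@seed, {
    w <- cfg@protectedWidth
    rl <- cfg@readLength
    margin <- as.integer(w + ceiling(4 * cfg@jitterSd) + rl + 10L)
    mol <- list(); sites <- list(); phantoms <- list()
    for (ch in names(cfg@genome)) {
      l <- cfg@genome[[ch]]
      if (cfg@nSites > 0L) {
        sitePos <- .place_sites(l, cfg@nSites, margin)
        nm <- cfg@moleculesPerSite
        for (i in seq_along(sitePos)) {
          s <- sitePos[i]
          strands <- rep(c("f", "r"), length.out = nm)
          jit <- as.integer(round(stats::rnorm(nm, 0, cfg@jitterSd)))
          pos <- as.integer(ifelse(strands == "f",
                                   s - ceiling(w / 2) + jit,
                                   s + floor(w / 2) + jit))
          mol[[length(mol) + 1L]] <- data.frame(
            chrom = ch, origin = paste0("site_", ch, "_", i),
            strand = strands, pos = pos,
            barcode = .random_barcodes(nm, cfg@barcodeLen),
            copies = 1L + stats::rpois(nm, cfg@pcrDuplicationMean))
        }
        sites[[length(sites) + 1L]] <- data.frame(chrom = ch,
                                                  pos = sitePos)
      }
      if (cfg@nPhantomLoci > 0L) {
        phPos <- .place_sites(l, cfg@nPhantomLoci, margin)
        nm <- cfg@moleculesPerPhantom
        for (i in seq_along(phPos)) {
          p <- phPos[i]
          strands <- rep(c("f", "r"), length.out = nm)
          # artifact geometry: no jitter, 5' ends exactly rl - 1 apart
          pos <- ifelse(strands == "f", p, p + rl - 1L)
          mol[[length(mol) + 1L]] <- data.frame(
            chrom = ch, origin = paste0("phantom_", ch, "_", i),
            strand = strands, pos = pos,
            barcode = .random_barcodes(nm, cfg@barcodeLen),
            copies = 1L + stats::rpois(nm, cfg@pcrDuplicationMean))
        }
        phantoms[[length(phantoms) + 1L]] <- data.frame(chrom = ch,
                                                        pos = phPos)
      }
      nBg <- stats::rpois(1L, cfg@backgroundRate * l)
      if (nBg > 0L) {
        mol[[length(mol) + 1L]] <- data.frame(
          chrom = ch, origin = "background",
          strand = sample(c("f", "r"), nBg, replace = TRUE),
          pos = sample.int(l, nBg, replace = TRUE),
          barcode = .random_barcodes(nBg, cfg@barcodeLen),
          copies = 1L)
      }
    }
    molecules <- if (length(mol)) do.call(rbind, mol) else
      data.frame(chrom = character(), origin = character(),
                 strand = character(), pos = integer(),
                 barcode = character(), copies = integer())
    # clamp rare jitter excursions into the chromosome
    if (nrow(molecules)) {
      lens <- cfg@genome[molecules$chrom]
      molecules$pos <- pmin(pmax(molecules$pos, 1L), lens)
    }
    sitesDf <- if (length(sites)) do.call(rbind, sites) else
      data.frame(chrom = character(), pos = integer())
    if (nrow(sitesDf)) {
      key <- paste0("site_", sitesDf$chrom, "_",
                    ave(seq_len(nrow(sitesDf)), sitesDf$chrom,
                        FUN = seq_along))
      fwd <- molecules[molecules$strand == "f", ]
      maxF <- tapply(fwd$pos, fwd$origin, max)
      rev <- molecules[molecules$strand == "r", ]
      hasR <- key %in% rev$origin
      sitesDf$expectedSummit <- ifelse(
        key %in% names(maxF) & hasR,
        as.integer(maxF[key]), NA_integer_)
    }
    phantomsDf <- if (length(phantoms)) do.call(rbind, phantoms) else
      data.frame(chrom = character(), pos = integer())
    rownames(molecules) <- rownames(sitesDf) <- rownames(phantomsDf) <- NULL

    idx <- rep(seq_len(nrow(molecules)), molecules$copies)
    hits <- HitSet(chrom = molecules$chrom[idx],
                   pos = molecules$pos[idx],
                   strand = molecules$strand[idx],
                   barcode = molecules$barcode[idx],
                   seqlengths = cfg@genome,
                   readLength = rl)
    list(hits = hits,
         truth = list(sites = sitesDf, molecules = molecules,
                      phantoms = phantomsDf))
  })
}

.read_id <- function(n) sprintf("sim%06d", seq_len(n))

#' Emit simulated raw reads as FASTQ (plus reference FASTA)
#'
#' Builds a deterministic random reference for the configured genome and
#' writes, for every hit, a raw read consisting of
#' `random barcode + fixed barcode + insert (+ adapter fill)`. The insert
#' is read from the reference starting at the molecule's 5' end (reverse
#' complement for reverse-strand molecules) and has the length of the
#' protected region; inserts shorter than the read length are padded with
#' adapter sequence, so adapter clipping restores the insert. Qualities
#' are constant "I". The reference FASTA is wrapped at 60 columns.
#'
#' @param sim Return value of [simulateHits()].
#' @param cfg The [SimConfig-class] used to generate `sim`.
#' @param dir Output directory (created if needed).
#' @return Named list with paths `fastq`, `fasta`, and the per-read
#'   `barcodes` in emitted order.
#' @export
emitFastq <- function(sim, cfg, dir) {
  stopifnot(is(cfg, "SimConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # reference generation draws from its own seed so that hit simulation
  # and sequence emission stay independently reproducible
  ref <- .with_seed(cfg@seed + 1L, {
    seqs <- lapply(cfg@genome, function(l)
      paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
             collapse = ""))
    Biostrings::DNAStringSet(unlist(seqs))
  })
  names(ref) <- names(cfg@genome)
  fastaPath <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref, fastaPath, width = 60L)

  gr <- hitGRanges(sim$hits)
  n <- length(gr)
  insertLen <- min(cfg@protectedWidth, cfg@readLength)
  chrom <- as.character(seqnames(gr))
  pos <- BiocGenerics::start(gr)
  fwd <- as.character(BiocGenerics::strand(gr)) == "+"
  lens <- chromLengths(sim$hits)[chrom]
  startRef <- ifelse(fwd, pos, pmax(1L, pos - insertLen + 1L))
  endRef <- ifelse(fwd, pmin(lens, pos + insertLen - 1L), pos)
  inserts <- character(n)
  if (n) {
    refStr <- as.character(ref)  # one string per chromosome
    v <- Biostrings::DNAStringSet(
      substring(refStr[chrom], startRef, endRef))
    v[!fwd] <- Biostrings::reverseComplement(v[!fwd])
    inserts <- as.character(v)
  }
  barcodes <- mcols(gr)$barcode
  raw <- paste0(barcodes, cfg@fixedBarcode, inserts)
  fill <- cfg@readLength + cfg@barcodeLen + nchar(cfg@fixedBarcode) -
    nchar(raw)
  pad <- substr(strrep(cfg@adapter, 2L), 1L, pmax(0L, fill))
  raw <- paste0(raw, substr(pad, 1L, pmax(0L, fill)))
  reads <- Biostrings::DNAStringSet(raw)
  names(reads) <- .read_id(n)
  fastqPath <- file.path(dir, "reads.fastq")
  Biostrings::writeXStringSet(
    reads, fastqPath, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(raw))))
  list(fastq = fastqPath, fasta = fastaPath, barcodes = barcodes)
}
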