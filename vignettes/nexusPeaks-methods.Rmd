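---
title: "Methods: barcode-aware duplicate removal, protected-region width estimation and qfrag peak calling"
author: "nexusPeaks"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(nexusPeaks)
  library(GenomicRanges)
})
```

## The data model

ChIP-nexus (and its predecessor ChIP-exo) maps protein-DNA binding at
nucleotide resolution: a 5'-3' lambda exonuclease digests
immunoprecipitated fragments up to the cross-link, so the 5' ends of
mapped reads pile up at the two borders of the *protected region* — the
stretch of DNA shielded by the cross-linked protein. Everything in this
package reduces a mapped read to a *hit*: its 5'-end position and strand,

$$T = \{\, h = (\mathrm{pos}, \mathrm{strand}) \mid \mathrm{pos} \in \{1,\dots,l\},\ \mathrm{strand} \in \{f, r\} \,\},$$

held per chromosome of length $l$ in a `HitSet` (a width-1 `GRanges`
with one row per read, so identically mapped reads keep their
multiplicity, plus the modal read length $rl$). Coordinates are 1-based
and closed throughout; only the BED/narrowPeak writers convert to
0-based half-open.

ChIP-nexus reads begin with a random barcode (a UMI) followed by a fixed
barcode. Because independent molecules can be digested to the same stop
position, positional deduplication would destroy real signal; the random
barcode lets PCR duplicates — same 5' terminus, same strand *and* same
barcode — be removed selectively.

## Preprocessing

`preprocessFastq()` applies two deterministic steps per read:

1. **Barcode extraction** (`parseBarcode()`): the first `randomLen`
   bases (default 5 nt) are the random barcode; the next
   `nchar(fixedBarcode)` bases are compared to the expected fixed
   barcode by Hamming distance. Reads with more than one mismatching
   nucleotide are discarded. The barcode is appended to the read ID as
   `TL:<barcode>` so that it travels through alignment into the BAM
   query name. There is no universal random-barcode length or fixed
   barcode — they are wet-lab protocol constants — so `fixedBarcode`
   must always be supplied and `randomLen` defaults to the common
   5-nt design. An `N` in the random barcode is carried verbatim; an
   `N` in the fixed barcode counts as a mismatch (conservative).
2. **Adapter clipping** (`clipAdapter()`): exonuclease digestion leaves
   many inserts shorter than the read, so reads run into the adapter.
   We clip at the leftmost exact match of an adapter *prefix* as a read
   *suffix*, requiring a minimum overlap (default 3 nt). Exact-overlap
   clipping was chosen over mismatch-tolerant alignment because it is
   deterministic and directly checkable against a brute-force oracle;
   mismatch-tolerant clipping is a non-goal. Reads consisting entirely
   of adapter, or clipped below `minLenAfterClip`, are discarded.
   Quality trimming is deliberately not performed.

Conservation (`input = output + discards`) is asserted on every run,
and qualities are always sliced identically to the sequence.

## Deduplication and duplication levels

`deduplicateHits()` keeps exactly one read per
(chromosome, position, strand, barcode); since only 5' ends are used
downstream, which member of a duplicate set survives is irrelevant, and
the first in coordinate-sorted order is kept so output bytes are
reproducible. Strands are never merged: the 5' terminus of a forward
and a reverse read at the same coordinate are different molecules ends.

`duplicationProfile()` reports three read classes:

* **IM** — identically mapped reads (same position and strand); a
  read's level is the size of its position group.
* **IMIB** — IM reads with identical barcode (presumed PCR
  duplicates); a read's level is its barcode subgroup size.
* **IMUB** — the retained one-per-barcode reads; a retained read's
  level is the number of distinct barcodes at its position, i.e. its
  post-deduplication 5'-end depth. We weight levels by reads (not by
  positions); the per-class *overall duplication level* is the
  proportion of reads with depth greater than one.

High IM with low IMUB indicates genuine exonuclease pile-ups rather
than overamplification, which is exactly the situation the random
barcode was designed to disambiguate.

## Protected-region width: qfrag signature with pseudo-control

A *qfrag* is the interval between an ordered pair of hits $(h_i, h_j)$
with $h_i \in T_f$, $h_j \in T_r$. The qfrag-length distribution counts
pairs at each distance $\delta = 2, \dots, \Delta$:

$$Q_t(\delta) = |\{ (h_i, h_j) \mid h_i \in T_f,\ h_j \in T_r,\ h_j - h_i = \delta \}|.$$

$\Delta$ defaults to 110 bp, comfortably above any plausible
single-factor footprint (6–20 bp) while keeping the signature cheap.
Pair counting respects read multiplicity and is summed over
chromosomes; by construction the genome-wide signature is additive over
chromosomes, a property the tests exercise.

The raw distribution is contaminated by the *phantom peak*: repetitive
loci produce matched forward/reverse pile-ups whose 5' ends sit exactly
one read length apart, creating a spurious maximum at $\delta = rl - 1$
(the same artifact that biases cross-correlation fragment-length
estimators). The correction builds a **pseudo-control**: each hit's
strand is swapped and its position shifted one read length towards the
new 5' direction,

$$h'.\mathrm{pos} = \begin{cases} h.\mathrm{pos} + rl - 1 & h'.\mathrm{strand} = r \\ h.\mathrm{pos} - rl + 1 & h'.\mathrm{strand} = f. \end{cases}$$

This transform is an involution, and it maps a data pair at distance
$\delta$ to a control pair at distance $2(rl-1) - \delta$ — so the
control distribution is the data distribution reflected about
$\delta = rl - 1$. Phantom configurations sit at the fixed point of the
reflection and are preserved exactly, while genuine sub-read-length
footprints are moved away; the difference
$D(\delta) = Q_t(\delta) - Q_p(\delta)$ therefore cancels the artifact,
and the width estimate is

$$\ell''' = \arg\max_\delta\, D(\delta).$$

Numerical choices: ties take the smallest $\delta$ (deterministic,
biased towards the sharper footprint); a constant signature (e.g. pure
phantom data, where $D \equiv 0$) degenerates to $\delta = 2$ and is
flagged; hits whose control position leaves the chromosome are dropped
and counted, not reflected — at genome scale the loss is negligible.
$rl$ is the modal mapped read length, overridable. Chromosome filtering
before the signature is available but off by default.

## Peak calling

With $x$ the allowed deviation (default 5 bp), qfrags are formed for
lengths in $[q_{\min}, q_{\max}] = [\ell''' - x,\ \ell''' + x]$, each
covering the closed interval from its forward to its reverse 5' end
(closed on both sides so the idealized single-site profile is
symmetric). The depth profile is assembled by weighted interval
coverage. *Summits* are free-standing local maxima: positions whose
depth is not exceeded within a radius of $q_{\min}$; a plateau yields
its leftmost position (the paper-level definition is silent on
plateaus; leftmost is deterministic and simple).

Every summit in a covered region is tested. For summit $s_i$, $k$ is
the number of 5' ends of both strands within
$[s_i - q_{\max}, s_i + q_{\max}]$, compared against a uniform-null
Poisson rate computed per chromosome:

$$\lambda = 2\, q_{\max} \frac{|T_f| + |T_r|}{l}, \qquad
  P(X \ge k) = 1 - \sum_{i=0}^{k-1} \mathrm{Pois}(i, \lambda).$$

The $2 q_{\max}$ factor and the $(2 q_{\max} + 1)$-position counting
window are kept exactly as printed in the method's definition, and the
upper tail is evaluated with the Poisson survival function rather than
by subtraction from one. p-values are Benjamini–Hochberg corrected
genome-wide, the list is sorted by p (ties: larger $k$, then
coordinate), truncated to `topN` (default 200000), and written as
summit BED, narrowPeak (summits extended by 2 bp on each side) and a
full TSV. A genome-pooled $\lambda$ is available behind `poolLambda`.
For ChIP-exo the identical caller is used; only the upstream
deduplication is skipped (the CLI's `--exo-mode`).

Note $k$ and qfrag depth are different quantities: a summit's $k$ may
legitimately be smaller or larger than its depth, and no control/input
library is used — the null is uniform by design.

## The simulator: what it emulates, and what it does not

`simulateHits()` generates the structure the estimators assume, with
every distributional choice exposed in `SimConfig`:

* **Sites**: placed on a 200-bp grid with random offsets so
  neighbouring sites stay well separated (distinct free-standing
  summits). Per site, molecules are split evenly between strands;
  forward 5' ends sit at $s - \lceil w/2 \rceil$ and reverse ends at
  $s + \lfloor w/2 \rfloor$ plus rounded-Gaussian jitter
  (`jitterSd`, default 1 bp), making the planted forward/reverse
  distance exactly the protected width $w$. Each sequenced read is one
  molecule's barcoded end — single-end sequencing reads one end per
  molecule — so each simulated molecule carries one strand.
* **PCR duplication**: each molecule appears as
  $1 + \mathrm{Poisson}(\mu)$ identical copies ($\mu$ default 1,
  giving overall IM duplication levels in the range reported for real
  libraries).
* **Background**: uniform on both strands. The default rate
  (0.001 hits/bp) reflects the sparse background of a strongly
  enriched library relative to its sites; for background-only null
  experiments a realistic whole-library density of about 0.05 hits/bp
  (a few million uniquely mapped reads on a ~10^8 bp genome) is the
  appropriate setting.
* **Phantom loci**: matched forward/reverse clusters exactly
  $rl - 1$ apart with distinct barcodes and no jitter — the repeat
  artifact in its pure form.

Ground truth records every molecule and, per site, the *expected
summit*: under the leftmost-of-plateau rule the maximal qfrag-coverage
plateau of an isolated site starts at the rightmost forward 5' end, a
closed form that recall can be measured against without running the
caller. Defaults (200 sites × 50 molecules on 1 Mb, $w = 18$,
$rl = 42$) keep every test and the acceptance script fast while leaving
thousands of reads per condition.

`emitFastq()` additionally writes a deterministic random reference and
raw reads (`barcode + fixed barcode + insert + adapter fill`), so the
FASTQ preprocessing round-trips against known barcodes. What the
simulator does **not** model: sequencing errors, indels, base-quality
variation, mappability, GC bias, or motif-driven binding-energy
heterogeneity. Passing tests therefore demonstrate algorithmic
correctness on the assumed data structure, not robustness to every
artifact of real libraries.

## Problem sizes and verification

The test suite verifies the qfrag statistics against $O(n^2)$
brute-force pair enumeration on a hundred random hit sets (up to 1000
hits each), the pseudo-control algebra (involution and reflection
identity) exactly, planted-width recovery within ±1 bp for
$w \in \{10, 14, 18\}$, site recall and background false-positive
control at BH $q < 0.01$, and byte-determinism of the full pipeline
under a fixed seed. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

## Known limitations

* Barcode errors are not corrected (no within-Hamming-1 merging), so
  sequencing errors in the UMI slightly understate the duplication
  level; barcode collisions slightly overstate it (the expected
  collision count is computable from the barcode length and is covered
  by a test).
* The uniform Poisson null ignores chromatin accessibility structure;
  at very low library densities the restriction of testing to
  qfrag-covered positions makes the test anti-conservative.
* Single-end data only; multi-mappers are expected to be removed by
  the aligner (`-m 1`-style settings), and only an optional MAPQ floor
  is provided.
* The order load → deduplicate → filter/estimate is fixed; both hooks
  are exposed if a different order is wanted.
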