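---
title: "Detecting small RNA biogenesis signatures with sRNAsieve"
author: "sRNAsieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small RNA biogenesis signatures with sRNAsieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When an animal ingests RNA — synthetic double-stranded RNA, short hairpins,
or dietary plant transcripts — some of it may enter RNA interference
pathways and become *trans*-acting small RNA, while most of it is simply
degraded. In organisms without validated antibodies or genetic tools, the
only accessible evidence is the small RNA sequencing library itself: because
library construction ligates adapters directly to RNA ends, the precise 5'
and 3' termini created by RNases such as Dicer are preserved, and strand is
preserved too. Biogenesis can therefore be read off the alignments:

* **Dicer products** (siRNAs, ~19–23 nt) arise from staggered RNase III
  cleavage of double-stranded RNA, leaving duplexes whose strands carry
  2-nt 3' overhangs. On a genome this appears as opposite-strand read pairs
  whose genomic overlap is 2 nt less than the read length.
* **piRNAs** (~25–30 nt) are amplified by the ping-pong cycle: a
  Piwi-loaded RNA directs cleavage of a complementary transcript 10 nt from
  its own 5' end. This produces opposite-strand pairs whose 5' ends overlap
  by exactly 10 nt, a 5'-uridine bias on primary piRNAs, and an adenine at
  position 10 of secondaries.
* **Degradation fragments** are short (mostly < 20 nt), strand-uninformed
  only insofar as the source was single-stranded, and carry no pairing
  structure beyond chance.

sRNAsieve implements the detectors for these signatures, the supporting
pipeline (adapter trimming, depth normalisation, perfect-match
all-placements alignment, locus calling, strand-resolved coverage, class
accounting), and a generative simulator with per-read ground truth so that
every statistic is testable by parameter recovery.

## The core statistic: the Dicer overlap-pair matrix

For alignments on a common reference, every ordered pair of opposite-strand
alignments on the same contig is examined. With query length $q$, partner
interval overlap $v$, and overhang $h$ (default 2 nt), a pair is counted
when

$$ v = q - h. $$

Counts are accumulated in a matrix indexed by (query length, partner
length). The criterion is relative to the *query* length, so the matrix is
asymmetric for duplexes whose strands differ by one or two bases. Two
derived quantities summarise a library:

* `dicerReadFraction()` — the fraction of distinct mapped reads
  participating in at least one counted pair (as query or partner);
* `dicerEnrichment()` — that fraction in a condition of interest divided by
  the fraction in a total-RNA reference.

**The two registers.** The overlap-length rule alone admits two geometric
registers: the true duplex register (partner 5' end $h$ nt inside the query
3' end) and a mirror register (partner 3' end $h$ nt inside the query 5'
end). The published analyses state only the overlap-length criterion, so
`mode = "literal"` is the default; `mode = "canonical"` additionally
requires the true-duplex register for users who want the stricter
definition. Both modes are covered by the quadratic-scan oracle tests.

## Ping-pong statistics

`fivePrimeOverlapHist()` counts, for each (+,−) pair on a contig, the 5'-5'
overlap $o$ defined inclusively: $o = 10$ means the ends share positions
$p..p+9$ (the standard ping-pong convention; the arithmetic is
$o = \mathrm{5'}_{-} - \mathrm{5'}_{+} + 1$ with 1-based coordinates). The
z-score at each offset is the count minus the mean of all *other* offsets,
over their standard deviation; a ping-pong signal is an argmax at 10 with
$z(10) > 3$. `nucleotideBias()` builds the position frequency matrix on
read-sense sequence (reverse complement of the genomic slice for
minus-strand alignments); reads shorter than a position contribute only to
positions they cover, with per-position denominators tracked.

## Alignment semantics

`mapPerfect()` reproduces `bowtie -a -v0 -m N`: all exact full-length
placements on both strands are reported, and a read with more than
`maxPlacements` (default 200) placements is discarded *entirely* — the cap
is what removes extremely low-complexity reads, and co-mapping statistics
depend on discard-not-truncate semantics. A k-mer seed table (k = 12) with
full-length verification makes k a speed knob only; equivalence with a
naive full-scan string search is a property test. `hierarchicalMap()` maps
to genome A, re-maps A-mapped reads to genome B with identical settings,
and reports co-mapping versus exclusive fractions.

## Loci, coverage, classes

`callLoci()` pools both strands into per-base coverage, keeps maximal runs
with depth ≥ 2, merges runs within `mergeDistance` (default 0 =
overlapping/bookended, the bedtools-merge default), and emits runs strictly
longer than 40 nt — "at least two read depth" is ≥ 2 and "greater than 40
nucleotides" is a strict inequality. Whether depth should be pooled or
per-strand is not specified by the published analyses; pooled is the
default and `perStrand = TRUE` is available. Read-to-locus assignment is
any-overlap, so a read straddling two loci counts in both.

`buildCoverage()` gives per-base, per-strand depth with size-range and
uniqueness filters; multi-mapped reads contribute at every placement
(consistent with `-a` mapping), with an optional `weighted` mode dividing
by placement count. `dualStrandFraction()` partitions bases into
dual-covered / single-strand / uncovered, summing to 1 exactly — dual
coverage is the footprint of double-stranded substrates (e.g. plastid RNA
in animals that ingested it). `compartmentRatio()` interprets "coverage of
X relative to Y" as length-normalised read density (distinct reads per bp),
a choice recorded in its output, since the original figure does not define
its units.

`annotateReads()` resolves multi-class overlaps by priority
(miRNA > tRNA > rRNA > other classes > unannotated); the published analysis
does not state a resolution rule, so the priority is a package decision and
is reported alongside the counts.

## The simulator: a stated world

`simulationConfig()` fixes the generative constants; `simulateLibrary()`
emits a mixed library with a per-read truth table. The defaults encode the
library types the detectors are meant for:

| parameter | default | rationale |
|---|---|---|
| `dicerSizeDist` | mass on 18–23 nt, mode 21 | arthropod Dicer products |
| `overhang` | 2 nt | RNase III 3' overhangs |
| `duplexAsymmetry` | offsets 0/±1/±2 (p = .5/.3/.2) | duplex pairs offset by one or two bases |
| `pingpongOverlap` | 10 nt | Piwi slicing 10 nt from the guide 5' end |
| `primary5pBias`, `secondary10ABias` | 0.8 | strong but imperfect 5'U / 10A biases |
| `piRNASizeRange` | 25–30 nt | piRNA-sized reads |
| `plantSRNASize` | 24 nt | plant heterochromatic Dicer products |
| `degradationSizeRange` | 15–19 nt | degradation skews below 20 nt; no quantitative distribution is published, so uniform 15–19 nt is a stated assumption exposed in the config |
| `degradationFraction` | 0.1 enriched / 0.8 total | chromatography enrichment vs total RNA background |
| trigger length | 350 nt | typical in-vitro dsRNA trigger size |

Two modelling points deserve emphasis:

* **Duplex lengths.** A duplex with 2-nt 3' overhangs at *both* ends has
  equal strand lengths by geometry. The simulator draws one size per duplex
  and adds a bounded partner offset, anchored in the canonical register.
  Offsets below $-h$ are rejected by the config validity check because such
  a pair can no longer satisfy $v = q - h$ from either role — it would be
  invisible to the detector the simulator exists to exercise.
* **Coupled piRNA biases.** With an exact 10-nt 5' overlap, the secondary's
  position-10 base is the Watson–Crick complement of the primary's 5' base.
  Since simulated reads must match the reference exactly (that invariant is
  what makes the aligner testable), one reference base realises both
  biases: the primary 5' position is drawn from reference T positions with
  probability `primary5pBias`. The two config fields are therefore honoured
  jointly when equal (the default); they are kept as separate fields for
  reporting symmetry.

Dicing is modelled as independent uniform placement within the source, not
processive phasing from dsRNA ends: phasing is not asserted by any detector
here, and independence keeps the chance-pair baseline analysable by
permutation. Quality strings are constant ("I"); qualities are never used.

**What a green test does not establish.** The simulator has uniform base
composition, no sequencing errors, no ligation bias, no PCR duplicates, and
clean class labels. Recovery of its parameters validates the estimators'
arithmetic and geometry, not their robustness to real-library artefacts.

## Numerical and interface choices

* Internal coordinates are 1-based closed `GRanges` throughout (the
  Bioconductor convention); BED and the truth TSV are written 0-based
  half-open, SAM 1-based, conversions happening only at the file boundary.
* The config requires `dicerSizeDist` to sum to 1 within 1e-9, and the
  weighted coverage validity check tolerates accumulated floating error of
  1e-9 per base.
* The z-score is undefined (NA) when the other offsets have zero variance;
  an empty alignment set yields an all-zero pair matrix, an `NA` Dicer
  fraction, and a `(0, 0, flagged)` strand fraction, while a zero
  denominator in `dicerEnrichment()`, `compartmentRatio()` or
  `representationRatio()` is an error rather than an Inf.
* Adapter trimming is exact-match: the leftmost full-adapter occurrence
  wins; otherwise the longest end-anchored adapter prefix of at least
  `minOverlap` (default 8) nt. Simulated data contains exact adapters, and
  no mismatch model is published; mismatch tolerance is left as a config
  extension point.
* Subsampling is uniform without replacement and errors rather than
  resample when asked for more reads than exist.
* `runPipeline()` takes a JSON config (no YAML parser is assumed), records
  every threshold and seed in `report.json`, writes the config verbatim
  into the output directory, and caches stage outputs keyed by a hash of
  their parameters chained to the upstream stage hash, so partial reruns
  reuse earlier work.

## Worked example

```{r, eval = FALSE}
library(sRNAsieve)

cfg <- simulationConfig(seed = 1, condition = "enriched", depth = 1000L)
refs <- makeReferences(cfg)
lib <- simulateLibrary(cfg, references = refs)

idx <- buildIndex(refs$genome, k = 12)
aln <- mapPerfect(lib$reads, idx, maxPlacements = 200)

trigger <- aln[seqnames(aln) == "trigger"]
pairMatrix(trigger)                 # mass on/near the diagonal, 18-23 nt
dicerReadFraction(trigger)          # 1.0 for pure simulated duplexes

nuclear <- aln[seqnames(aln) == "nuclear"]
fivePrimeOverlapHist(nuclear)       # peak at offset 10
callLoci(aln)                       # depth >= 2, length > 40 loci
```

## Limitations

* The aligner is exact-match only (no mismatches, gaps, or qualities), by
  design — it reproduces a specific published mapping protocol, not a
  general-purpose aligner.
* Low-complexity filtering is implemented solely through the placement cap;
  no dust-style sequence filter is applied.
* Locus intersection reports raw any-overlap counts; no overlap-enrichment
  null model is provided.
* The pipeline is single-library; comparative statistics
  (`dicerEnrichment()`, `representationRatio()`, `intersectLoci()`) take
  the two precomputed sides explicitly.
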