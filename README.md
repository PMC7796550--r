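# sRNAsieve

Small RNA sequencing libraries mix genuine *trans*-acting small RNAs
(siRNAs, miRNAs, piRNAs) with RNA degradation fragments — a problem that is
acute when asking what happens to *ingested* RNA (synthetic dsRNA triggers,
short hairpins, dietary plant transcripts) in animals that lack antibodies
or genetic tools for direct validation. Because small RNA library
construction preserves the exact 5'/3' termini and the strand of every
molecule, biogenesis can be read from alignments alone. sRNAsieve detects
those signatures and ships a ground-truth simulator so that every statistic
is verifiable by parameter recovery.

## What it computes

* **Dicer duplex signature.** RNase III cleavage leaves 2-nt 3' overhangs,
  so the two strands of an siRNA duplex overlap by 2 nt less than the read
  length. For query length $q$, partner overlap $v$ and overhang $h$, a
  pair of opposite-strand alignments is counted when $v = q - h$;
  `pairMatrix()` accumulates counts by (query length, partner length),
  `dicerReadFraction()` gives the fraction of distinct reads in at least
  one such pair, `dicerEnrichment()` the ratio of that fraction between a
  condition of interest and total RNA.
* **piRNA ping-pong.** `fivePrimeOverlapHist()` counts opposite-strand
  pairs by 5'-5' overlap $o$ (inclusive; the ping-pong signal is an argmax
  at $o = 10$ with z-score > 3) and `nucleotideBias()` builds positional
  base-frequency matrices (5'U on primaries, position-10 A on secondaries).
* **Perfect-match all-placements alignment.** `buildIndex()` /
  `mapPerfect()` reproduce `bowtie -a -v0 -m 200` semantics, including the
  discard-entirely multimapping cap; `hierarchicalMap()` gives two-genome
  co-mapping fractions.
* **Expressed loci.** `callLoci()` annotates intervals with pooled read
  depth ≥ 2 over runs longer than 40 nt; `locusSizeProfile()` and
  `intersectLoci()` give per-locus size histograms and set overlaps.
* **Coverage analytics.** `buildCoverage()`, `dualStrandFraction()` (the
  footprint of double-stranded substrates), `compartmentRatio()`
  (length-normalised plastid vs nuclear representation), `densityTrack()`.
* **Read accounting.** `trimAdapter()`, `subsampleReads()`,
  `sizeDistribution()`, `annotateReads()`, `representationRatio()`.
* **Simulation.** `simulationConfig()` + `simulateLibrary()` generate
  references, annotations, and reads with per-read truth labels under an
  "enriched" (10% degradation) or "total" (80% degradation) condition;
  `runPipeline()` orchestrates everything from one JSON config.

## Worked example

```r
library(sRNAsieve)
library(GenomicRanges)

cfg  <- simulationConfig(seed = 1, condition = "enriched", depth = 1000L)
refs <- makeReferences(cfg)
lib  <- simulateLibrary(cfg, references = refs)

idx <- buildIndex(refs$genome, k = 12)
aln <- mapPerfect(lib$reads, idx, maxPlacements = 200)

trigger <- aln[seqnames(aln) == "trigger"]
pairMatrix(trigger)
#> PairMatrix (literal mode, overhang 2 nt): 3762 pairs from 1004 alignments
#>   (q=21, t=21): 484
#>   (q=21, t=19): 248
#>   (q=21, t=20): 247
#>   (q=20, t=20): 246
#>   (q=20, t=21): 227
dicerReadFraction(trigger)
#> [1] 0.9980159
fivePrimeOverlapHist(aln[seqnames(aln) == "nuclear"])
#> OverlapHistogram: offsets 1..30; peak at 10 (z = 207.62)
length(callLoci(aln))
#> [1] 59
```

The pair matrix concentrates on 19–23 nt cells on or near the diagonal —
the size and asymmetry structure of Dicer duplexes — and essentially every
read on the dsRNA trigger participates in a counted pair. The nuclear
piRNA reads peak at a 10-nt 5' overlap, and 59 read-dense loci pass the
depth ≥ 2 / length > 40 thresholds.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline statistics from scratch against the
installed package: it simulates matched enriched and total-RNA libraries
from the same substrates, appends and trims adapters, maps with the
perfect-match aligner, and reruns the Dicer, ping-pong, locus and coverage
detectors, logging the results and writing the target object to `--out`.

## Layout

* `R/` — implementation (S4 classes in `AllClasses.R`, one file per stage).
* `tests/testthat/` — unit, property and oracle-equivalence tests;
  `test-acceptance.R` holds the acceptance surface.
* `vignettes/small-rna-signatures.Rmd` — the methods vignette: models,
  assumptions, parameter rationale, simulator scope, limitations.
* `scripts/acceptance.R` — see above.
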