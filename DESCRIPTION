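Package: sRNAsieve
Title: Small RNA Biogenesis Signatures: Dicer Duplexes, Ping-Pong Pairs,
    and Expressed Loci from Small RNA Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects the hallmarks of small RNA biogenesis in short-read
    sequencing libraries so that trans-acting small RNAs (siRNAs, miRNAs,
    piRNAs) can be distinguished from RNA degradation fragments. Implements
    adapter trimming and depth normalisation, a self-contained perfect-match
    all-placements read aligner with Bowtie-style multimapping caps, the
    overlap-pair matrix that identifies Dicer cleavage duplexes by their
    2-nt 3' overhangs, the piRNA ping-pong 10-nt 5'-overlap statistic with
    positional nucleotide-bias matrices, density-based annotation of small
    RNA producing loci, strand-resolved coverage analytics, and read-class
    accounting against genomic annotations. A generative simulator with
    per-read ground truth makes every statistic verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Sequencing, SmallRNA, Alignment, Coverage, Annotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
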