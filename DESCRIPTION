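Package: srnapipe
Title: Small RNA-Seq Discovery and Differential Expression for Multi-Replicon Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and characterizing bacterial
    small RNAs (sRNAs) from two-condition sRNA-Seq libraries on genomes with
    several replicons (a chromosome plus plasmids). Provides adapter trimming
    and read-level quality filters, an exact-match test mapper emitting SAM,
    unification of near-identical alignments into transcript units,
    strand-aware genomic-context classification (rRNA, tRNA, ORF, antisense,
    intergenic, 5' leader), a threshold-based two-condition differential
    filter, length-distribution and replicon-location statistics, cis-antisense
    target coordinate mapping with IUPAC motif scanning for RNase E cleavage
    consensus sites, and a ground-truthed synthetic scenario generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
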