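Package: satquant
Title: Satellite and Repeat Transcript Quantification from Stranded RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies satellite (HSAT2, HSAT3, alpha-satellite) and
    retroelement (LINE, SINE, LTR/ERV) transcripts from stranded, aligned
    RNA-seq reads. Builds a repeat/non-repeat annotation with de novo
    pericentromeric HSAT3 locus calling and hierarchical resolution of
    overlapping features, filters reads by mapping quality and rRNA/tRNA
    overlap, and reports class-level RPM tables, the repeat/mRNA ratio,
    per-locus satellite expression matrices and sense/antisense strand
    summaries. Also provides pathogen-likeness sequence statistics (GC and
    AU skew, CpG/UpA dinucleotide observed-over-expected usage), analysis
    of ChIP-derived contigs against a 24-mer satellite motif library
    (identity filtering, locus assignment, enrichment testing, recurring
    k-mer motifs, peak-repeat overlap counting), exact small-sample
    Wilcoxon rank statistics, and a synthetic-data generator that plants
    satellite arrays, retroelements and coding genes in a toy genome and
    simulates stranded aligned read sets and ChIP contigs with per-record
    truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
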