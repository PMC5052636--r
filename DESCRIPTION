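Package: bsrwalk
Title: Bulked-Segregant RNA-Seq Linkage Mapping and Transposon Seq-Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Map-based cloning toolkit for recessive mutants in biparental
    crosses, modeled on the strategy used to clone maize root-hair genes.
    Computes per-SNP Bayesian linkage posteriors from pooled (bulked
    segregant) RNA-seq allele counts of mutant and wild-type F2 bulks,
    scans chromosomes with a sliding-window median to call a mapping
    interval in physical and genetic coordinates, and identifies candidate
    transposon insertion alleles from barcoded flanking-sequence
    ("Seq-walking") reads by demultiplexing, terminal-inverted-repeat
    trimming, desk-scale read mapping, binned insertion-site calling,
    subtraction of a control library, and read-count ranking inside the
    mapping interval. A fully seeded synthetic-data generator (reference
    genome, genetic map with centromeric recombination suppression, F2
    population under the Haldane model, bulk allele counts, Seq-walking
    FASTQ) provides ground truth for end-to-end recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
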