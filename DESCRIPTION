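Package: introscan
Title: Coverage-Based Detection of Alien Introgressions in Wheat Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large alien introgressions (wild-relative chromosomal
    segments, rye arm translocations, and assembled haplotype contigs) in
    panels of inbred wheat lines from whole-genome alignment coverage
    summaries against multiple reference genomes, including composite
    references carrying an alien chromosome. Provides a synthetic panel
    generator with known ground truth for validating the detectors,
    readers and writers for samtools-coverage tables, bedgraph tracks,
    GT-only VCF and PAF alignments, site filtering by minor allele
    frequency, missingness and heterozygosity, sequence-ontology impact
    classification, per-base nucleotide diversity, neighbor-joining trees
    from identity-by-state distances, and a reproducible multi-stage
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
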