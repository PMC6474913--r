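Package: paleometh
Title: Regional CpG Methylation Inference from Ancient DNA Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood mapping of regional CpG methylation levels
    from ancient DNA sequencing data. Post-mortem cytosine deamination is
    faster at methylated than unmethylated CpGs; paleometh exploits this by
    first estimating position-specific deamination rates along DNA fragments
    for methylated and unmethylated cytosines, then estimating the fraction
    of methylated CpG copies in genomic windows while marginalising over an
    unobserved dinucleotide genotype space and accounting for sequencing and
    mapping errors. A methylation-aware ancient-DNA read simulator is
    included for end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
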