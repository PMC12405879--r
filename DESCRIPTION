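Package: satmine
Title: Satellite DNA Discovery and Comparison in Genome Assemblies and Reads
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandem repeat arrays in genome assemblies, standardizes
    repeat monomers to a canonical rotation/strand, clusters them into
    satellite DNA families with consensus and A/B variant calling, quantifies
    per-family genomic abundance (BED/TSV reports), profiles simple short
    satellites directly in unassembled short reads, flags families restricted
    to or enriched in one assembly (e.g. germline-restricted chromosomes),
    and designs conserved and variant-discriminating FISH oligo probes.
    Includes a seeded synthetic-data generator with truth manifests so every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
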