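Package: methylowp
Title: Whole-Genome Bisulfite Methylome Analysis Under Low-Phosphorus Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing methylomes
    in paired stress/control designs, modelled on the low-phosphorus soybean
    root methylome. Provides per-context (CG/CHG/CHH) methylation metrics and
    conversion-efficiency estimation from an unmethylated spike-in, metagene
    and transposable-element methylation profiles, a six-criterion
    differentially methylated region (DMR) caller based on methylated-site
    chaining and a pooled-count chi-square test, FPKM computation and
    differential expression calling, DMR-to-gene/TE integration with
    hypergeometric term enrichment, 24-nt siRNA association analyses, and a
    fully deterministic synthetic-data generator with truth tables for
    benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
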