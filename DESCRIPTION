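Package: bsamap
Title: Bulked Segregant Analysis Mapping from Pooled Sequencing of F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for mapping a monogenic recessive locus by bulked segregant
    analysis of pooled whole-genome sequencing (QTL-seq style). Implements SNP
    reliability filtering, per-pool SNP-index and delta SNP-index statistics, a
    sliding-window genome scan with Monte-Carlo confidence bands, candidate
    region delimitation, and Mendelian segregation and marker-phenotype
    co-segregation tests. Includes a fully parameterized simulator of F2
    populations segregating a recessive causal locus with phenotypic pool
    construction and pooled short-read sampling, so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
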