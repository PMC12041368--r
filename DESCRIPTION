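Package: germsoma
Title: Somatic Alterations in Germline Cancer Risk Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates somatic mutation data with germline ovarian-cancer
    risk regions: gene-by-signature association scans with a permutation
    gene-set null, construction of 1 Mb risk-locus intervals around GWAS
    index SNPs, frequently-mutated-element burden testing and enrichment
    across functional annotations and chromatin states, recurrent
    copy-number region calling from segmentation data, and transcription
    factor binding-site disruption scoring for germline and somatic
    variants with intersection of the resulting TF lists. A synthetic-data
    module generates all inputs with the statistical structure the
    analyses assume, so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
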