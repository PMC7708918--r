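Package: gikit
Title: InDel Marker Panels, Identity Signatures and Population Genetics
    for Clonal Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for managing large clonal-crop germplasm collections with
    co-dominant insertion/deletion (InDel) fragment-length markers. Covers the
    full workflow: triage of structural-variant calls (Delly-style VCF) into
    genotyping candidates, selection of a genome-spaced marker panel and its
    packing into fluorescent multiplex PCR groups; canonical identity
    signatures for accession fingerprinting with duplicate, synonym, homonym
    and bud-sport analysis; population diversity statistics (Na, Ne, Shannon
    I, Ho, He, F), Weir-Cockerham Fst with exact differentiation tests,
    Hardy-Weinberg exact tests and genotype-frequency pattern classification;
    Mendelian-exclusion parentage analysis; and a synthetic-collection
    generator (Balding-Nichols structured populations, pedigrees, clonal
    lineages with somatic mutation) with a machine-readable truth log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
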