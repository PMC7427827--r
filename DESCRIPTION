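Package: coldqtl
Title: Chilling Tolerance Trait Phenotyping and Mixed-Model QTL Mapping in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping seedling-stage chilling tolerance in structured
    rice diversity panels. Computes percent electrolyte leakage (EL) and
    low-temperature seedling survivability (LTSS) from replicated raw
    measurements, estimates the median lethal temperature (LT50) per accession
    with a binomial generalized linear model, runs an EMMAX-style single-marker
    mixed-model association scan with an identity-by-state kinship matrix,
    calls quantitative trait loci (QTL) from clusters of significant SNPs,
    merges them into unique and multi-trait QTL with genome-coverage and
    legacy-QTL accounting, and applies a candidate-gene filtering cascade
    (transposable-element purge, significant-SNP presence, major-allele
    frequency and allele-effect direction). A Balding-Nichols synthetic panel
    generator with planted causal loci and temperature-dependent survival makes
    the whole pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
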