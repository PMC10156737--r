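Package: famseg
Title: Family-Based Rare-Variant Segregation Analysis for Dominant Late-Onset Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery analysis for rare, high-impact coding variants in
    multiplex families under an autosomal dominant model with incomplete
    penetrance. Provides annotation-driven variant filtering (functional
    category, CADD deleteriousness, reference-population allele frequency),
    per-family segregation testing with a configurable discordance tolerance,
    cross-family gene-level collapsing and ranking, carrier-frequency burden
    comparison against a reference cohort (exact and chi-squared), two-locus
    phenotype co-occurrence rates, densitometry quantification for
    co-immunoprecipitation experiments with exact rank tests, and a
    gene-dropping simulator that generates fully synthetic pedigree studies
    (VCF, PED, annotation and carrier tables) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
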