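Package: hbdscan
Title: Autozygosity Mapping and Recessive Variant Prioritization in
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive disease genes in consanguineous
    families from exome variant calls. Implements read-fraction zygosity
    classification, sliding-window homozygosity mapping (500-marker windows
    with heterozygote and gap tolerances), run-based identity-by-descent
    segment detection, intersection of case-shared homozygosity-by-descent
    (HBD) regions with exclusion of control overlap, variant-level filters
    for rare protein-affecting recessive candidates, and prioritization of
    variants that segregate with disease under an autosomal recessive
    model. A gene-drop simulator for first-cousin pedigrees with planted
    causal variants provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
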