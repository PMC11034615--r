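Package: dyneqtl
Title: Dynamic eQTL Mapping and GWAS Integration for Condition-Responsive
    Regulatory Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis- and trans-acting expression quantitative trait loci
    (eQTL) in a diversity panel assayed under two conditions, classifies each
    gene's population-level stress response by a fold-change/prevalence rule,
    catalogues association peaks into static and dynamic (condition-specific)
    categories, runs kinship-aware mixed-model genome-wide association scans,
    colocalizes trait and expression signals with approximate Bayes factors,
    and triangulates candidate genes across the resulting evidence sets.
    Includes a synthetic-data generator that plants known cis/trans effects,
    response classes and a colocalizing trait QTL so that the whole inference
    chain can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
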