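Package: triase
Title: Allele-Specific Expression, Dosage and Heterosis Analysis for Triploid Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gene expression in interspecific triploid
    hybrids from diploid x tetraploid crosses: negative-binomial exact tests
    for differential expression, classification of expression inheritance
    (additive, dominant, transgressive), cis/trans regulatory divergence from
    allele-specific read counts, chromosome dosage and aneuploidy inference
    from allelic ratios, per-gene dosage-outlier detection, and ridge-regression
    prediction of midparent heterosis under nested cross-validation. Includes a
    fully labelled synthetic-data generator emulating the count and
    allele-count structure of such families, so every stage can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
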