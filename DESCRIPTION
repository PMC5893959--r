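Package: micrantha
Title: Comparative Genomics of a Non-Berry-Forming Strawberry Relative:
    Assembly Metrics, LTR Retrotransposon Dating, Expression Dynamics,
    and Microsynteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative procedures for comparative genome and
    transcriptome analysis between Potentilla micrantha and Fragaria
    vesca (woodland strawberry) style datasets: flow-cytometry genome
    size conversion and assembly/annotation summary statistics;
    structural validation of full-length LTR retrotransposons (TG..CA
    termini, target-site duplications, primer binding sites, polypurine
    tracts), superfamily classification from protein domain order,
    Kimura two-parameter inter-LTR divergence and insertion-age dating
    calibrated from Nei-Gojobori synonymous substitution rates; an
    FPKM/mode-alignment/variance-stabilisation/one-way-ANOVA
    differential expression procedure with sqrt(MSR) and p-value
    cut-offs; ortholog-anchor microsynteny block detection with
    inversion and translocation reporting; and seeded synthetic-data
    generators with ground-truth tables so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    ggplot2,
    withr
Config/testthat/edition: 3
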