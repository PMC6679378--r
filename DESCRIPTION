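Package: eqtlcross
Title: Expression QTL Mapping in F2 Intercrosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of expression quantitative trait loci
    (eQTL) in an F2 intercross between two inbred strains. Provides a
    synthetic-data generator for F2 genotypes and expression phenotypes with
    known genetic architecture, hidden-Markov-model genotype probabilities on
    a pseudomarker grid, Haley-Knott regression genome scans with additive
    and interactive covariates (sex, cross direction), per-transcript
    permutation-based genome-wide significance with Benjamini-Hochberg FDR
    across transcripts, cis/trans eQTL classification, trans-hotspot
    detection, cross-tissue and cross-population conservation analysis,
    hypergeometric pathway enrichment, and microarray preprocessing
    (normexp background correction, quantile normalization, detection
    filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
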