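Package: snpmeta
Title: Meta-Analysis of Case-Control Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of case-control single-nucleotide
    polymorphism association studies from per-study genotype counts.
    Implements Hardy-Weinberg equilibrium testing with control-arm study
    filtering, construction of 2x2 exposure tables under the five standard
    genetic-model contrasts (allele, homozygote, heterozygote, dominant,
    recessive), Mantel-Haenszel fixed-effects and DerSimonian-Laird
    random-effects odds-ratio pooling with Cochran Q / I-squared
    heterogeneity and automatic model selection, Egger regression and
    Begg-Mazumdar rank-correlation publication-bias tests, funnel- and
    forest-plot data, etiology subgroup analysis, leave-one-out sensitivity
    analysis, and a seed-deterministic simulator of genotype-count corpora
    with known ground truth. Ships a curated corpus of published TGF-beta-1
    polymorphism studies in chronic liver disease as example data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
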