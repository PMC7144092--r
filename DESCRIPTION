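Package: modscreen
Title: Quantitative Analysis for Drosophila Genetic-Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for genetic-modifier screens of
    Drosophila excitability mutants: the Benzer countercurrent climbing
    index and its binomial generative model, a center-occupancy tremor
    metric for circular-arena video tracking, heat-induced seizure
    incidence time-courses with two-way repeated-measures ANOVA,
    bang-sensitivity recovery-time comparisons, exact contingency-table
    analysis of penetrance and viability tables with Bonferroni control,
    and a simplified negative-binomial differential-expression stage with
    median-of-ratios normalization, Benjamini-Hochberg adjustment and
    hypergeometric GO over-representation. Includes synthetic-data
    generators emulating every assay so the full pipeline is testable
    without raw recordings or sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
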