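Package: adaptscan
Title: Climate-Adaptation Scans for Candidate-Gene Promoter Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for detecting footprints of climate-driven
    selection in candidate-gene promoter polymorphisms genotyped across many
    populations. Reads published breed-level genotype/allele-frequency and
    climate tables, reconstructs integer genotype counts, and provides
    population-genetic summaries (heterozygosity, Hardy-Weinberg exact test,
    EM-based linkage-disequilibrium r2), Weir-Cockerham FST and Reynolds
    distances with permutation and Markov-chain exact differentiation tests,
    partial least squares regression of allele frequencies on environmental
    predictors with VIP/VT2 variable elimination and van der Voet model
    comparison, per-allele logistic environmental-association scans with
    likelihood-ratio and Wald tests under Bonferroni control, island-model
    FST-outlier detection with an iterative neutral-FST procedure, and
    cross-species molecular-evolution summaries (Tamura 3-parameter plus
    gamma distances, Tajima's D, neighbor-joining trees). A synthetic-data
    module generates genotype panels, climate tables and sequence alignments
    with the statistical structure each stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
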