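Package: titr
Title: Trans-Ancestral Iterative Tissue Refinement for Functionally
    Informed Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of functionally informed polygenic
    risk score (PRS) models whose SNPs are prioritized by tissue-specific
    regulatory annotations. Implements stratified LD score regression to
    partition SNP heritability across annotation tracks, PLINK-style
    p-value clumping with an LD-block sampling rule that selects at most
    one SNP per block, pruning-and-thresholding score optimization over a
    dense p-value grid, and the Trans-ancestral Iterative Tissue
    Refinement (TITR) loop that greedily merges percentile slices of
    heritability-enriched tissue annotations into a cumulative PRS,
    accepting an iteration only when it adds significant information
    (ANOVA for nested models, Davidson-MacKinnon J test otherwise).
    Includes a two-population genotype/phenotype/annotation simulator with
    controllable linkage-disequilibrium contrast for studying PRS
    portability between a training and a genetically distinct target
    population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    jsonlite,
    yaml
Config/testthat/edition: 3
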