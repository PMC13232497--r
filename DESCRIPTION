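Package: privqtl
Title: Genetic Architecture of Hierarchical Size Traits in Isogenic Fly Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of body size,
    nutritional size plasticity, sexual size dimorphism (SSD), and
    sex-specific plasticity (SSP) in panels of isogenic Drosophila lineages.
    Implements lineage-level BLUP phenotype indices from mixed models,
    a two-step genome-wide association scan (a fast lineage-level screen
    followed by per-marker mixed linear models keyed to genotype-by-sex,
    genotype-by-diet, and genotype-by-sex-by-diet interaction terms),
    an LD-aware gene-based association test with a multivariate-normal
    empirical null, permutation gene-set enrichment on per-gene minimum
    p-values, and factorial analysis of RNAi knockdown validation
    experiments with backward elimination. Includes a synthetic-data
    generator that plants context-dependent ("private") marker effects so
    the whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
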