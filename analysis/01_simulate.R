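#!/usr/bin/env Rscript
# Stage 1: build the synthetic study panel.
#
# Simulates an isogenic panel in the image of a DGRP-style experiment:
# 150 lineages, 800 markers in 4-marker LD blocks, Wolbachia/inversion/PC
# covariates, and individual log pupal-case sizes for every lineage x sex
# x diet cell under the panel mixed model. Three private QTLs are planted:
# one context-free size locus (G), one diet-context plasticity locus
# (GxD), and one sex-by-diet locus (GxSxD) -- the SSP signal the rest of
# the workflow hunts for. All fixtures and the generative truth land in
# results/data/.

suppressMessages(library(privqtl))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

panel <- simulate_panel(n_lineages = 150, n_markers = 800,
                        maf_range = c(0.05, 0.5), ld_block_size = 4,
                        ld_rho = 0.6, missing_rate = 0.01, seed = 101)
covars <- simulate_covariates(panel, wolbachia_freq = 0.5, n_inversions = 5,
                              n_pcs = 10, seed = 102)
ann <- simulate_annotation(panel, markers_per_gene = 4, frac_intergenic = 0.15,
                           seed = 104)

# plant QTLs in gene-assigned, common markers so the gene-level stage has
# a recoverable target
genic <- panel$marker_id %in% ann$marker_id[ann$gene_id != "intergenic"]
by_maf <- intersect(panel$marker_id[order(-panel$maf)], panel$marker_id[genic])
planted <- data.frame(
  marker_id = by_maf[c(1, 40, 80)],
  class = c("GxSxD", "GxD", "G"),
  beta = c(0.08, 0.08, 0.08))
truth <- sim_truth(planted = planted, seed = 103)

records <- simulate_individuals(panel, covars, truth,
                                design = list(n_per_group = 12, n_blocks = 4),
                                seed = 103)

write_fixture("results/data", panel, covars, records, truth)
write_annotation(ann, "results/data/annotation.tsv")

write_provenance("results/data/provenance_simulate.json",
                 config = list(seeds = c(panel = 101, covars = 102, truth = 103,
                                         annotation = 104),
                               n_lineages = 150, n_markers = 800,
                               ld_block_size = 4, ld_rho = 0.6,
                               n_per_group = 12, n_blocks = 4,
                               planted = planted),
                 counts = list(records = nrow(records),
                               genes = length(setdiff(unique(ann$gene_id),
                                                      "intergenic"))))

cat(sprintf("panel: %d lineages x %d markers; %d individual records\n",
            nrow(panel$calls), length(panel$marker_id), nrow(records)))
cat("planted effects:\n"); print(planted)
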