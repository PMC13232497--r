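#!/usr/bin/env Rscript
# Stage 3: the fast lineage-level association screen.
#
# For each summary phenotype, every marker is tested with an ordinary
# linear model of the lineage value on the major/minor allele class,
# correcting additively for Wolbachia, inversions, and relatedness PCs.
# This is the cheap prescreen of the two-step design; its ranked tables
# feed the mixed-model stage. SSP is screened on both the raw index and
# the fed-independent index, as the downstream scan unions their top sets.

suppressMessages(library(privqtl))

panel <- read_genotypes("results/data/genotypes.tsv")
covars <- read_covariates("results/data/covariates.tsv")
summ <- read_tsv <- utils::read.table("results/lineage_summary.tsv",
                                      header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE)

phenos <- c("ssp", "ssp_indep", "ssd_fed", "delta_lineage", "b_lineage_fed")
for (ph in phenos) {
  v <- setNames(summ[[ph]], summ$lineage_id)
  tab <- screen_all(panel, covars, v, phenotype_name = ph)
  write_result_table(tab, sprintf("results/screen_%s.tsv", ph),
                     meta = c(phenotype = ph, min_minor_lineages = 4))
  cat(sprintf("%-14s: %d tested, %d skipped, best p = %.3e (%s)\n",
              ph, sum(!tab$skipped), sum(tab$skipped),
              tab$p_value[1], tab$marker_id[1]))
}
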