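# shared fixture builders; everything is generated in code at test time

# tiny deterministic panel built by hand (6 lineages x 4 markers)
toy_panel <- function() {
  calls <- rbind(c(0, 0, 2, 0),
                 c(0, 2, 0, 0),
                 c(0, 0, 0, 2),
                 c(2, 0, 2, 0),
                 c(2, 2, 0, 0),
                 c(2, 0, 0, 2))
  rownames(calls) <- sprintf("L%d", 1:6)
  panel_genotypes(paste0("m", 1:4), rep("2L", 4), c(100, 200, 5000, 9000),
                  rep("A", 4), rep("T", 4), calls)
}

# balanced noise-free records for a given per-cell mean function
cell_records <- function(lineages, mean_fun, n_per_cell = 2,
                         block = "b1") {
  grid <- expand.grid(lineage_id = lineages, sex = c("F", "M"),
                      diet = c("fed", "starved"), rep = seq_len(n_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$block <- block
  grid$size <- mapply(mean_fun, grid$lineage_id, grid$sex, grid$diet)
  grid[c("lineage_id", "sex", "diet", "block", "size")]
}

# mean over a lineage x sex x diet cell of a record set
cell_mean <- function(records, lineage, sex, diet) {
  mean(records$size[records$lineage_id == lineage &
                      records$sex == sex & records$diet == diet])
}

# the SSP contrast of cell means for one lineage:
# (fed - starved) difference of the (female - male) difference
ssp_contrast <- function(records, lineage) {
  (cell_mean(records, lineage, "F", "fed") - cell_mean(records, lineage, "M", "fed")) -
    (cell_mean(records, lineage, "F", "starved") - cell_mean(records, lineage, "M", "starved"))
}

zero_varcomp <- c(lineage_intercept = 0, sex_slope = 0, diet_slope = 0,
                  sexdiet_slope = 0, block = 0, residual = 0)
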