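test_that("simulated panels respect the isogenic coding and marker map invariants", {
  pan <- simulate_panel(40, 60, maf_range = c(0.1, 0.4), ld_block_size = 5,
                        ld_rho = 0.5, missing_rate = 0.05, seed = 11)
  expect_true(all(pan$calls %in% c(0, 2) | is.na(pan$calls)))
  expect_true(all(pan$maf >= 0.1 - 1e-9 & pan$maf <= 0.5))
  for (ch in unique(pan$chrom))
    expect_true(all(diff(pan$pos[pan$chrom == ch]) > 0))
  expect_equal(pan$maf, compute_maf(pan$calls))
  expect_gt(mean(is.na(pan$calls)), 0.02)
})

test_that("identical seeds reproduce the panel bitwise; invalid arguments are rejected", {
  a <- simulate_panel(20, 30, seed = 5)
  b <- simulate_panel(20, 30, seed = 5)
  expect_identical(a$calls, b$calls)
  expect_identical(a$pos, b$pos)
  expect_error(simulate_panel(20, 30, ld_rho = 1), "ld_rho")
  expect_error(simulate_panel(20, 0), "n_markers")
  expect_error(simulate_panel(1, 10), "n_lineages")
})

test_that("ld_rho = 0 gives independent markers; ld_rho = 0.8 is hit within 0.1", {
  pan0 <- simulate_panel(400, 40, ld_block_size = 4, ld_rho = 0, seed = 7)
  cc <- cor(pan0$calls)
  off <- abs(cc[upper.tri(cc)])
  expect_lt(mean(off), 3 / sqrt(400))

  pan <- simulate_panel(500, 80, ld_block_size = 4, ld_rho = 0.8, seed = 8)
  adj <- sapply(seq(1, 77, by = 4), function(j)
    c(cor(pan$calls[, j], pan$calls[, j + 1]),
      cor(pan$calls[, j + 1], pan$calls[, j + 2]),
      cor(pan$calls[, j + 2], pan$calls[, j + 3])))
  expect_lt(abs(mean(adj) - 0.8), 0.1)
  # between-block independence
  btw <- sapply(seq(4, 76, by = 4), function(j) cor(pan$calls[, j], pan$calls[, j + 1]))
  expect_lt(abs(mean(btw)), 0.15)
})

test_that("covariates: PC1 separates genotype clusters, wolbachia_freq = 0 is all-zero, seeds reproduce", {
  # two clearly separated clusters of lineages
  set.seed(3)
  calls <- rbind(matrix(rbinom(15 * 30, 1, 0.9) * 2, 15),
                 matrix(rbinom(15 * 30, 1, 0.1) * 2, 15))
  rownames(calls) <- sprintf("L%02d", 1:30)
  pan <- panel_genotypes(paste0("m", 1:30), rep("X", 30), seq_len(30) * 1000,
                         rep("A", 30), rep("G", 30), calls)
  cov <- simulate_covariates(pan, wolbachia_freq = 0, n_inversions = 2,
                             n_pcs = 1, seed = 4)
  cluster <- rep(c(1, 0), each = 15)
  expect_gt(abs(cor(cov$PC1, cluster)), 0.9)
  expect_true(all(cov$wolbachia == 0))
  cov2 <- simulate_covariates(pan, wolbachia_freq = 0, n_inversions = 2,
                              n_pcs = 1, seed = 4)
  expect_identical(cov, cov2)
  expect_error(simulate_covariates(pan, n_pcs = 30, seed = 1), "n_pcs")
})

test_that("noise-free records reproduce the fixed-effect cell means exactly", {
  pan <- toy_panel()
  tr <- sim_truth(fixed = c(intercept = 6, sex = 0.1, diet = 0.2, sex_diet = 0.04),
                  varcomp = zero_varcomp)
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 2, n_blocks = 1),
                              seed = 1)
  expected <- function(sex, diet) {
    s <- ifelse(sex == "F", 0.5, -0.5); d <- ifelse(diet == "fed", 0.5, -0.5)
    6 + 0.1 * s + 0.2 * d + 0.04 * s * d
  }
  expect_equal(rec$size, expected(rec$sex, rec$diet), tolerance = 1e-12)
})

test_that("a planted three-way effect equals the cell-mean contrast exactly in the noise-free limit", {
  pan <- toy_panel()
  beta <- 0.07
  tr <- sim_truth(planted = data.frame(marker_id = "m1", class = "GxSxD", beta = beta),
                  varcomp = zero_varcomp)
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 3, n_blocks = 1),
                              seed = 2)
  minor <- rownames(pan$calls)[pan$calls[, "m1"] == 2]
  major <- rownames(pan$calls)[pan$calls[, "m1"] == 0]
  contrast <- mean(sapply(minor, ssp_contrast, records = rec)) -
    mean(sapply(major, ssp_contrast, records = rec))
  expect_equal(contrast, beta, tolerance = 1e-12)
})

test_that("a planted diet-context effect leaves the fed-cell sex contrast untouched", {
  pan <- toy_panel()
  tr0 <- sim_truth(varcomp = zero_varcomp)
  trd <- sim_truth(planted = data.frame(marker_id = "m2", class = "GxD", beta = 0.1),
                   varcomp = zero_varcomp)
  r0 <- simulate_individuals(pan, NULL, tr0, list(n_per_group = 2, n_blocks = 1), seed = 3)
  rd <- simulate_individuals(pan, NULL, trd, list(n_per_group = 2, n_blocks = 1), seed = 3)
  for (l in rownames(pan$calls)) {
    sex_fed_0 <- cell_mean(r0, l, "F", "fed") - cell_mean(r0, l, "M", "fed")
    sex_fed_d <- cell_mean(rd, l, "F", "fed") - cell_mean(rd, l, "M", "fed")
    expect_equal(sex_fed_d, sex_fed_0, tolerance = 1e-12)
    # but the diet contrast moves for minor-allele lineages
    if (pan$calls[l, "m2"] == 2) {
      d0 <- cell_mean(r0, l, "F", "fed") - cell_mean(r0, l, "F", "starved")
      dd <- cell_mean(rd, l, "F", "fed") - cell_mean(rd, l, "F", "starved")
      expect_equal(dd - d0, 0.1, tolerance = 1e-12)
    }
  }
})

test_that("planted markers must exist in the panel and seeds reproduce records", {
  pan <- toy_panel()
  tr <- sim_truth(planted = data.frame(marker_id = "nope", class = "G", beta = 1))
  expect_error(simulate_individuals(pan, NULL, tr, list(n_per_group = 1, n_blocks = 1), seed = 1),
               "absent from panel")
  tr2 <- sim_truth()
  a <- simulate_individuals(pan, NULL, tr2, list(n_per_group = 2, n_blocks = 2), seed = 9)
  b <- simulate_individuals(pan, NULL, tr2, list(n_per_group = 2, n_blocks = 2), seed = 9)
  expect_identical(a, b)
})

test_that("a fitted mixed model recovers the generative variance components within 20%", {
  pan <- simulate_panel(400, 10, ld_rho = 0, seed = 21)
  tr <- sim_truth(varcomp = c(lineage_intercept = 0.004, sex_slope = 0.002,
                              diet_slope = 0.003, sexdiet_slope = 0.001,
                              block = 0, residual = 0.01))
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 12, n_blocks = 1),
                              seed = 22)
  rec$s <- ifelse(rec$sex == "F", 0.5, -0.5)
  rec$d <- ifelse(rec$diet == "fed", 0.5, -0.5)
  rec$sd_ <- rec$s * rec$d
  fit <- lme4::lmer(size ~ s * d + (1 | lineage_id) + (0 + s | lineage_id) +
                      (0 + d | lineage_id) + (0 + sd_ | lineage_id),
                    rec, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- c(vc$vcov[vc$var1 %in% "(Intercept)" & vc$grp != "Residual"][1],
           vc$vcov[vc$var1 %in% "s"], vc$vcov[vc$var1 %in% "d"],
           vc$vcov[vc$var1 %in% "sd_"],
           vc$vcov[vc$grp == "Residual"])
  truth <- unname(tr$varcomp[c("lineage_intercept", "sex_slope", "diet_slope",
                               "sexdiet_slope", "residual")])
  expect_true(all(abs(est - truth) / truth < 0.2))
})
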