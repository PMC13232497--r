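toy_annotation <- function() {
  data.frame(marker_id = paste0("m", 1:5),
             gene_id = c("geneA", "geneA", "geneB", "intergenic", "geneB"),
             site_class = c("coding", "intronic", "UTR", "intergenic", "upstream"),
             distance = c(0, 0, 0, 5000, 1500),
             stringsAsFactors = FALSE)
}

test_that("markers map to genes by annotation, intergenic and unknown markers are excluded", {
  ann <- toy_annotation()
  map <- assign_snps_to_genes(ann, paste0("m", 1:5))
  expect_equal(sort(names(map)), c("geneA", "geneB"))
  expect_setequal(map$geneA, c("m1", "m2"))
  expect_setequal(map$geneB, c("m3", "m5"))
  expect_true(all(assign_snps_to_genes(
    data.frame(marker_id = "z", gene_id = "intergenic",
               site_class = "intergenic", distance = 9000),
    "z") |> lengths() == 0))
  expect_warning(assign_snps_to_genes(ann, c("m1", "mystery")), "not in the annotation")
  # a marker annotated to two genes appears under each
  ann2 <- rbind(ann, data.frame(marker_id = "m1", gene_id = "geneB",
                                site_class = "downstream", distance = 200))
  map2 <- assign_snps_to_genes(ann2, paste0("m", 1:5))
  expect_true("m1" %in% map2$geneA && "m1" %in% map2$geneB)
})

test_that("the 2 kb assignment window is enforced on annotation read", {
  ok <- data.frame(marker_id = "a", gene_id = "g1", site_class = "upstream",
                   distance = 1999)
  bad <- data.frame(marker_id = "b", gene_id = "g1", site_class = "upstream",
                    distance = 2001)
  f <- tempfile(fileext = ".tsv")
  write_annotation(ok, f)
  expect_silent(read_annotation(f))
  write_annotation(bad, f)
  expect_error(read_annotation(f), "2 kb")
  # intergenic rows may sit at any distance
  write_annotation(data.frame(marker_id = "c", gene_id = "intergenic",
                              site_class = "intergenic", distance = 99999), f)
  expect_silent(read_annotation(f))
})

test_that("the gene statistic is the sum of inverse-chi-square transforms of the SNP p-values", {
  expect_equal(gene_statistic(1)$statistic, 0)
  gs <- gene_statistic(c(0.05, 0.5))
  expect_equal(gs$x, c(3.841459, 0.4549364), tolerance = 1e-6)
  expect_equal(gs$statistic, 4.296395, tolerance = 1e-6)
  k <- 7
  expect_equal(gene_statistic(rep(0.5, k))$statistic, k * qchisq(0.5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # monomorphic SNPs are ignored
  gs2 <- gene_statistic(c(0.05, 0.5), polymorphic = c(TRUE, FALSE))
  expect_equal(gs2$statistic, 3.841459, tolerance = 1e-6)
  expect_equal(gs2$n_snps_used, 1L)
  expect_warning(gene_statistic(c(0, 0.5)), "clamped")
  expect_error(gene_statistic(c(-0.1, 0.5)), "p-values")
})

test_that("LD matrices are Pearson correlations repaired to positive definiteness", {
  calls <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2), c(0, 0, 2, 2), c(2, 2, 2, 2))
  rownames(calls) <- paste0("L", 1:4)
  pan <- panel_genotypes(paste0("m", 1:4), rep("X", 4), 1:4 * 100,
                         rep("A", 4), rep("C", 4), calls)
  # orthogonal pair: correlation 0
  r <- ld_matrix(pan, c("m1", "m2"))
  expect_equal(unname(r[1, 2]), 0, tolerance = 1e-12)
  # duplicated column: off-diagonal ~1 after repair, unit diagonal, PD
  r2 <- ld_matrix(pan, c("m1", "m3"))
  expect_gte(unname(r2[1, 2]), 1 - 1e-6)
  expect_equal(unname(diag(r2)), c(1, 1), tolerance = 1e-12)
  expect_gt(min(eigen(r2, symmetric = TRUE)$values), 0)
  # constant column dropped before correlation
  r3 <- ld_matrix(pan, c("m1", "m4"))
  expect_equal(dim(r3), c(1L, 1L))
  expect_equal(attr(r3, "dropped"), "m4")
})

test_that("the MVN empirical null matches analytic chi-square tails under identity LD", {
  expect_equal(vegas_empirical_p(0, diag(3), n_reps = 1000, seed = 1), 1)
  for (k in c(2, 6)) {
    obs <- qchisq(0.1, k, lower.tail = FALSE)
    p <- vegas_empirical_p(obs, diag(k), n_reps = 5e4, seed = k)
    expect_lt(abs(p - 0.1), 3 * sqrt(0.1 * 0.9 / 5e4))
  }
  # lower-tail convention is the complement
  obs <- qchisq(0.25, 2, lower.tail = FALSE)
  up <- vegas_empirical_p(obs, diag(2), n_reps = 2e4, seed = 3)
  lo <- vegas_empirical_p(obs, diag(2), n_reps = 2e4, seed = 3, tail = "lower")
  expect_lt(abs(up + lo - 1), 0.01)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(vegas_empirical_p(1, bad), "positive definite")
  expect_error(vegas_empirical_p(1, diag(2), n_reps = 10), "n_reps")
})

test_that("aggregate gene signal can beat the best single SNP, and small n_reps warns", {
  set.seed(81)
  pan <- simulate_panel(60, 6, ld_rho = 0, seed = 81)
  ann <- data.frame(marker_id = pan$marker_id,
                    gene_id = c(rep("geneA", 4), "geneB", "intergenic"),
                    site_class = "coding", distance = 0)
  mlm <- data.frame(marker_id = pan$marker_id,
                    p_value = c(rep(5e-3, 4), 0.4, 0.9),
                    skipped = FALSE)
  res <- suppressWarnings(run_vegas(pan, ann, mlm, threshold = 1e-4,
                                    n_reps = 1e5, seed = 82))
  pA <- res$empirical_p[res$gene_id == "geneA"]
  expect_lt(pA, 5e-3)      # beats the best constituent SNP
  expect_equal(res$n_snps[res$gene_id == "geneA"], 4)
  expect_warning(run_vegas(pan, ann, mlm, threshold = 1e-5, n_reps = 1000,
                           seed = 1), "resolve")
})

test_that("set enrichment reproduces the exhaustive permutation null on a small universe", {
  # universe of 4 genes with min-p 0.1/0.2/0.3/0.4; set = the two smallest
  pan <- simulate_panel(30, 4, ld_rho = 0, seed = 83)
  ann <- data.frame(marker_id = pan$marker_id,
                    gene_id = paste0("g", 1:4), site_class = "coding", distance = 0)
  mlm <- data.frame(marker_id = pan$marker_id, p_value = c(0.1, 0.2, 0.3, 0.4),
                    skipped = FALSE)
  res <- set_enrichment(mlm, ann, c("g1", "g2"), n_perm = 20000, seed = 84)
  expect_equal(res$observed_mean_min_p, 0.15)
  # exhaustive null over the 6 two-gene subsets: exactly one mean <= 0.15
  expect_lt(abs(res$empirical_p - 1 / 6), 2 * sqrt((1/6) * (5/6) / 20000) + 0.01)
  # saturation: set = universe, every draw reproduces the observed mean
  sat <- set_enrichment(mlm, ann, paste0("g", 1:4), n_perm = 500, seed = 85)
  expect_equal(sat$empirical_p, 1)
  expect_error(set_enrichment(mlm, ann, "absent_gene"), "no overlap")
})
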