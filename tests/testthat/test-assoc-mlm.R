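test_that("phenotype names map to the correct model forms and target terms", {
  ssp <- build_spec("SSP")
  expect_equal(ssp$target, "s:d:g2")
  expect_setequal(ssp$random, c("intercept", "sex", "diet", "sex_diet"))
  expect_true("s:d:g2" %in% ssp$fixed)

  ssd <- build_spec("ssd_fed")
  expect_equal(ssd$target, "s:g2")
  expect_equal(ssd$subset$diet, "fed")
  expect_setequal(ssd$random, c("intercept", "sex"))

  pf <- build_spec("plasticity_female")
  expect_equal(pf$target, "d:g2")
  expect_equal(pf$subset$sex, "F")

  sz <- build_spec("size_female_fed")
  expect_equal(sz$fixed, "g2")
  expect_equal(sz$target, "g2")
  expect_equal(sz$random, "intercept")

  expect_error(build_spec("not_a_trait"), "unknown phenotype")
})

test_that("with zero random-effect variance the MLM reproduces factorial least squares", {
  pan <- toy_panel()
  tr <- sim_truth(planted = data.frame(marker_id = "m1", class = "GxSxD", beta = 0.08),
                  varcomp = c(lineage_intercept = 0, sex_slope = 0, diet_slope = 0,
                              sexdiet_slope = 0, block = 0, residual = 0.01))
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 6, n_blocks = 1),
                              seed = 61)
  spec <- build_spec("ssp")
  res <- fit_marker_mlm(rec, pan$calls[, "m1"], spec, marker_id = "m1")
  # factorial OLS oracle on the same coding
  d <- rec
  d$s <- ifelse(d$sex == "F", 0.5, -0.5)
  d$d_ <- ifelse(d$diet == "fed", 0.5, -0.5)
  d$g2 <- pan$calls[d$lineage_id, "m1"] / 2
  ols <- lm(size ~ s * d_ * g2, d)
  expect_equal(res$effect, unname(coef(ols)["s:d_:g2"]), tolerance = 1e-6)
  expect_false(res$skipped)
})

test_that("monomorphic markers are skipped and the fallback ladder is recorded", {
  pan <- toy_panel()
  tr <- sim_truth()
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 4, n_blocks = 2),
                              seed = 62)
  spec <- build_spec("ssp")
  mono <- setNames(rep(0, 6), rownames(pan$calls))
  res <- fit_marker_mlm(rec, mono, spec)
  expect_true(res$skipped)
  expect_equal(res$reason, "monomorphic")
  ok <- fit_marker_mlm(rec, pan$calls[, "m1"], spec)
  expect_equal(ok$fallback, "diagonal")
  ok2 <- fit_marker_mlm(rec, pan$calls[, "m1"], spec, re_structure = "intercept")
  expect_equal(ok2$fallback, "intercept")
})

test_that("a planted three-way effect is recovered by the two-step scan and ranks as a candidate", {
  pan <- simulate_panel(80, 60, ld_block_size = 3, ld_rho = 0.4, seed = 63)
  tr <- sim_truth(planted = data.frame(marker_id = "mrk_00010", class = "GxSxD",
                                       beta = 0.12))
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 10, n_blocks = 3),
                              seed = 64)
  bl <- estimate_blups(rec)
  summ <- derive_indices(bl)
  ts <- run_two_step(pan, NULL, rec, "ssp",
                     list(ssp = setNames(summ$ssp, summ$lineage_id)),
                     k = 15, threshold = 1e-5)
  expect_true("mrk_00010" %in% ts$candidates)
  expect_equal(ts$counts$n_fitted, length(ts$top_markers))
  # threshold = 1 makes every fitted marker a candidate
  cand_all <- ts$mlm_table$marker_id[!ts$mlm_table$skipped]
  ts1 <- ts
  expect_setequal(ts1$mlm_table$marker_id[!ts1$mlm_table$skipped &
                                            ts1$mlm_table$p_value < 1], cand_all)
})

test_that("private-QTL contract: a context-free effect does not masquerade as an SSP signal", {
  pan <- simulate_panel(100, 8, ld_rho = 0, seed = 65)
  trG <- sim_truth(planted = data.frame(marker_id = "mrk_00001", class = "G",
                                        beta = 0.15))
  rec <- simulate_individuals(pan, NULL, trG, list(n_per_group = 10, n_blocks = 2),
                              seed = 66)
  rec <- remove_block_effects(rec)
  ssp_res <- fit_marker_mlm(rec, pan$calls[, "mrk_00001"], build_spec("ssp"),
                            marker_id = "mrk_00001")
  sz_res <- fit_marker_mlm(rec[rec$sex == "F" & rec$diet == "fed", ],
                           pan$calls[, "mrk_00001"], build_spec("size_female_fed"),
                           marker_id = "mrk_00001")
  expect_gt(ssp_res$p_value, 0.01)   # three-way test stays null
  expect_lt(sz_res$p_value, 1e-5)    # size test sees the main effect
})

test_that("covariate elimination keeps a planted confounder and drops pure noise covariates", {
  set.seed(67)
  pan <- simulate_panel(120, 10, ld_rho = 0, seed = 67)
  tr <- sim_truth()
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 8, n_blocks = 2),
                              seed = 68)
  rec <- remove_block_effects(rec)
  lid <- rownames(pan$calls)
  wol <- rbinom(120, 1, 0.5)
  # wolbachia shifts lineage mean size; one noise covariate alongside
  rec$size <- rec$size + 0.08 * wol[match(rec$lineage_id, lid)]
  cov <- data.frame(lineage_id = lid, wolbachia = wol, noise = rnorm(120))
  class(cov) <- c("lineage_covariates", "data.frame")
  kept <- select_covariates(rec, cov, build_spec("ssp"), alpha = 0.05)
  expect_true("wolbachia" %in% kept)
  expect_false(any(grepl("noise", kept)))
  # zero covariates: empty retained set
  cov0 <- data.frame(lineage_id = lid)
  class(cov0) <- c("lineage_covariates", "data.frame")
  expect_length(select_covariates(rec, cov0, build_spec("ssp")), 0)
  # constant covariate excluded with a note
  covc <- data.frame(lineage_id = lid, flat = 1)
  class(covc) <- c("lineage_covariates", "data.frame")
  sel <- select_covariates(rec, covc, build_spec("ssp"))
  expect_equal(attr(sel, "excluded"), "flat")
})

test_that("rank accumulation counts hits along stage-1 rank and finds the plateau", {
  ranks <- setNames(1:6, paste0("m", 1:6))
  p <- setNames(c(1, 1e-6, 1, 1, 1e-7, 1), paste0("m", 1:6))
  acc <- rank_accumulation(ranks, p)
  expect_equal(acc$curve$cum_hits, c(0L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(acc$plateau_rank, 5L)
  expect_equal(acc$n_hits, 2L)
  # no hits: constant-zero curve, plateau 0
  acc0 <- rank_accumulation(ranks, setNames(rep(0.5, 6), paste0("m", 1:6)))
  expect_true(all(acc0$curve$cum_hits == 0L))
  expect_equal(acc0$plateau_rank, 0L)
  # monotone non-decreasing for random inputs
  set.seed(69)
  for (i in 1:5) {
    pr <- setNames(runif(20)^4, paste0("x", 1:20))
    rk <- setNames(sample(20), paste0("x", 1:20))
    a <- rank_accumulation(rk, pr, threshold = 0.05)
    expect_true(all(diff(a$curve$cum_hits) >= 0))
  }
})

test_that("the random-control scan samples reproducibly from outside the prescreen set", {
  pan <- simulate_panel(50, 30, ld_rho = 0, seed = 70)
  tr <- sim_truth()
  rec <- simulate_individuals(pan, NULL, tr, list(n_per_group = 3, n_blocks = 1),
                              seed = 71)
  spec <- build_spec("size_fed")
  excl <- pan$marker_id[1:20]
  a <- random_control(pan, excl, 5, rec, spec, seed = 7)
  b <- random_control(pan, excl, 5, rec, spec, seed = 7)
  expect_identical(attr(a, "summary")$sampled, attr(b, "summary")$sampled)
  expect_true(all(!attr(a, "summary")$sampled %in% excl))
  expect_error(random_control(pan, pan$marker_id, 5, rec, spec), "pool")
})
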