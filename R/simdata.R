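#' Simulate an isogenic-panel genotype matrix with block LD
#'
#' Generates homozygous biallelic markers for a panel of inbred lineages.
#' Markers are arranged in blocks of `ld_block_size` adjacent markers;
#' within a block, adjacent markers are in linkage disequilibrium with
#' pairwise genotype correlation targeting `ld_rho`, and markers in
#' different blocks are independent. LD is produced by a Gaussian copula:
#' each block draws latent standard-normal vectors with a first-order
#' autoregressive structure whose latent correlation is calibrated
#' (numerically, through the bivariate-normal orthant probability) so that
#' the *thresholded* 0/2 genotypes attain the requested correlation. One
#' minor-allele frequency is drawn per block from `maf_range` so the
#' within-block correlation target is attainable; thresholding is at the
#' empirical latent quantile, making the realized frequency of the minor
#' lineage class deterministic given the draw.
#'
#' @param n_lineages number of isogenic lineages (>= 2).
#' @param n_markers number of markers (>= 1).
#' @param maf_range length-2 numeric in (0, 0.5]: minor-lineage frequency
#'   band markers are drawn from.
#' @param ld_block_size markers per LD block.
#' @param ld_rho target genotype correlation between adjacent markers of a
#'   block, in \[0, 1).
#' @param missing_rate proportion of calls set missing completely at random.
#' @param seed integer RNG seed; identical seeds give identical panels.
#' @return A [panel_genotypes] object.
#' @export
simulate_panel <- function(n_lineages, n_markers,
                           maf_range = c(0.05, 0.5),
                           ld_block_size = 5, ld_rho = 0.8,
                           missing_rate = 0, seed = 1) {
  if (n_lineages < 2) stop("n_lineages must be >= 2")
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  set.seed(seed)

  n_blocks <- ceiling(n_markers / ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(n_markers)]
  block_maf <- stats::runif(n_blocks, maf_range[1], maf_range[2])

  # minor-class count per block: fixed by empirical-quantile thresholding,
  # clamped so the realized frequency stays inside maf_range
  m_lo <- max(1L, ceiling(maf_range[1] * n_lineages))
  m_hi <- max(m_lo, floor(maf_range[2] * n_lineages))
  block_m <- pmin(m_hi, pmax(m_lo, round(block_maf * n_lineages)))

  calls <- matrix(0, n_lineages, n_markers)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    p <- block_m[b] / n_lineages
    r_lat <- if (ld_rho == 0 || length(idx) == 1) 0 else latent_rho(p, ld_rho)
    z <- matrix(stats::rnorm(n_lineages * length(idx)), n_lineages)
    if (r_lat > 0 && length(idx) > 1) {
      for (j in 2:length(idx))
        z[, j] <- r_lat * z[, j - 1] + sqrt(1 - r_lat^2) * z[, j]
    }
    for (j in seq_along(idx)) {
      minor <- rank(z[, j], ties.method = "first") <= block_m[b]
      calls[minor, idx[j]] <- 2
    }
  }

  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA

  # marker map: blocks split over the five major chromosome arms,
  # positions spaced 0.1-5 kb apart, tight within blocks
  arms <- c("2L", "2R", "3L", "3R", "X")
  arm_of_block <- arms[ceiling(seq_len(n_blocks) / max(1, ceiling(n_blocks / 5)))]
  chrom <- arm_of_block[block_of]
  pos <- integer(n_markers)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    gaps <- ifelse(duplicated(block_of[i]), sample(100:500, length(i), TRUE),
                   sample(2000:5000, length(i), TRUE))
    pos[i] <- cumsum(gaps)
  }
  nts <- c("A", "C", "G", "T")
  major <- sample(nts, n_markers, TRUE)
  minor <- vapply(major, function(a) sample(setdiff(nts, a), 1), "")

  rownames(calls) <- sprintf("line_%03d", seq_len(n_lineages))
  panel_genotypes(sprintf("mrk_%05d", seq_len(n_markers)),
                  chrom, pos, major, minor, calls)
}

# Latent AR coefficient such that two standard-normal variables with that
# correlation, both thresholded at the p-quantile, have binary correlation
# `target`. Solved through the bivariate-normal orthant probability.
latent_rho <- function(p, target) {
  q <- stats::qnorm(p)
  binr <- function(r) {
    if (r >= 1) return(1)
    p11 <- stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm((q - r * z) / sqrt(1 - r^2)),
      -8, q, rel.tol = 1e-10)$value
    (p11 - p^2) / (p * (1 - p))
  }
  stats::uniroot(function(r) binr(r) - target, c(0, 0.99999),
                 tol = 1e-8)$root
}

#' Simulate lineage covariates (Wolbachia, inversions, relatedness PCs)
#'
#' Produces the covariate record used to correct association scans in
#' DGRP-style panels: binary Wolbachia infection status, binary inversion
#' genotypes drawn from the catalogue of common cosmopolitan inversions,
#' and the leading principal-component scores of the centered genotype
#' matrix (missing calls imputed to the marker mean), which capture panel
#' relatedness structure.
#'
#' @param panel a [panel_genotypes] object.
#' @param wolbachia_freq infection probability per lineage.
#' @param n_inversions number of inversion loci simulated (<= 11, the
#'   catalogue size).
#' @param n_pcs number of genotype principal components returned
#'   (<= n_lineages - 1).
#' @param inversion_freq carrier frequency per inversion.
#' @param seed integer RNG seed.
#' @return data.frame of class `lineage_covariates` with columns
#'   `lineage_id`, `wolbachia`, one column per inversion, `PC1..PCn`.
#' @export
simulate_covariates <- function(panel, wolbachia_freq = 0.5, n_inversions = 5,
                                n_pcs = 20, inversion_freq = 0.2, seed = 1) {
  nl <- n_lineages(panel)
  if (nl < 1) stop("panel is empty")
  if (n_pcs > nl - 1) stop("n_pcs must be <= n_lineages - 1")
  if (n_inversions > length(inversion_catalogue()))
    stop("at most ", length(inversion_catalogue()), " inversions available")
  set.seed(seed)
  cov <- data.frame(lineage_id = lineage_ids(panel),
                    wolbachia = stats::rbinom(nl, 1, wolbachia_freq),
                    stringsAsFactors = FALSE)
  inv_names <- inversion_catalogue()[seq_len(n_inversions)]
  for (nm in inv_names) cov[[nm]] <- stats::rbinom(nl, 1, inversion_freq)
  if (n_pcs > 0) {
    g <- impute_marker_means(panel$calls)
    g <- g[, apply(g, 2, stats::sd) > 0, drop = FALSE]
    pc <- stats::prcomp(g, center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    cov <- cbind(cov, as.data.frame(sc))
  }
  rownames(cov) <- NULL
  class(cov) <- c("lineage_covariates", "data.frame")
  cov
}

#' @export
inversion_catalogue <- function() {
  c("In(2L)t", "In(2R)NS", "In(3R)K", "In(3R)P", "In(3R)Mo",
    "In(2R)Y1", "In(2R)Y5", "In(3L)P", "In(3L)M", "In(3L)Y", "In(3R)C")
}

impute_marker_means <- function(calls) {
  if (!anyNA(calls)) return(calls)
  mu <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls), arr.ind = TRUE)
  calls[idx] <- mu[idx[, 2]]
  calls
}

#' Declare the generative truth of a simulated experiment
#'
#' Bundles the fixed effects, planted marker effects, and variance
#' components that [simulate_individuals()] realizes. Fixed and planted
#' effects are declared on the contrast scale: `sex` is the female-minus-male
#' difference, `diet` the fed-minus-starved difference, `sex_diet` the diet
#' difference of the sex difference, all in log-size units. A planted effect
#' of class `"G"` shifts the lineage mean of minor-allele carriers by `beta`;
#' `"GxS"` shifts their sex contrast, `"GxD"` their diet contrast, and
#' `"GxSxD"` their sex-by-diet contrast, each by `beta`, leaving the other
#' contrasts untouched (the "private QTL" structure).
#'
#' @param fixed named numeric: `intercept`, `sex`, `diet`, `sex_diet`.
#' @param planted data.frame with columns `marker_id`,
#'   `class` in \{"G","GxS","GxD","GxSxD"\}, `beta` (log units); at most one
#'   class per marker. NULL for none.
#' @param varcomp named numeric variances (all >= 0):
#'   `lineage_intercept`, `sex_slope`, `diet_slope`, `sexdiet_slope`,
#'   `block`, `residual`.
#' @param seed integer seed recorded with the truth.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(fixed = c(intercept = 6, sex = 0.1, diet = 0.15, sex_diet = 0.05),
                      planted = NULL,
                      varcomp = c(lineage_intercept = 0.0036, sex_slope = 4e-4,
                                  diet_slope = 9e-4, sexdiet_slope = 2.25e-4,
                                  block = 4e-4, residual = 0.01),
                      seed = 1) {
  need <- c("intercept", "sex", "diet", "sex_diet")
  if (!all(need %in% names(fixed))) stop("fixed must name ", paste(need, collapse = ", "))
  needv <- c("lineage_intercept", "sex_slope", "diet_slope", "sexdiet_slope",
             "block", "residual")
  if (!all(needv %in% names(varcomp))) stop("varcomp must name ", paste(needv, collapse = ", "))
  if (any(varcomp < 0)) stop("variance components must be >= 0")
  if (is.null(planted)) {
    planted <- data.frame(marker_id = character(), class = character(),
                          beta = numeric(), stringsAsFactors = FALSE)
  } else {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("marker_id", "class", "beta") %in% names(planted)))
    if (!all(planted$class %in% c("G", "GxS", "GxD", "GxSxD")))
      stop("planted class must be G, GxS, GxD or GxSxD")
    if (anyDuplicated(planted$marker_id)) stop("at most one planted effect per marker")
  }
  structure(list(fixed = fixed[need], planted = planted,
                 varcomp = varcomp[needv], seed = seed),
            class = "sim_truth")
}

#' Simulate individual size records under the panel model
#'
#' Realizes log body-size observations for every lineage x sex x diet cell
#' under the generative counterpart of the panel mixed model: fixed sex,
#' diet, and sex-by-diet effects; planted context-dependent marker effects
#' scaled by allele dose/2; lineage random intercepts and independent random
#' sex, diet, and sex-by-diet slopes; a random block intercept; and Gaussian
#' residual noise. Sex and diet enter as centered +-1/2 contrasts (female
#' and fed positive), so each fixed or planted coefficient equals the
#' corresponding cell-mean contrast exactly in the noise-free limit.
#'
#' @param panel a [panel_genotypes] object.
#' @param covariates unused by the generator (covariate effects on size are
#'   not simulated); accepted for interface symmetry. Pass NULL.
#' @param truth a [sim_truth] object; every planted marker must be in `panel`.
#' @param design list with `n_per_group` (records per lineage x sex x diet
#'   cell) and `n_blocks` (temporal blocks, assigned at random per record).
#' @param seed integer RNG seed.
#' @return data.frame of `SizeRecord`s: `lineage_id`, `sex` ("F"/"M"),
#'   `diet` ("fed"/"starved"), `block`, `size` (log scale).
#' @export
simulate_individuals <- function(panel, covariates = NULL, truth,
                                 design = list(n_per_group = 10, n_blocks = 3),
                                 seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (design$n_per_group < 1 || design$n_blocks < 1) stop("design counts must be >= 1")
  missing_planted <- setdiff(truth$planted$marker_id, panel$marker_id)
  if (length(missing_planted))
    stop("planted marker(s) absent from panel: ", paste(missing_planted, collapse = ", "))
  set.seed(seed)

  lid <- lineage_ids(panel)
  nl <- length(lid)
  grid <- expand.grid(lineage_id = lid, sex = c("F", "M"),
                      diet = c("fed", "starved"),
                      rep = seq_len(design$n_per_group),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- ifelse(grid$sex == "F", 0.5, -0.5)
  d <- ifelse(grid$diet == "fed", 0.5, -0.5)
  li <- match(grid$lineage_id, lid)

  vc <- truth$varcomp
  u0 <- stats::rnorm(nl, 0, sqrt(vc["lineage_intercept"]))
  us <- stats::rnorm(nl, 0, sqrt(vc["sex_slope"]))
  ud <- stats::rnorm(nl, 0, sqrt(vc["diet_slope"]))
  usd <- stats::rnorm(nl, 0, sqrt(vc["sexdiet_slope"]))
  blk <- sample.int(design$n_blocks, nrow(grid), replace = TRUE)
  ablk <- stats::rnorm(design$n_blocks, 0, sqrt(vc["block"]))

  fx <- truth$fixed
  size <- fx["intercept"] + fx["sex"] * s + fx["diet"] * d + fx["sex_diet"] * s * d +
    u0[li] + us[li] * s + ud[li] * d + usd[li] * s * d + ablk[blk] +
    stats::rnorm(nrow(grid), 0, sqrt(vc["residual"]))

  if (nrow(truth$planted)) {
    for (r in seq_len(nrow(truth$planted))) {
      dose <- panel$calls[, truth$planted$marker_id[r]] / 2
      dose[is.na(dose)] <- 0   # missing call: no planted contribution
      b <- truth$planted$beta[r]
      ctx <- switch(truth$planted$class[r],
                    G = 1, GxS = s, GxD = d, GxSxD = s * d)
      size <- size + dose[li] * b * ctx
    }
  }

  data.frame(lineage_id = grid$lineage_id, sex = grid$sex, diet = grid$diet,
             block = sprintf("block_%02d", blk), size = as.numeric(size),
             stringsAsFactors = FALSE)
}

#' Simulate a marker-to-gene annotation table
#'
#' Assigns runs of consecutive markers to synthetic genes, leaving a
#' fraction intergenic (more than 2 kb from any gene), mirroring the
#' structure of DGRP-style annotation files: genic markers carry a site
#' class (coding, UTR, intronic) at distance 0; flanking markers are
#' upstream/downstream at a distance within the 2 kb assignment window.
#'
#' @param panel a [panel_genotypes] object.
#' @param markers_per_gene consecutive markers assigned to each gene.
#' @param frac_intergenic fraction of markers left unassigned.
#' @param seed integer RNG seed.
#' @return annotation data.frame (`marker_id`, `gene_id`, `site_class`,
#'   `distance`).
#' @export
simulate_annotation <- function(panel, markers_per_gene = 4,
                                frac_intergenic = 0.2, seed = 1) {
  set.seed(seed)
  n <- length(panel$marker_id)
  gene_of <- rep(seq_len(ceiling(n / markers_per_gene)),
                 each = markers_per_gene)[seq_len(n)]
  intergenic <- stats::runif(n) < frac_intergenic
  genic_classes <- c("coding", "UTR", "intronic")
  flank_classes <- c("upstream", "downstream")
  flank <- stats::runif(n) < 0.25
  site <- ifelse(intergenic, "intergenic",
                 ifelse(flank, sample(flank_classes, n, TRUE),
                        sample(genic_classes, n, TRUE)))
  dist <- ifelse(site == "intergenic", sample(2001:50000, n, TRUE),
                 ifelse(site %in% flank_classes, sample(1:2000, n, TRUE), 0L))
  data.frame(marker_id = panel$marker_id,
             gene_id = ifelse(intergenic, "intergenic",
                              sprintf("gene_%04d", gene_of)),
             site_class = site,
             distance = as.integer(dist),
             stringsAsFactors = FALSE)
}

#' Write a simulated data set to disk as plain-text fixtures
#'
#' Serializes a panel, covariates, individual records, and the generative
#' truth to an output directory (`genotypes.tsv`, `covariates.tsv`,
#' `individuals.tsv`, `truth.json`). Files round-trip losslessly through
#' [read_genotypes()], [read_covariates()], [read_individuals()] and
#' [read_truth()]: non-float fields exactly, floats to 12 significant digits.
#'
#' @param outdir output directory, created if needed.
#' @param panel,covariates,records,truth the objects to serialize; any may
#'   be NULL to skip.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(outdir, panel = NULL, covariates = NULL,
                          records = NULL, truth = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  paths <- character()
  if (!is.null(panel)) {
    p <- file.path(outdir, "genotypes.tsv")
    write_genotypes(panel, p); paths <- c(paths, p)
  }
  if (!is.null(covariates)) {
    p <- file.path(outdir, "covariates.tsv")
    write_covariates(covariates, p); paths <- c(paths, p)
  }
  if (!is.null(records)) {
    p <- file.path(outdir, "individuals.tsv")
    write_individuals(records, p); paths <- c(paths, p)
  }
  if (!is.null(truth)) {
    p <- file.path(outdir, "truth.json")
    write_truth(truth, p); paths <- c(paths, p)
  }
  invisible(paths)
}
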