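#' Map tested markers to genes
#'
#' Restricts a marker set to those assigned to annotated genes (markers in
#' intergenic regions more than 2 kb from a gene are excluded) and returns
#' the gene-to-marker map. A marker annotated to several genes appears
#' under each; markers absent from the annotation are excluded with a
#' warning.
#'
#' @param annotation annotation data.frame (`marker_id`, `gene_id`,
#'   `site_class`, `distance`); `gene_id = "intergenic"` rows are ignored.
#' @param markers marker ids to map.
#' @return named list: gene_id -> character vector of marker ids.
#' @export
assign_snps_to_genes <- function(annotation, markers) {
  unknown <- setdiff(markers, annotation$marker_id)
  if (length(unknown))
    warning(length(unknown), " marker(s) not in the annotation; excluded")
  ann <- annotation[annotation$marker_id %in% markers &
                      !is.na(annotation$gene_id) &
                      annotation$gene_id != "intergenic", , drop = FALSE]
  ann <- unique(ann[c("marker_id", "gene_id")])
  split(ann$marker_id, ann$gene_id)
}

#' Gene-level chi-square sum statistic
#'
#' Converts the per-SNP association p-values of a gene into equivalent
#' 1-df chi-square values through the inverse chi-square quantile at
#' `1 - p` (small p, large chi-square) and sums them. SNPs flagged
#' monomorphic contribute nothing. A p-value of exactly 0 would map to an
#' infinite quantile and is clamped to the smallest positive double, with
#' a warning.
#'
#' @param p_values per-SNP p-values in (0, 1].
#' @param polymorphic logical flags per SNP (default all TRUE).
#' @return list: `x` (per-SNP chi-square values, NA for skipped SNPs),
#'   `statistic` (their sum), `n_snps_used`.
#' @export
gene_statistic <- function(p_values, polymorphic = rep(TRUE, length(p_values))) {
  stopifnot(length(polymorphic) == length(p_values))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p <- p_values
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-value of 0 clamped to the smallest representable positive value")
    p[p == 0] <- .Machine$double.xmin
  }
  use <- polymorphic & !is.na(p)
  x <- rep(NA_real_, length(p))
  x[use] <- stats::qchisq(p[use], df = 1, lower.tail = FALSE)
  list(x = x, statistic = sum(x[use]), n_snps_used = sum(use))
}

#' LD correlation matrix of a marker set, repaired to positive definite
#'
#' Pearson correlations of the genotype columns across lineages
#' (pairwise-complete over missing calls), with constant columns dropped
#' and the matrix repaired to numerical positive definiteness by flooring
#' its eigenvalues at `eps` and rescaling back to unit diagonal.
#'
#' @param panel a [panel_genotypes].
#' @param markers marker ids.
#' @param eps eigenvalue floor.
#' @return correlation matrix over the retained markers (attribute
#'   `dropped` lists constant markers).
#' @export
ld_matrix <- function(panel, markers, eps = 1e-8) {
  g <- panel$calls[, markers, drop = FALSE]
  keep <- apply(g, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  dropped <- markers[!keep]
  g <- g[, keep, drop = FALSE]
  if (ncol(g) == 0) stop("no polymorphic markers to correlate")
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  if (any(e$values < eps)) {
    v <- pmax(e$values, eps)
    r <- e$vectors %*% (v * t(e$vectors))
    r <- stats::cov2cor(r)
    dimnames(r) <- list(colnames(g), colnames(g))
  }
  attr(r, "dropped") <- dropped
  r
}

#' Empirical gene-level p-value from the multivariate-normal LD null
#'
#' Simulates the gene statistic's null distribution under linkage
#' disequilibrium: draws `n_reps` multivariate-normal vectors with the
#' gene's SNP correlation structure, squares the components (1-df
#' chi-squares), and sums them. The default empirical p-value is the upper
#' tail — the proportion of simulated statistics at or above the observed
#' one, so small p means strong aggregate association. A literal
#' lower-tail convention is available via `tail = "lower"`, and the
#' add-one (never exactly zero) correction via `add_one = TRUE`.
#'
#' @param observed_statistic observed chi-square sum.
#' @param ld positive-definite correlation matrix from [ld_matrix()].
#' @param n_reps Monte-Carlo replicates (>= 1000).
#' @param seed RNG seed.
#' @param tail `"upper"` (default) or `"lower"`.
#' @param add_one if TRUE report `(1 + count) / (1 + n_reps)`.
#' @return empirical p-value.
#' @export
vegas_empirical_p <- function(observed_statistic, ld, n_reps = 1e6, seed = 1,
                              tail = c("upper", "lower"), add_one = FALSE) {
  tail <- match.arg(tail)
  if (n_reps < 1000) stop("n_reps must be >= 1000")
  ch <- tryCatch(chol(ld), error = function(e)
    stop("LD matrix is not positive definite; repair it with ld_matrix()"))
  k <- ncol(ld)
  set.seed(seed)
  count <- 0
  left <- n_reps
  chunk <- max(1, min(left, floor(2e6 / k)))
  while (left > 0) {
    n <- min(chunk, left)
    z <- matrix(stats::rnorm(n * k), n, k) %*% ch
    tstat <- rowSums(z * z)
    count <- count + if (tail == "upper") sum(tstat >= observed_statistic)
                     else sum(tstat <= observed_statistic)
    left <- left - n
  }
  if (add_one) (1 + count) / (1 + n_reps) else count / n_reps
}

#' Gene-based association scan over all annotated genes
#'
#' For each gene with at least one tested polymorphic SNP: sums the
#' per-SNP chi-square equivalents of the stage-2 p-values, estimates the
#' gene's LD matrix from the panel, and computes the empirical p-value
#' against the multivariate-normal null. Genes beating `threshold` are
#' flagged as candidates — a gene can qualify through many modest SNPs
#' even when no single SNP does.
#'
#' @param panel a [panel_genotypes].
#' @param annotation marker annotation table.
#' @param mlm_table AssocResult table (stage-2) with `marker_id`,
#'   `p_value`, `skipped`.
#' @param threshold candidate gene threshold.
#' @param n_reps replicates per gene (a warning is issued when
#'   `1 / n_reps > threshold`, i.e. the null cannot resolve the
#'   candidate threshold).
#' @param seed base RNG seed (per-gene seeds derive from it).
#' @param tail tail convention, see [vegas_empirical_p()].
#' @return GeneAssocResult data.frame: `gene_id`, `n_snps`, `statistic`,
#'   `empirical_p`, `candidate`, `n_reps`, plus omitted-gene notes in
#'   attribute `omitted`.
#' @export
run_vegas <- function(panel, annotation, mlm_table, threshold = 1e-5,
                      n_reps = 1e6, seed = 1, tail = "upper") {
  if (1 / n_reps > threshold)
    warning("n_reps = ", n_reps, " cannot resolve the candidate threshold ",
            threshold)
  tested <- mlm_table[!mlm_table$skipped & !is.na(mlm_table$p_value), ,
                      drop = FALSE]
  pmap <- stats::setNames(tested$p_value, tested$marker_id)
  genes <- assign_snps_to_genes(annotation, names(pmap))
  omitted <- character()
  rows <- list()
  for (i in seq_along(genes)) {
    gid <- names(genes)[i]
    mk <- genes[[i]]
    poly <- mk[apply(panel$calls[, mk, drop = FALSE], 2, function(x)
      stats::sd(x, na.rm = TRUE) > 0)]
    if (length(poly) == 0) { omitted <- c(omitted, gid); next }
    gs <- gene_statistic(pmap[poly])
    ld <- ld_matrix(panel, poly)
    emp <- vegas_empirical_p(gs$statistic, ld, n_reps = n_reps,
                             seed = seed + i, tail = tail)
    rows[[gid]] <- data.frame(gene_id = gid, n_snps = length(poly),
                              statistic = gs$statistic, empirical_p = emp,
                              candidate = emp < threshold, n_reps = n_reps,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  attr(out, "seed") <- seed
  out
}

#' Permutation gene-set enrichment on per-gene minimum p-values
#'
#' Summarizes each gene in the tested universe by the minimum stage-2
#' p-value across its SNPs; the set statistic is the mean of these minima
#' over the genes of the set present in the universe. The null is built by
#' drawing the same number of genes at random from the universe, `n_perm`
#' times; the one-sided empirical p-value is the proportion of null means
#' at or below the observed mean (small means signal enrichment for strong
#' associations).
#'
#' @param mlm_table stage-2 AssocResult table.
#' @param annotation marker annotation table.
#' @param gene_set character vector of gene ids.
#' @param universe gene universe; defaults to all genes with >= 1 tested
#'   SNP.
#' @param n_perm permutation replicates.
#' @param seed RNG seed.
#' @param set_name label for the output.
#' @return list of class `set_enrichment_result`: `set_name`,
#'   `n_genes_tested`, `observed_mean_min_p`, `null_mean`, `null_sd`,
#'   `n_permutations`, `empirical_p`, `gene_min_p` (the per-gene minima
#'   used).
#' @export
set_enrichment <- function(mlm_table, annotation, gene_set, universe = NULL,
                           n_perm = 10000, seed = 1, set_name = "set") {
  tested <- mlm_table[!mlm_table$skipped & !is.na(mlm_table$p_value), ,
                      drop = FALSE]
  pmap <- stats::setNames(tested$p_value, tested$marker_id)
  genes <- assign_snps_to_genes(annotation, names(pmap))
  min_p <- vapply(genes, function(mk) min(pmap[mk]), 0.0)
  if (is.null(universe)) universe <- names(min_p)
  universe <- intersect(universe, names(min_p))
  members <- intersect(unique(gene_set), universe)
  if (length(members) == 0)
    stop("gene set has no overlap with the tested universe")
  observed <- mean(min_p[members])
  m <- length(members)
  set.seed(seed)
  null_means <- vapply(seq_len(n_perm), function(i)
    mean(min_p[sample(universe, m)]), 0.0)
  structure(list(set_name = set_name,
                 n_genes_tested = m,
                 observed_mean_min_p = observed,
                 null_mean = mean(null_means),
                 null_sd = stats::sd(null_means),
                 n_permutations = n_perm,
                 empirical_p = mean(null_means <= observed),
                 gene_min_p = min_p[members]),
            class = "set_enrichment_result")
}

#' @export
print.set_enrichment_result <- function(x, ...) {
  cat(sprintf("gene-set enrichment '%s': %d genes tested\n", x$set_name,
              x$n_genes_tested))
  cat(sprintf("  observed mean min-p %.4f vs null %.4f (sd %.4f), empirical p = %s\n",
              x$observed_mean_min_p, x$null_mean, x$null_sd,
              if (x$empirical_p == 0) sprintf("< %g", 1 / x$n_permutations)
              else format(x$empirical_p)))
  invisible(x)
}
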