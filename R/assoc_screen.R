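#' Stage-1 lineage-level association test for one marker
#'
#' The fast prescreen: an ordinary linear model of a per-lineage summary
#' phenotype on the major/minor allele class, with additive correction for
#' Wolbachia status, inversion genotypes, and relatedness principal
#' components. With no covariates and balanced classes this is exactly the
#' pooled two-sample t-test. Markers with fewer than `min_minor_lineages`
#' lines in either allele class (after dropping missing calls) are skipped.
#'
#' @param panel a [panel_genotypes].
#' @param covariates `lineage_covariates` data.frame or NULL.
#' @param phenotype named numeric vector of per-lineage values (names are
#'   lineage ids) or an unnamed vector aligned to the panel's lineages.
#' @param marker_id marker to test.
#' @param min_minor_lineages minimum lineages per allele class.
#' @return one-row data.frame (`AssocResult`): `marker_id`,
#'   `phenotype_name`, `stage`, `target_term`, `effect` (minor minus major,
#'   log units), `se`, `p_value`, `n_lineages_used`, `skipped`, `reason`.
#' @export
screen_marker <- function(panel, covariates, phenotype, marker_id,
                          min_minor_lineages = 4,
                          phenotype_name = "phenotype") {
  g <- panel$calls[, marker_id]
  if (is.null(names(phenotype))) names(phenotype) <- lineage_ids(panel)
  y <- phenotype[lineage_ids(panel)]
  ok <- !is.na(g) & !is.na(y)
  skip_row <- function(reason)
    data.frame(marker_id = marker_id, phenotype_name = phenotype_name,
               stage = "screen", target_term = "allele", effect = NA_real_,
               se = NA_real_, p_value = NA_real_, n_lineages_used = sum(ok),
               skipped = TRUE, reason = reason, stringsAsFactors = FALSE)
  if (min(sum(g[ok] == 2), sum(g[ok] == 0)) < min_minor_lineages)
    return(skip_row("low-MAF"))
  df <- data.frame(y = as.numeric(y[ok]), allele = g[ok] / 2)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv <- cv[match(lineage_ids(panel)[ok], cv$lineage_id),
             setdiff(names(cv), "lineage_id"), drop = FALSE]
    cv <- cv[, vapply(cv, function(x) stats::var(x, na.rm = TRUE) > 0, TRUE),
             drop = FALSE]
    df <- cbind(df, cv)
  }
  if (stats::var(df$y) == 0)
    return(data.frame(marker_id = marker_id, phenotype_name = phenotype_name,
                      stage = "screen", target_term = "allele", effect = 0,
                      se = NA_real_, p_value = 1, n_lineages_used = sum(ok),
                      skipped = FALSE, reason = "zero-variance",
                      stringsAsFactors = FALSE))
  fit <- stats::lm(y ~ ., data = df)
  co <- summary(fit)$coefficients
  if (!"allele" %in% rownames(co)) return(skip_row("aliased"))
  data.frame(marker_id = marker_id, phenotype_name = phenotype_name,
             stage = "screen", target_term = "allele",
             effect = co["allele", "Estimate"], se = co["allele", "Std. Error"],
             p_value = co["allele", "Pr(>|t|)"], n_lineages_used = sum(ok),
             skipped = FALSE, reason = "", stringsAsFactors = FALSE)
}

#' Screen every marker of a panel and rank by p-value
#'
#' Applies [screen_marker()] to all markers and returns the table ranked by
#' ascending p-value, ties broken deterministically by (chrom, pos).
#' Skipped markers (low MAF, aliased) sort to the bottom with missing p.
#'
#' @inheritParams screen_marker
#' @return ranked AssocResult data.frame with a `rank` column (NA for
#'   skipped markers).
#' @export
screen_all <- function(panel, covariates, phenotype, min_minor_lineages = 4,
                       phenotype_name = "phenotype") {
  rows <- lapply(panel$marker_id, function(m)
    screen_marker(panel, covariates, phenotype, m, min_minor_lineages,
                  phenotype_name))
  tab <- do.call(rbind, rows)
  tab$chrom <- panel$chrom[match(tab$marker_id, panel$marker_id)]
  tab$pos <- panel$pos[match(tab$marker_id, panel$marker_id)]
  ord <- order(tab$p_value, tab$chrom, tab$pos, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- NA_integer_
  tested <- !tab$skipped
  tab$rank[tested] <- seq_len(sum(tested))
  rownames(tab) <- NULL
  tab
}

#' Union of the top-k markers across phenotype screens
#'
#' Takes the `k` lowest-p markers from each ranked screen table and returns
#' the union (phenotypes sharing hits shrink the union below `k` per
#' table). Markers tied with the k-th p-value are all included.
#'
#' @param tables a ranked screen table or a list of them (one per
#'   phenotype), as returned by [screen_all()].
#' @param k markers retained per table.
#' @return character vector of marker ids (the prescreen set), with
#'   attribute `per_table` giving each table's contribution size.
#' @export
select_top <- function(tables, k = 10000) {
  if (is.data.frame(tables)) tables <- list(tables)
  picks <- lapply(tables, function(tab) {
    tab <- tab[!tab$skipped & !is.na(tab$p_value), , drop = FALSE]
    if (k > nrow(tab)) stop("k exceeds the number of tested markers")
    cut <- sort(tab$p_value)[k]
    tab$marker_id[tab$p_value <= cut]
  })
  out <- unique(unlist(picks))
  attr(out, "per_table") <- lengths(picks)
  out
}
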