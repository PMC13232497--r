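#' Panel genotype container
#'
#' A `panel_genotypes` object holds the lineage-by-marker genotype matrix of
#' an isogenic panel together with marker metadata. Lines are fully
#' homozygous, so calls are coded 0 (homozygous major allele) or 2
#' (homozygous minor allele); heterozygotes do not occur. The minor-allele
#' frequency (`maf`) is the frequency of the minor homozygous line class,
#' computed over non-missing lineages, and is bounded by 0.5.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom chromosome label per marker.
#' @param pos 1-based physical position (bp); strictly increasing within a
#'   chromosome.
#' @param major,minor single-character nucleotide labels per marker.
#' @param calls numeric lineage x marker matrix with entries in \{0, 2, NA\};
#'   row names are lineage ids, column names marker ids.
#'
#' @return An object of class `panel_genotypes`: a list with elements
#'   `marker_id`, `chrom`, `pos`, `major`, `minor`, `calls`, `maf`.
#' @export
panel_genotypes <- function(marker_id, chrom, pos, major, minor, calls) {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id)) stop("duplicate marker ids")
  n_mrk <- length(marker_id)
  stopifnot(length(chrom) == n_mrk, length(pos) == n_mrk,
            length(major) == n_mrk, length(minor) == n_mrk)
  calls <- as.matrix(calls)
  if (ncol(calls) != n_mrk) stop("calls must have one column per marker")
  bad <- !(calls %in% c(0, 2) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 2 or NA (isogenic lines carry no heterozygotes)")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(calls) <- marker_id
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("line_%03d", seq_len(nrow(calls)))
  obj <- structure(list(marker_id = marker_id,
                        chrom = as.character(chrom),
                        pos = as.integer(pos),
                        major = as.character(major),
                        minor = as.character(minor),
                        calls = calls,
                        maf = compute_maf(calls)),
                   class = "panel_genotypes")
  obj
}

#' Minor-lineage frequency per marker
#'
#' Frequency of the minor homozygous class among non-missing lineages.
#' Markers whose 0/2 orientation is inverted (coded class 2 more frequent
#' than class 0) report `maf` as the rarer class all the same, so callers
#' should normalize orientation first (see [read_genotypes()]).
#'
#' @param calls lineage x marker matrix in \{0, 2, NA\}.
#' @return numeric vector in \[0, 0.5\] (NaN for all-missing columns).
#' @export
compute_maf <- function(calls) {
  f2 <- colMeans(calls == 2, na.rm = TRUE)
  pmin(f2, 1 - f2)
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat(sprintf("panel_genotypes: %d lineages x %d markers (%d chromosome%s)\n",
              nrow(x$calls), length(x$marker_id), length(unique(x$chrom)),
              if (length(unique(x$chrom)) > 1) "s" else ""))
  cat(sprintf("  maf range [%.3f, %.3f]; missing calls: %.2f%%\n",
              min(x$maf, na.rm = TRUE), max(x$maf, na.rm = TRUE),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
`[.panel_genotypes` <- function(x, markers) {
  if (is.character(markers)) markers <- match(markers, x$marker_id)
  panel_genotypes(x$marker_id[markers], x$chrom[markers], x$pos[markers],
                  x$major[markers], x$minor[markers],
                  x$calls[, markers, drop = FALSE])
}

n_lineages <- function(panel) nrow(panel$calls)
lineage_ids <- function(panel) rownames(panel$calls)
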