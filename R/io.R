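#' @title Plain-text interchange formats
#' @description
#' All tables are UTF-8, tab-delimited, `NA` for missing, positions 1-based.
#' Metadata (seeds, thresholds, the log base of the size column) travels in
#' leading `# key=value` comment lines so every output is self-describing.
#' @name io-formats
#' @keywords internal
NULL

fmt_num <- function(x) {
  # 12 significant digits; enough for lossless float round-trips at the
  # precision the fixtures contract
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_meta <- function(path, colClasses = NA) {
  lines <- readLines(path, encoding = "UTF-8")
  metalines <- grep("^#", lines)
  meta <- list()
  if (length(metalines)) {
    kv <- sub("^#\\s*", "", lines[metalines])
    key <- sub("=.*$", "", kv)
    meta <- as.list(sub("^[^=]*=", "", kv))
    names(meta) <- key
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), metalines)],
                          header = TRUE, sep = "\t", na.strings = "NA",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = colClasses)
  attr(df, "meta") <- meta
  df
}

#' Write / read a panel genotype table
#'
#' Columns: `marker_id`, `chrom`, `pos`, `major`, `minor`, then one column
#' per lineage with calls in \{0, 2, NA\}. On read, the minor-lineage
#' frequency is recomputed, and markers whose coded class 2 is in fact the
#' more frequent class are re-oriented (codes flipped, allele labels
#' swapped) so that code 2 always marks the minor class; re-oriented
#' markers are reported via the `flipped` attribute.
#'
#' @param panel a [panel_genotypes] object.
#' @param path file path.
#' @return `read_genotypes` returns a [panel_genotypes]; the character
#'   vector of re-oriented marker ids is attached as attribute `flipped`.
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(marker_id = panel$marker_id, chrom = panel$chrom,
                   pos = panel$pos, major = panel$major, minor = panel$minor,
                   t(panel$calls), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path, meta = c(format = "panel_genotypes", coding = "0=major,2=minor"))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_meta(path, colClasses = c(marker_id = "character",
                                           chrom = "character",
                                           major = "character",
                                           minor = "character"))
  need <- c("marker_id", "chrom", "pos", "major", "minor")
  if (!all(need %in% names(df)))
    stop("malformed genotype header: need columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker_id)) stop("duplicate marker ids in ", path)
  lin <- setdiff(names(df), need)
  calls <- t(as.matrix(df[lin]))
  storage.mode(calls) <- "double"
  colnames(calls) <- df$marker_id
  rownames(calls) <- lin
  # normalize orientation: code 2 must be the minor class
  f2 <- colMeans(calls == 2, na.rm = TRUE)
  flip <- which(!is.na(f2) & f2 > 0.5)
  major <- df$major; minor <- df$minor
  if (length(flip)) {
    calls[, flip] <- 2 - calls[, flip]
    tmp <- major[flip]; major[flip] <- minor[flip]; minor[flip] <- tmp
  }
  out <- panel_genotypes(df$marker_id, df$chrom, df$pos, major, minor, calls)
  attr(out, "flipped") <- df$marker_id[flip]
  out
}

#' Import panel genotypes from a VCF
#'
#' Reads a VCF of fully homozygous diploid calls: `0/0` maps to 0, `1/1`
#' to 2, missing to NA. Heterozygous or multiallelic records violate the
#' isogenic-panel contract and are dropped with a count (attribute
#' `rejected`). Requires the `vcfR` package.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [panel_genotypes] with attribute `rejected` (number of
#'   excluded records).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[] <- gsub("\\|", "/", gt)
  multi <- grepl(",", fix[, "ALT"])
  het <- apply(gt, 1, function(r) any(!is.na(r) & !r %in% c("0/0", "1/1", "./.")))
  keep <- !multi & !het
  n_rej <- sum(!keep)
  if (!any(keep)) stop("no biallelic homozygous records in ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  calls <- matrix(NA_real_, ncol(gt), nrow(gt))
  calls[t(gt) == "0/0"] <- 0
  calls[t(gt) == "1/1"] <- 2
  rownames(calls) <- colnames(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  colnames(calls) <- ids
  # orient so code 2 is the minor class
  f2 <- colMeans(calls == 2, na.rm = TRUE)
  flip <- which(!is.na(f2) & f2 > 0.5)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  if (length(flip)) {
    calls[, flip] <- 2 - calls[, flip]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  }
  out <- panel_genotypes(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                         ref, alt, calls)
  attr(out, "rejected") <- n_rej
  attr(out, "flipped") <- ids[flip]
  out
}

#' Write / read lineage covariates
#' @param covariates `lineage_covariates` data.frame.
#' @param path file path.
#' @export
write_covariates <- function(covariates, path) {
  write_tsv_meta(as.data.frame(covariates), path, meta = c(format = "lineage_covariates"))
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- read_tsv_meta(path)
  if (!"lineage_id" %in% names(df)) stop("covariate table needs a lineage_id column")
  df$lineage_id <- as.character(df$lineage_id)
  class(df) <- c("lineage_covariates", "data.frame")
  df
}

#' Write / read individual size records
#'
#' Columns `lineage_id`, `sex` (F/M), `diet` (fed/starved), `block`,
#' `size` (log scale; the log base is recorded as metadata, natural log
#' for everything this package writes).
#' @param records SizeRecord data.frame.
#' @param path file path.
#' @export
write_individuals <- function(records, path) {
  write_tsv_meta(records, path,
                 meta = c(format = "size_records", size_scale = "log_natural"))
}

#' @rdname write_individuals
#' @export
read_individuals <- function(path) {
  df <- read_tsv_meta(path, colClasses = c(lineage_id = "character",
                                           sex = "character",
                                           diet = "character",
                                           block = "character"))
  need <- c("lineage_id", "sex", "diet", "block", "size")
  if (!all(need %in% names(df)))
    stop("individuals table needs columns ", paste(need, collapse = ", "))
  stopifnot(all(df$sex %in% c("F", "M")), all(df$diet %in% c("fed", "starved")),
            all(is.finite(df$size)))
  df$lineage_id <- as.character(df$lineage_id)
  df$block <- as.character(df$block)
  df
}

#' Write / read the generative truth of a simulation
#' @param truth a [sim_truth] object.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(fixed = as.list(truth$fixed),
                            planted = truth$planted,
                            varcomp = as.list(truth$varcomp),
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- x$planted
  if (is.null(planted) || length(planted) == 0)
    planted <- NULL
  sim_truth(fixed = unlist(x$fixed), planted = planted,
            varcomp = unlist(x$varcomp), seed = x$seed)
}

#' Read a marker-to-gene annotation table
#'
#' Expected columns: `marker_id`, `gene_id` (or `"intergenic"`),
#' `site_class`, `distance` (bp to the gene for markers outside it; 0
#' within). Gene-assigned markers outside the gene body must lie within
#' 2 kb, mirroring the +-2 kb assignment window of DGRP-style annotation
#' files.
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_meta(path)
  need <- c("marker_id", "gene_id", "site_class", "distance")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns ", paste(need, collapse = ", "))
  genic <- df$gene_id != "intergenic" & !is.na(df$gene_id)
  bad <- genic & !is.na(df$distance) & df$distance > 2000
  if (any(bad))
    stop(sum(bad), " gene-assigned marker(s) farther than 2 kb from the gene")
  df
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_meta(annotation, path, meta = c(format = "marker_annotation", window_bp = 2000))
}

#' Read gene sets (one set per line: name TAB gene ids)
#' @param path text file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) unique(p[-1])),
                  vapply(parts, `[[`, "", 1))
}

#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Write a provenance record for a pipeline run
#'
#' Captures configuration, seeds, package version, and per-stage counts so
#' any output table can be regenerated from the record alone.
#' @param path JSON path.
#' @param config named list of parameters (must include every seed used).
#' @param counts named list of per-stage input/output counts.
#' @export
write_provenance <- function(path, config, counts = list()) {
  jsonlite::write_json(list(
    package = "privqtl",
    version = as.character(utils::packageVersion("privqtl")),
    r_version = as.character(getRversion()),
    config = config, counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an association / result table with metadata header
#' @param df result data.frame.
#' @param path TSV path.
#' @param meta named character vector of `# key=value` metadata.
#' @export
write_result_table <- function(df, path, meta = NULL) {
  write_tsv_meta(df, path, meta = meta)
}
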