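#' Build the per-phenotype mixed-model specification
#'
#' Each hierarchical phenotype is mapped to the mixed linear model whose
#' genotype-interaction term carries it: single-sex/diet body size tests the
#' genotype main effect on that stratum; sex-averaged size adds a sex term;
#' SSD (per diet) tests the sex-by-genotype interaction with a random sex
#' slope; per-sex plasticity tests diet-by-genotype with a random diet
#' slope; sex-averaged plasticity tests diet-by-genotype in the full
#' two-factor model; and SSP tests the three-way sex-by-diet-by-genotype
#' interaction in the full model with lineage random intercept and random
#' sex, diet, and sex-by-diet slopes.
#'
#' @param phenotype_name one of `size_female_fed`, `size_male_fed`,
#'   `size_female_starved`, `size_male_starved`, `size_fed`, `size_starved`,
#'   `ssd_fed`, `ssd_starved`, `plasticity_female`, `plasticity_male`,
#'   `plasticity`, `ssp` (case-insensitive).
#' @return list of class `mlm_spec`: `phenotype_name`, `subset` (sex/diet
#'   restriction), `fixed` (term strings over `s`, `d`, `g2`), `random`
#'   (subset of intercept/sex/diet/sex_diet), `target` term.
#' @export
build_spec <- function(phenotype_name) {
  key <- tolower(phenotype_name)
  specs <- list(
    size_female_fed     = list(subset = list(sex = "F", diet = "fed"),
                               fixed = "g2", random = "intercept", target = "g2"),
    size_male_fed       = list(subset = list(sex = "M", diet = "fed"),
                               fixed = "g2", random = "intercept", target = "g2"),
    size_female_starved = list(subset = list(sex = "F", diet = "starved"),
                               fixed = "g2", random = "intercept", target = "g2"),
    size_male_starved   = list(subset = list(sex = "M", diet = "starved"),
                               fixed = "g2", random = "intercept", target = "g2"),
    size_fed            = list(subset = list(diet = "fed"),
                               fixed = c("s", "g2"), random = "intercept",
                               target = "g2"),
    size_starved        = list(subset = list(diet = "starved"),
                               fixed = c("s", "g2"), random = "intercept",
                               target = "g2"),
    ssd_fed             = list(subset = list(diet = "fed"),
                               fixed = c("s", "g2", "s:g2"),
                               random = c("intercept", "sex"), target = "s:g2"),
    ssd_starved         = list(subset = list(diet = "starved"),
                               fixed = c("s", "g2", "s:g2"),
                               random = c("intercept", "sex"), target = "s:g2"),
    plasticity_female   = list(subset = list(sex = "F"),
                               fixed = c("d", "g2", "d:g2"),
                               random = c("intercept", "diet"), target = "d:g2"),
    plasticity_male     = list(subset = list(sex = "M"),
                               fixed = c("d", "g2", "d:g2"),
                               random = c("intercept", "diet"), target = "d:g2"),
    plasticity          = list(subset = list(),
                               fixed = c("s", "d", "s:d", "g2", "s:g2", "d:g2"),
                               random = c("intercept", "sex", "diet", "sex_diet"),
                               target = "d:g2"),
    ssp                 = list(subset = list(),
                               fixed = c("s", "d", "s:d", "g2", "s:g2", "d:g2", "s:d:g2"),
                               random = c("intercept", "sex", "diet", "sex_diet"),
                               target = "s:d:g2"))
  if (!key %in% names(specs))
    stop("unknown phenotype name '", phenotype_name, "'; known: ",
         paste(names(specs), collapse = ", "))
  structure(c(list(phenotype_name = key), specs[[key]]), class = "mlm_spec")
}

# subset records per spec and add contrast columns
prepare_mlm_data <- function(records, spec) {
  dat <- records
  if (!is.null(spec$subset$sex)) dat <- dat[dat$sex == spec$subset$sex, , drop = FALSE]
  if (!is.null(spec$subset$diet)) dat <- dat[dat$diet == spec$subset$diet, , drop = FALSE]
  dat$s <- sex_contrast(dat$sex)
  dat$d <- diet_contrast(dat$diet)
  dat$s_d <- dat$s * dat$d
  dat$lineage_id <- factor(dat$lineage_id)
  dat
}

random_formula <- function(random, structure) {
  slope_col <- c(sex = "s", diet = "d", sex_diet = "s_d")
  slopes <- slope_col[setdiff(random, "intercept")]
  switch(structure,
         intercept = "(1 | lineage_id)",
         diagonal = paste(c("(1 | lineage_id)",
                            sprintf("(0 + %s | lineage_id)", slopes)),
                          collapse = " + "),
         unstructured = if (length(slopes))
           sprintf("(1 + %s | lineage_id)", paste(slopes, collapse = " + "))
         else "(1 | lineage_id)",
         stop("unknown random-effect structure ", structure))
}

# Wald test of a fixed term in a merMod / lm: asymptotic normal reference
wald_term <- function(fit, term) {
  fe <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  vc <- as.matrix(stats::vcov(fit))
  nm <- match_term(names(fe), term)
  if (is.na(nm)) return(list(effect = NA_real_, se = NA_real_, p = NA_real_))
  est <- fe[[nm]]
  se <- sqrt(vc[nm, nm])
  list(effect = est, se = se, p = 2 * stats::pnorm(-abs(est / se)))
}

# coefficient names may permute interaction components and drop backticks;
# match on sorted, backtick-stripped parts
match_term <- function(coef_names, term) {
  parts <- function(x) sort(gsub("`", "", strsplit(x, ":")[[1]]))
  want <- parts(term)
  hit <- which(vapply(coef_names, function(nm) identical(parts(nm), want), TRUE))
  if (length(hit) != 1) return(NA_character_)
  coef_names[hit]
}

# quote non-syntactic variable names for use in formulas
bt <- function(nm) ifelse(make.names(nm) == nm, nm, paste0("`", nm, "`"))

#' Select Wolbachia / inversion / PC covariate terms for a phenotype model
#'
#' Substitutes each candidate covariate for the genotype term in the
#' phenotype's model, tests its interaction terms first (highest order
#' down) and its additive term last, dropping each if non-significant at
#' `alpha` (Wald test on the asymptotic normal reference). The retained
#' terms are then held fixed in every per-marker fit of that phenotype.
#' Covariates constant across lineages are excluded with a note.
#'
#' @param records block-residualized SizeRecords.
#' @param covariates `lineage_covariates` data.frame.
#' @param spec an [build_spec()] result.
#' @param alpha retention threshold.
#' @param re_structure random-effect structure for the selection fits.
#' @return character vector of retained covariate terms (e.g.
#'   `"wolbachia"`, `"s:PC1"`); attribute `excluded` lists constant
#'   covariates.
#' @export
select_covariates <- function(records, covariates, spec, alpha = 0.05,
                              re_structure = "diagonal") {
  dat0 <- prepare_mlm_data(records, spec)
  cv <- as.data.frame(covariates)
  cand <- setdiff(names(cv), "lineage_id")
  const <- cand[vapply(cand, function(nm)
    stats::var(cv[[nm]], na.rm = TRUE) == 0, TRUE)]
  cand <- setdiff(cand, const)
  re <- random_formula(spec$random, re_structure)
  retained <- character()
  for (nm in cand) {
    dat <- dat0
    dat[[nm]] <- cv[[nm]][match(as.character(dat$lineage_id), cv$lineage_id)]
    terms_cov <- sub("g2", bt(nm), spec$fixed[grepl("g2", spec$fixed)], fixed = TRUE)
    base <- setdiff(spec$fixed, spec$fixed[grepl("g2", spec$fixed)])
    ord <- lengths(strsplit(terms_cov, ":"))
    current <- terms_cov
    for (o in sort(unique(ord[ord > 1]), decreasing = TRUE)) {
      for (tm in terms_cov[ord == o]) {
        if (!tm %in% current) next
        fit <- fit_lmm(dat, c(base, current), re)
        if (is.null(fit)) { current <- setdiff(current, tm); next }
        p <- wald_term(fit, tm)$p
        if (is.na(p) || p >= alpha) current <- setdiff(current, tm)
      }
    }
    add <- terms_cov[ord == 1]
    if (length(setdiff(current, add)) == 0 && add %in% current) {
      fit <- fit_lmm(dat, c(base, current), re)
      p <- if (is.null(fit)) NA_real_ else wald_term(fit, add)$p
      if (is.na(p) || p >= alpha) current <- setdiff(current, add)
    }
    retained <- c(retained, current)
  }
  structure(retained, excluded = const)
}

fit_lmm <- function(dat, fixed_terms, re, start = NULL) {
  form <- stats::as.formula(paste("size ~", paste(c(fixed_terms, re), collapse = " + ")))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  tryCatch(suppressMessages(
    lme4::lmer(form, dat, REML = TRUE, control = ctrl, start = start)),
    error = function(e) NULL, warning = function(w) NULL)
}

#' Fit the per-marker mixed model and test the target term
#'
#' Fits the phenotype's mixed linear model on all individual records (minor
#' allele dose/2 as `g2`), lineages with missing calls excluded, and
#' reports the Wald test of the spec's target term on the log-size scale.
#' Monomorphic markers are skipped. On non-convergence the random-effect
#' structure is simplified down a ladder (unstructured -> diagonal ->
#' intercept-only, starting from `re_structure`) and the level actually
#' used is recorded.
#'
#' @param records block-residualized SizeRecords (any covariate columns
#'   named by `covariate_terms` must already be merged; see
#'   [merge_covariates()]).
#' @param calls named genotype vector (lineage id -> \{0, 2, NA\}) or a
#'   marker id looked up in `panel` by [mlm_scan()].
#' @param spec an [build_spec()] result.
#' @param covariate_terms retained covariate terms from
#'   [select_covariates()].
#' @param re_structure starting random-effect structure: `"diagonal"`
#'   (default; independent lineage intercept and slopes), `"unstructured"`,
#'   or `"intercept"`.
#' @param test `"wald"` (asymptotic z) or `"lrt"` (ML likelihood-ratio
#'   refit of the target term).
#' @param start optional `theta` warm start for the first ladder level.
#' @param marker_id label for the output row.
#' @return one-row AssocResult data.frame with `fallback` (ladder level
#'   used) and `test`; attribute `theta` carries the converged covariance
#'   parameters for warm-starting the next marker.
#' @export
fit_marker_mlm <- function(records, calls, spec, covariate_terms = character(),
                           re_structure = "diagonal", test = "wald",
                           start = NULL, marker_id = "marker") {
  dat <- prepare_mlm_data(records, spec)
  g <- calls[as.character(dat$lineage_id)]
  dat$g2 <- as.numeric(g) / 2
  dat <- dat[!is.na(dat$g2), , drop = FALSE]
  nl_used <- length(unique(dat$lineage_id[!is.na(dat$g2)]))
  row <- data.frame(marker_id = marker_id, phenotype_name = spec$phenotype_name,
                    stage = "mlm", target_term = spec$target,
                    effect = NA_real_, se = NA_real_, p_value = NA_real_,
                    n_lineages_used = nl_used, skipped = FALSE, reason = "",
                    fallback = "", test = test, stringsAsFactors = FALSE)
  if (length(unique(dat$g2)) < 2) {
    row$skipped <- TRUE; row$reason <- "monomorphic"
    return(row)
  }
  ladder <- c("unstructured", "diagonal", "intercept")
  ladder <- ladder[match(re_structure, ladder):length(ladder)]
  fixed <- c(spec$fixed, covariate_terms)
  fit <- NULL
  for (lv in ladder) {
    re <- random_formula(spec$random, lv)
    fit <- fit_lmm(dat, fixed, re, start = if (lv == re_structure) start else NULL)
    if (!is.null(fit)) { row$fallback <- lv; break }
  }
  if (is.null(fit)) {
    row$skipped <- TRUE; row$reason <- "non-convergence"
    return(row)
  }
  w <- wald_term(fit, spec$target)
  row$effect <- w$effect; row$se <- w$se
  if (test == "wald") {
    row$p_value <- w$p
  } else {
    reml0 <- stats::update(fit, REML = FALSE)
    drop_target <- setdiff(fixed, spec$target)
    re <- random_formula(spec$random, row$fallback)
    form0 <- stats::as.formula(paste("size ~", paste(c(drop_target, re), collapse = " + ")))
    reml1 <- suppressMessages(lme4::lmer(form0, dat, REML = FALSE,
                                         control = lme4::lmerControl(calc.derivs = FALSE,
                                                                     check.conv.singular = "ignore")))
    lrt <- 2 * (stats::logLik(reml0) - stats::logLik(reml1))
    row$p_value <- stats::pchisq(as.numeric(lrt), df = 1, lower.tail = FALSE)
  }
  attr(row, "theta") <- lme4::getME(fit, "theta")
  row
}

#' Merge lineage covariate columns onto individual records
#' @param records SizeRecords.
#' @param covariates `lineage_covariates` or NULL.
#' @return records with covariate columns joined by lineage id.
#' @export
merge_covariates <- function(records, covariates) {
  if (is.null(covariates)) return(records)
  cv <- as.data.frame(covariates)
  idx <- match(records$lineage_id, cv$lineage_id)
  for (nm in setdiff(names(cv), "lineage_id")) records[[nm]] <- cv[[nm]][idx]
  records
}

#' Mixed-model scan over a marker set
#'
#' Runs [fit_marker_mlm()] for each marker, warm-starting each fit from the
#' previous marker's converged covariance parameters (the variance
#' components barely move between markers, so this cuts optimizer work
#' substantially).
#'
#' @inheritParams fit_marker_mlm
#' @param panel a [panel_genotypes].
#' @param marker_ids markers to fit.
#' @return AssocResult data.frame, one row per marker.
#' @export
mlm_scan <- function(records, panel, marker_ids, spec,
                     covariate_terms = character(),
                     re_structure = "diagonal", test = "wald") {
  theta <- NULL
  rows <- vector("list", length(marker_ids))
  for (i in seq_along(marker_ids)) {
    m <- marker_ids[i]
    r <- fit_marker_mlm(records, panel$calls[, m], spec, covariate_terms,
                        re_structure, test, start = theta, marker_id = m)
    if (!is.null(attr(r, "theta")) && r$fallback == re_structure)
      theta <- attr(r, "theta")
    attr(r, "theta") <- NULL
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The two-step association scan for one phenotype
#'
#' Stage 1 screens every marker with the fast lineage-level test on each
#' supplied summary phenotype; the union of the top-`k` markers across
#' screens is carried to stage 2, where the phenotype's mixed linear model
#' is fitted per marker on the individual records (block effects are
#' removed by residualization first). Candidates are markers whose
#' target-term p-value falls below `threshold`.
#'
#' @param panel a [panel_genotypes].
#' @param covariates `lineage_covariates` or NULL.
#' @param records raw SizeRecords (block residualization is applied here).
#' @param phenotype_name phenotype for [build_spec()].
#' @param screen_phenotypes named list of per-lineage summary vectors to
#'   screen on (e.g. `list(ssp = ..., ssp_indep = ...)`).
#' @param k stage-1 markers retained per screen.
#' @param threshold candidate p-value threshold.
#' @param alpha_covariates retention threshold for [select_covariates()];
#'   set `select_covars = FALSE` to skip selection.
#' @inheritParams fit_marker_mlm
#' @return list of class `two_step_result`: `screen_tables`, `top_markers`,
#'   `covariate_terms`, `mlm_table`, `candidates`, `counts`.
#' @export
run_two_step <- function(panel, covariates, records, phenotype_name,
                         screen_phenotypes, k = 10000, threshold = 1e-5,
                         alpha_covariates = 0.05, min_minor_lineages = 4,
                         re_structure = "diagonal", test = "wald",
                         select_covars = !is.null(covariates)) {
  spec <- build_spec(phenotype_name)
  screen_tables <- lapply(names(screen_phenotypes), function(nm)
    screen_all(panel, covariates, screen_phenotypes[[nm]],
               min_minor_lineages, phenotype_name = nm))
  names(screen_tables) <- names(screen_phenotypes)
  top <- select_top(screen_tables, k)
  rec <- remove_block_effects(records)
  cov_terms <- character()
  if (select_covars && !is.null(covariates)) {
    cov_terms <- select_covariates(rec, covariates, spec, alpha_covariates,
                                   re_structure)
    rec <- merge_covariates(rec, covariates)
  }
  mlm <- mlm_scan(rec, panel, top, spec, cov_terms, re_structure, test)
  cand <- mlm$marker_id[!mlm$skipped & !is.na(mlm$p_value) &
                          mlm$p_value < threshold]
  structure(list(screen_tables = screen_tables,
                 top_markers = top,
                 covariate_terms = cov_terms,
                 mlm_table = mlm,
                 candidates = cand,
                 counts = list(n_markers = length(panel$marker_id),
                               n_top = length(top),
                               n_fitted = sum(!mlm$skipped),
                               n_candidates = length(cand),
                               k = k, threshold = threshold)),
            class = "two_step_result")
}

#' Cumulative hit curve of stage-2 hits over stage-1 rank
#'
#' Orders markers by their stage-1 rank and counts, cumulatively, how many
#' have a stage-2 p-value below `threshold`; the plateau rank (smallest
#' rank attaining the final count) shows how deep a prescreen must reach to
#' capture every hit.
#'
#' @param stage1_ranks named integer vector of stage-1 ranks per marker, or
#'   a [screen_all()] table.
#' @param mlm_pvalues named numeric vector of stage-2 p-values for the same
#'   markers.
#' @param threshold hit threshold.
#' @return list: `curve` (data.frame rank/marker_id/cum_hits, ordered by
#'   rank), `plateau_rank` (0 when there are no hits), `n_hits`.
#' @export
rank_accumulation <- function(stage1_ranks, mlm_pvalues, threshold = 1e-5) {
  if (is.data.frame(stage1_ranks))
    stage1_ranks <- stats::setNames(stage1_ranks$rank, stage1_ranks$marker_id)
  stage1_ranks <- stage1_ranks[!is.na(stage1_ranks)]
  common <- intersect(names(stage1_ranks), names(mlm_pvalues))
  if (length(common) != length(stage1_ranks))
    stop("stage-1 and stage-2 tables must cover the same markers")
  ord <- order(stage1_ranks[common])
  m <- common[ord]
  hit <- !is.na(mlm_pvalues[m]) & mlm_pvalues[m] < threshold
  cum <- cumsum(hit)
  plateau <- if (sum(hit) == 0) 0L else as.integer(stage1_ranks[m][max(which(hit))])
  list(curve = data.frame(rank = as.integer(stage1_ranks[m]), marker_id = m,
                          cum_hits = as.integer(cum), row.names = NULL),
       plateau_rank = plateau, n_hits = sum(hit))
}

#' Mixed-model scan of a random marker subset (negative control)
#'
#' Samples `k` markers without replacement from outside the prescreen set
#' and fits the stage-2 model on each — the control for prescreen
#' completeness: if the prescreen is adequate, the random remainder yields
#' no hits at the candidate threshold.
#'
#' @param panel a [panel_genotypes].
#' @param excluded marker ids to exclude (the prescreen top set).
#' @param k markers to sample.
#' @param records block-residualized SizeRecords (covariates merged if
#'   `covariate_terms` used).
#' @param spec an [build_spec()] result.
#' @param seed RNG seed for the draw.
#' @inheritParams fit_marker_mlm
#' @param threshold hit threshold for the summary.
#' @return AssocResult table with attribute `summary` (list: `min_p`,
#'   `n_hits`, `sampled`).
#' @export
random_control <- function(panel, excluded, k, records, spec,
                           covariate_terms = character(), seed = 1,
                           re_structure = "diagonal", threshold = 1e-5) {
  pool <- setdiff(panel$marker_id, excluded)
  if (length(pool) < k) stop("remaining pool (", length(pool),
                             ") smaller than k = ", k)
  set.seed(seed)
  picks <- sample(pool, k)
  tab <- mlm_scan(records, panel, picks, spec, covariate_terms, re_structure)
  p <- tab$p_value[!tab$skipped & !is.na(tab$p_value)]
  attr(tab, "summary") <- list(min_p = if (length(p)) min(p) else NA_real_,
                               n_hits = sum(p < threshold),
                               sampled = picks)
  tab
}
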