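#' Drop undersized lineage x sex x diet groups
#'
#' Removes every lineage-by-sex-by-diet group with fewer than `min_n` size
#' measurements, the standard guard against noisy lineage summaries in
#' panel phenotyping.
#'
#' @param records SizeRecord data.frame (`lineage_id`, `sex`, `diet`,
#'   `block`, `size`).
#' @param min_n minimum records per group; groups with `n < min_n` are
#'   dropped ("fewer than" semantics: a group of exactly `min_n` is kept).
#' @return list with `records` (the retained rows) and `drop_report`
#'   (data.frame of removed groups with their counts).
#' @export
filter_groups <- function(records, min_n = 10) {
  stopifnot(nrow(records) > 0)
  key <- interaction(records$lineage_id, records$sex, records$diet, drop = TRUE)
  n <- table(key)
  small <- names(n)[n < min_n]
  drop <- records[key %in% small, c("lineage_id", "sex", "diet")]
  drop_report <- unique(drop)
  if (nrow(drop_report)) {
    drop_report$n <- as.integer(n[match(
      interaction(drop_report$lineage_id, drop_report$sex, drop_report$diet),
      names(n))])
    rownames(drop_report) <- NULL
  } else {
    drop_report <- data.frame(lineage_id = character(), sex = character(),
                              diet = character(), n = integer())
  }
  kept <- records[!(key %in% small), , drop = FALSE]
  if (nrow(kept) == 0) warning("all groups dropped by the size filter")
  rownames(kept) <- NULL
  list(records = kept, drop_report = drop_report)
}

#' Remove block effects by residualizing size on block
#'
#' Regresses size on the block factor and replaces size with the
#' residuals. For a single categorical regressor this equals centering each
#' block at its own mean, so every per-block mean of the output is zero.
#' Used upstream of the association scans; BLUP estimation instead keeps
#' block as a random intercept.
#'
#' @param records SizeRecord data.frame with a `block` column.
#' @return the records with `size` replaced by block-centered residuals.
#' @export
remove_block_effects <- function(records) {
  stopifnot("block" %in% names(records))
  records$size <- records$size - stats::ave(records$size, records$block)
  records
}

sex_contrast <- function(sex) ifelse(sex == "F", 0.5, -0.5)
diet_contrast <- function(diet) ifelse(diet == "fed", 0.5, -0.5)

#' Lineage BLUPs of sex-specific size per diet stratum
#'
#' Fits, separately within the fed and the starved stratum, the mixed model
#' `size ~ sex + (1 + sex | lineage) + (1 | block)` by REML (sex as a
#' centered female = +1/2 contrast), and extracts the best linear unbiased
#' prediction of log size for each lineage x sex as fixed effects plus the
#' lineage's predicted random intercept and sex deviation. The lineage
#' intercept and sex slope are correlated (unstructured 2x2 covariance);
#' on non-convergence the stratum is refitted with independent
#' (diagonal) random effects, recorded in the diagnostics. Lineages
#' lacking a sex within a stratum get a missing BLUP for that cell.
#'
#' @param records SizeRecord data.frame (unresidualized; block enters the
#'   model as a random intercept where the stratum has >= 2 blocks).
#' @param random_slope if FALSE, drop the random sex slope and fit a pure
#'   random-intercept model (useful for shrinkage diagnostics).
#' @return data.frame of class `blup_estimates` with columns `lineage_id`,
#'   `b_female_fed`, `b_female_starved`, `b_male_fed`, `b_male_starved`;
#'   attributes `varcomp` (per-stratum variance components) and
#'   `diagnostics` (convergence and fallback per stratum).
#' @export
estimate_blups <- function(records, random_slope = TRUE) {
  stopifnot(length(unique(records$lineage_id)) >= 2,
            all(c("F", "M") %in% records$sex))
  lid <- sort(unique(records$lineage_id))
  out <- data.frame(lineage_id = lid, b_female_fed = NA_real_,
                    b_female_starved = NA_real_, b_male_fed = NA_real_,
                    b_male_starved = NA_real_, stringsAsFactors = FALSE)
  varcomp <- list(); diagnostics <- list()

  for (diet in c("fed", "starved")) {
    dat <- records[records$diet == diet, , drop = FALSE]
    if (nrow(dat) == 0) next
    dat$sex_c <- sex_contrast(dat$sex)
    dat$lineage_id <- factor(dat$lineage_id)
    has_block <- length(unique(dat$block)) >= 2
    re_lin <- if (random_slope) "(1 + sex_c | lineage_id)" else "(1 | lineage_id)"
    form <- stats::as.formula(paste("size ~ sex_c +", re_lin,
                                    if (has_block) "+ (1 | block)" else ""))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              optCtrl = list(xtol_rel = 1e-8, ftol_rel = 1e-8))
    fit <- tryCatch(lme4::lmer(form, dat, REML = TRUE, control = ctrl),
                    warning = function(w) w, error = function(e) e)
    fallback <- "none"
    if (inherits(fit, c("warning", "error")) && random_slope) {
      form2 <- stats::as.formula(paste(
        "size ~ sex_c + (1 | lineage_id) + (0 + sex_c | lineage_id)",
        if (has_block) "+ (1 | block)" else ""))
      fit <- tryCatch(suppressWarnings(
        lme4::lmer(form2, dat, REML = TRUE, control = ctrl)),
        error = function(e) e)
      fallback <- "diagonal"
    }
    if (inherits(fit, "error"))
      stop("BLUP model failed to converge in the ", diet, " stratum: ",
           conditionMessage(fit))
    if (inherits(fit, "warning")) {
      # warning but usable fit: refit suppressing to retrieve the object
      fit <- suppressWarnings(lme4::lmer(form, dat, REML = TRUE, control = ctrl))
      fallback <- "warned"
    }

    fe <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$lineage_id
    int <- re[["(Intercept)"]]
    slope <- if ("sex_c" %in% names(re)) re[["sex_c"]] else rep(0, nrow(re))
    names(int) <- names(slope) <- rownames(re)
    # diagonal fallback returns two ranef blocks with the same grouping name
    if (is.null(re[["sex_c"]]) && fallback == "diagonal") {
      reL <- lme4::ranef(fit)
      blocks <- which(names(reL) == "lineage_id")
      if (length(blocks) == 2) {
        int <- stats::setNames(reL[[blocks[1]]][["(Intercept)"]], rownames(reL[[blocks[1]]]))
        slope <- stats::setNames(reL[[blocks[2]]][["sex_c"]], rownames(reL[[blocks[2]]]))
      }
    }
    present <- unique(dat[c("lineage_id", "sex")])
    for (sx in c("F", "M")) {
      sc <- sex_contrast(sx)
      ids <- as.character(present$lineage_id[present$sex == sx])
      val <- fe[["(Intercept)"]] + fe[["sex_c"]] * sc +
        int[ids] + slope[ids] * sc
      col <- paste0("b_", if (sx == "F") "female" else "male", "_", diet)
      out[[col]][match(ids, out$lineage_id)] <- val
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp[[diet]] <- vc
    diagnostics[[diet]] <- list(fallback = fallback,
                                singular = lme4::isSingular(fit),
                                n_records = nrow(dat))
  }
  structure(out, varcomp = varcomp, diagnostics = diagnostics,
            class = c("blup_estimates", "data.frame"))
}

#' Derive the hierarchical size indices from lineage BLUPs
#'
#' From the four per-lineage BLUPs (female/male x fed/starved log size)
#' computes the full index hierarchy on the log scale:
#' sex-averaged size per diet, sexual size dimorphism per diet
#' (female minus male), nutritional plasticity per sex (fed minus starved),
#' sex-averaged plasticity, and sex-specific plasticity
#' `SSP = delta_female - delta_male`, which is algebraically identical to
#' `ssd_fed - ssd_starved`. Lineages missing any BLUP get missing indices
#' and are flagged `complete = FALSE`.
#'
#' @param blups a [estimate_blups] result (or any data.frame with the four
#'   `b_*` columns and `lineage_id`).
#' @return data.frame (`lineage_summary`) with all index columns.
#' @export
derive_indices <- function(blups) {
  b <- as.data.frame(blups)
  need <- c("b_female_fed", "b_female_starved", "b_male_fed", "b_male_starved")
  stopifnot(all(c("lineage_id", need) %in% names(b)))
  out <- b[c("lineage_id", need)]
  out$b_lineage_fed <- (b$b_female_fed + b$b_male_fed) / 2
  out$b_lineage_starved <- (b$b_female_starved + b$b_male_starved) / 2
  out$ssd_fed <- b$b_female_fed - b$b_male_fed
  out$ssd_starved <- b$b_female_starved - b$b_male_starved
  out$delta_female <- b$b_female_fed - b$b_female_starved
  out$delta_male <- b$b_male_fed - b$b_male_starved
  out$delta_lineage <- (out$delta_female + out$delta_male) / 2
  out$ssp <- out$delta_female - out$delta_male
  out$complete <- stats::complete.cases(b[need])
  class(out) <- c("lineage_summary", "data.frame")
  out
}

#' Plasticity indices independent of fed body size
#'
#' SSD and SSP both contain the fed BLUPs, so they are correlated with
#' plasticity by construction. This regresses, per sex, the starved BLUP
#' on the fed BLUP across lineages by ordinary least squares and takes the
#' residuals as an index of plasticity uncorrelated with fed size
#' (`delta_*_indep`); their difference is `ssp_indep`.
#'
#' @param summaries a [derive_indices] result (needs the four `b_*` columns).
#' @return `summaries` with `delta_female_indep`, `delta_male_indep`,
#'   `ssp_indep` appended.
#' @export
independent_plasticity <- function(summaries) {
  s <- summaries
  complete <- stats::complete.cases(
    s[c("b_female_fed", "b_female_starved", "b_male_fed", "b_male_starved")])
  if (sum(complete) < 3)
    stop("independent plasticity needs >= 3 lineages with complete BLUPs")
  s$delta_female_indep <- NA_real_
  s$delta_male_indep <- NA_real_
  for (sx in c("female", "male")) {
    fed <- s[[paste0("b_", sx, "_fed")]][complete]
    stv <- s[[paste0("b_", sx, "_starved")]][complete]
    fit <- stats::lm(stv ~ fed)
    s[[paste0("delta_", sx, "_indep")]][complete] <- stats::residuals(fit)
  }
  s$ssp_indep <- s$delta_female_indep - s$delta_male_indep
  s
}
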