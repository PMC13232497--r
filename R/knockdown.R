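#' Fit the full factorial knockdown model
#'
#' Validation crosses are analyzed with a fixed-effects factorial linear
#' model of log size on sex, diet, and fly type (experimental knockdown
#' vs control), with all two-way interactions and the three-way term.
#' All three factors enter as centered +-1/2 contrasts (female, fed,
#' experimental positive), so each coefficient is the corresponding
#' cell-mean contrast: the three-way term is the knockdown effect on
#' sex-specific plasticity, diet-by-type the effect on plasticity,
#' sex-by-type the effect on SSD, and the type main effect the effect on
#' body size. Each cross is a single genotype pair, so no random effects
#' enter; the fit is ordinary least squares.
#'
#' @param records data.frame with `sex` (F/M), `diet` (fed/starved),
#'   `fly_type` (experimental/control), `size` (log scale). All eight
#'   cells must be populated.
#' @return list of class `knockdown_fit`: `fit` (the lm), `terms`
#'   (data.frame term/estimate/se/p_value), `data`.
#' @export
fit_factorial <- function(records) {
  stopifnot(all(records$sex %in% c("F", "M")),
            all(records$diet %in% c("fed", "starved")),
            all(records$fly_type %in% c("experimental", "control")))
  cells <- table(records$sex, records$diet, records$fly_type)
  if (any(cells == 0)) {
    i <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: sex=%s diet=%s fly_type=%s",
                 dimnames(cells)[[1]][i[1]], dimnames(cells)[[2]][i[2]],
                 dimnames(cells)[[3]][i[3]]))
  }
  dat <- data.frame(size = records$size,
                    s = sex_contrast(records$sex),
                    d = diet_contrast(records$diet),
                    t = ifelse(records$fly_type == "experimental", 0.5, -0.5))
  fit <- stats::lm(size ~ s * d * t, data = dat)
  co <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(co)[-1],
                      estimate = co[-1, "Estimate"],
                      se = co[-1, "Std. Error"],
                      p_value = co[-1, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, terms = terms, data = dat),
            class = "knockdown_fit")
}

kd_term_order <- function(term) lengths(strsplit(term, ":"))

kd_contains <- function(term, candidate) {
  # is `candidate` a lower-order component of `term`?
  all(strsplit(candidate, ":")[[1]] %in% strsplit(term, ":")[[1]])
}

#' Backward elimination and trait classification of a knockdown fit
#'
#' Starting from the full factorial fit, iteratively removes the least
#' significant non-significant interaction of the currently highest order
#' and refits, never removing a term contained in a retained higher-order
#' term (marginality) and never removing the sex or diet main effects
#' (every cross shows sex and diet effects on size independent of type).
#' The retained type-involving terms classify what the knockdown affects:
#' the three-way sex-by-diet-by-type term means SSP; otherwise
#' diet-by-type means plasticity and/or sex-by-type means SSD; otherwise a
#' significant type main effect means body size; nothing retained means no
#' detectable effect.
#'
#' @param fit a [fit_factorial()] result.
#' @param alpha significance threshold for retention.
#' @param gene label carried into the result.
#' @return list of class `knockdown_result`: `gene`, `path` (data.frame of
#'   removed terms with the p-value at removal), `final_terms`, `full_p`
#'   (per-term p of the full fit), `classification` (subset of
#'   \{"SSP","plasticity","SSD","size","none"\}).
#' @export
backward_reduce <- function(fit, alpha = 0.05, gene = "gene") {
  stopifnot(inherits(fit, "knockdown_fit"))
  dat <- fit$data
  all_terms <- c("s", "d", "t", "s:d", "s:t", "d:t", "s:d:t")
  protected <- c("s", "d")
  current <- all_terms
  path <- data.frame(term = character(), p_at_removal = numeric(),
                     stringsAsFactors = FALSE)
  term_p <- function(terms) {
    f <- stats::as.formula(paste("size ~", paste(terms, collapse = " + ")))
    m <- stats::lm(f, data = dat)
    co <- summary(m)$coefficients
    p <- stats::setNames(rep(NA_real_, length(terms)), terms)
    for (tm in terms) {
      nm <- match_term(rownames(co), tm)
      if (!is.na(nm)) p[tm] <- co[nm, "Pr(>|t|)"]
    }
    p
  }
  repeat {
    p <- term_p(current)
    removable <- setdiff(current, protected)
    removable <- removable[vapply(removable, function(tm)
      !any(vapply(setdiff(current, tm), kd_contains, TRUE, candidate = tm)),
      TRUE)]
    ns <- removable[!is.na(p[removable]) & p[removable] >= alpha]
    if (length(ns) == 0) break
    top_order <- max(kd_term_order(ns))
    cand <- ns[kd_term_order(ns) == top_order]
    drop_tm <- cand[order(-p[cand], cand)][1]
    path <- rbind(path, data.frame(term = drop_tm,
                                   p_at_removal = unname(p[drop_tm]),
                                   stringsAsFactors = FALSE))
    current <- setdiff(current, drop_tm)
  }
  final_p <- term_p(current)
  classification <- if ("s:d:t" %in% current) {
    "SSP"
  } else {
    cls <- c(if ("d:t" %in% current) "plasticity",
             if ("s:t" %in% current) "SSD")
    if (is.null(cls)) {
      if ("t" %in% current && !is.na(final_p["t"]) && final_p["t"] < alpha)
        "size" else "none"
    } else cls
  }
  structure(list(gene = gene, path = path, final_terms = current,
                 full_p = stats::setNames(fit$terms$p_value, fit$terms$term),
                 final_p = final_p,
                 classification = classification),
            class = "knockdown_result")
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat(sprintf("knockdown '%s': final model %s\n", x$gene,
              paste(x$final_terms, collapse = " + ")))
  cat("  classification:", paste(x$classification, collapse = " & "), "\n")
  invisible(x)
}

#' Simulate a knockdown validation experiment
#'
#' Generates balanced records for the eight sex x diet x type cells under
#' the factorial model with declared contrast-scale effects and Gaussian
#' noise — used to calibrate power and false-positive behaviour of the
#' classifier.
#'
#' @param effects named numeric of contrast-scale effects; any of
#'   `intercept`, `s`, `d`, `t`, `s:d`, `s:t`, `d:t`, `s:d:t` (missing
#'   entries are 0).
#' @param n_per_cell records per cell.
#' @param sd residual standard deviation (log units).
#' @param seed RNG seed.
#' @return KnockdownRecord data.frame.
#' @export
simulate_knockdown <- function(effects = c(intercept = 6, s = 0.1, d = 0.15),
                               n_per_cell = 30, sd = 0.1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(sex = c("F", "M"), diet = c("fed", "starved"),
                      fly_type = c("experimental", "control"),
                      rep = seq_len(n_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- sex_contrast(grid$sex)
  d <- diet_contrast(grid$diet)
  t <- ifelse(grid$fly_type == "experimental", 0.5, -0.5)
  eff <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  mu <- eff("intercept") + eff("s") * s + eff("d") * d + eff("t") * t +
    eff("s:d") * s * d + eff("s:t") * s * t + eff("d:t") * d * t +
    eff("s:d:t") * s * d * t
  data.frame(sex = grid$sex, diet = grid$diet, fly_type = grid$fly_type,
             size = mu + stats::rnorm(nrow(grid), 0, sd),
             stringsAsFactors = FALSE)
}
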