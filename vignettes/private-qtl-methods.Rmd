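---
title: "Dissecting hierarchical size traits in isogenic panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hierarchical size traits in isogenic panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Body size in *Drosophila* sits at the bottom of a hierarchy of derived
traits. Sexual size dimorphism (SSD) is the female-minus-male difference in
size; nutritional plasticity (Δ) is the fed-minus-starved difference within
a sex; and sex-specific plasticity (SSP) — the difference between female and
male plasticity — is algebraically identical to the change of SSD across
diets. A genetic variant can only move SSP by moving size in at least one
sex-by-diet context, so loci for the higher-order traits are necessarily
*context-dependent*: their allelic effects are confined to particular
sex/diet combinations ("private QTLs").

In a panel of fully homozygous, isogenic lineages, every lineage is one
fixed genotype that can be measured repeatedly in every context, which makes
these hierarchical contrasts estimable per genotype. `privqtl` implements
the full analysis chain for such panels — phenotype indices, a two-step
genome-wide association scan keyed to interaction terms, a gene-based
aggregation test with an LD-aware empirical null, permutation gene-set
enrichment, and the factorial analysis of RNAi knockdown validation crosses
— together with a synthetic-data generator that plants known
context-dependent effects so every stage can be calibrated end to end.

All sizes are analyzed on the natural-log scale (file metadata records
this), so effects are approximately proportional changes.

## Lineage phenotypes

Within each diet stratum we fit, by REML through `lme4`,

$$B_{jklm} = S_j + \lambda_l + \sigma_{l(j)} + \alpha_k + \varepsilon_{jklm},$$

with fixed sex ($S$, a centered female $= +1/2$ contrast), a random lineage
intercept $\lambda_l$, a correlated random lineage-specific sex deviation
$\sigma_{l(j)}$ (unstructured 2×2 covariance; an independent-components
fallback is applied on non-convergence and recorded in the diagnostics), and
a random block intercept $\alpha_k$. The best linear unbiased prediction
(BLUP) of log size for a lineage-by-sex cell is the fixed part plus the
lineage's predicted intercept and sex deviation. Fitting *per diet stratum*
is a design decision: the model carries no diet term, yet four quantities
per lineage ($\hat B_{\text{female/male} \times \text{fed/starved}}$) are
required downstream, and the per-stratum fit is the only reading consistent
with that. Blocks enter as they occur within the stratum.

From the four BLUPs the index hierarchy follows by arithmetic:
sex-averaged size; $\mathrm{SSD} = \hat B_{f} - \hat B_{m}$ per diet;
$\Delta = \hat B_{\text{fed}} - \hat B_{\text{starved}}$ per sex;
sex-averaged plasticity; and
$\mathrm{SSP} = \Delta_f - \Delta_m \equiv \mathrm{SSD}_{\text{fed}} -
\mathrm{SSD}_{\text{starved}}$. The identity is exact and is asserted to
1e-12 in the test suite. Because SSD and SSP share the fed BLUPs, we also
provide a de-confounded plasticity index: the OLS residual of the starved
BLUP regressed on the fed BLUP across lineages, per sex
(`independent_plasticity()`); the residuals are exactly orthogonal to fed
size by construction.

Before any index estimation, lineage-by-sex-by-diet groups with fewer than
ten measurements are dropped (`filter_groups()`, strict "fewer than"
semantics), the conventional guard against noisy lineage summaries.

## The two-step association scan

**Stage 1** (`screen_all()`) is a fast lineage-level screen: for each
marker, an ordinary linear model of the summary phenotype on the major vs
minor homozygous class, correcting additively for Wolbachia infection,
inversion genotypes, and the leading principal components of the genotype
matrix. With no covariates and balanced classes this is exactly the pooled
two-sample t-test (asserted in the tests). Markers with fewer than four
minor-class lineages are skipped — the panel convention for an effective
MAF floor; the count is configurable. The screen is cheap but
anticonservative: lineage summaries hide within-lineage measurement
uncertainty and unequal replication.

**Stage 2** (`mlm_scan()`) refits the union of the top-*k* stage-1 markers
(ties at the boundary included) with the full mixed linear model on every
individual record. For SSP the model is

$$B = S + D + G + S{\cdot}D + S{\cdot}G + D{\cdot}G + S{\cdot}G{\cdot}D +
\lambda_l + \sigma_{l} s + \delta_{l} d + \gamma_{l} sd + \varepsilon,$$

with the three-way fixed term as the target; SSD, plasticity, and plain
size phenotypes use the reduced forms returned by `build_spec()`, each with
the random slopes its strata support. Sex and diet are centered ±1/2
contrasts and genotype is minor-allele dose/2, so the target coefficient
*is* the cell-mean contrast it names (e.g. the three-way coefficient equals
the diet difference of the sex difference between minor- and major-allele
lineages). Block effects are removed beforehand by residualizing size on
the block factor — equivalent to per-block centering — while BLUP
estimation keeps block as a random intercept; the two stages deliberately
treat blocks differently, matching how each is used.

Numerical choices that matter at scale:

* **Random-effect structure.** Per-marker fits default to *independent*
  (diagonal) lineage intercept and slope components. Correlations among
  four lineage-level random terms are rarely estimable within a single
  marker refit and attempting them triples the cost of a scan; the
  unstructured covariance remains available (`re_structure =
  "unstructured"`). Non-convergence falls down the ladder unstructured →
  diagonal → intercept-only, and the level actually used is recorded per
  marker.
* **Warm starts.** Variance components barely move between markers, so each
  fit starts from the previous marker's converged covariance parameters.
* **Inference.** The target term is tested by a Wald z statistic on the
  asymptotic normal reference (a likelihood-ratio refit is available via
  `test = "lrt"`). With ~100 lineages the effective degrees of freedom for
  lineage-level contrasts are large enough that no small-sample correction
  is applied; the choice is recorded in each result row.
* **Covariates.** Each candidate covariate is substituted for genotype in
  the phenotype's model; its interaction terms are tested first (highest
  order down) and its additive term last, dropping non-significant terms at
  α = 0.05. Retained terms are then held fixed across all marker fits of
  that phenotype.

Candidates are markers with a target-term p below 1 × 10⁻⁵, the
conventional panel-GWAS threshold; no FDR layer is added on top.

**Validity diagnostics.** `rank_accumulation()` plots the cumulative count
of stage-2 hits against stage-1 rank; a plateau well inside *k* shows the
prescreen reached every hit. `random_control()` refits the stage-2 model on
markers sampled from *outside* the top set; an adequate prescreen yields no
hits there.

## Gene-based test

`run_vegas()` aggregates SNP-level evidence per gene: each stage-2 p-value
becomes the 1-df chi-square quantile at $1 - p$, the per-gene statistic is
the sum over its polymorphic SNPs, and the null distribution is simulated
by drawing multivariate-normal vectors with the gene's SNP correlation
matrix, squaring, and summing. The LD matrix is the Pearson correlation of
genotype columns (pairwise-complete over missing calls), repaired to
positive definiteness by flooring eigenvalues at 1e-8 and rescaling to unit
diagonal. Markers are assigned to genes through an annotation table;
markers more than 2 kb from any gene are excluded, and a marker annotated
to several genes counts in each.

Two conventions deserve note:

* **Tail direction.** The empirical p defaults to the *upper* tail — the
  proportion of simulated statistics at or above the observed sum — so that
  small gene-level p means strong aggregate association, consistent with
  the quantile transform (small SNP p → large chi-square) and with using a
  small candidate threshold. A literal lower-tail convention is available
  behind `tail = "lower"` for comparison, since the two readings are easy
  to conflate when a procedure is described in words.
* **Zero counts.** An empirical p of 0 is printed as `< 1/n_reps`; the
  add-one correction `(1 + count)/(1 + n_reps)` is off by default so that
  the reported value is literally a proportion of replicates.

The identity-LD case is the module's principal oracle: with uncorrelated
SNPs the statistic is exactly $\chi^2_k$, and the empirical p must match the
analytic survival function within Monte-Carlo error — the acceptance suite
checks this over a grid of $k$ and tail probabilities, plus the single-SNP
round trip $p \to \chi^2_1(1-p) \to p$.

## Gene-set enrichment

`set_enrichment()` implements the permutation test on per-gene minimum
p-values: each gene in the tested universe (genes with at least one tested
SNP) is summarized by the smallest stage-2 p among its SNPs; the set
statistic is the mean of these minima over the set members present in the
universe; and the null re-draws the same number of genes from the universe
10,000 times (configurable). The one-sided empirical p is the proportion of
null means at or below the observed mean. The null samples *genes*, not
SNP-count-matched sets — per-gene minima already condition on each gene's
own SNP content, and gene sampling is the direct reading of a
"randomly sampled the same number of genes" design. On a small universe the
permutation p converges to the exhaustive enumeration over subsets, which
the acceptance suite verifies on a 4-gene universe (exact p = 1/6).

## Knockdown validation analysis

A validation cross compares experimental (RNAi knockdown) against control
flies over the sex × diet factorial:

$$B = S + D + T + S{\cdot}D + S{\cdot}T + D{\cdot}T + S{\cdot}D{\cdot}T +
\varepsilon,$$

fitted by OLS (a single cross has no lineage structure), all factors as
centered ±1/2 contrasts. `backward_reduce()` removes, iteratively, the
least-significant non-significant interaction of the currently highest
order, refitting each time, never violating marginality and never removing
the sex or diet main effects (every cross shows sex and diet effects on
size regardless of knockdown). Ties in "least significant" break toward
higher order, then lexicographically. The retained type-involving terms
classify the knockdown: the three-way term means the gene affects SSP;
otherwise diet-by-type means plasticity and/or sex-by-type means SSD;
otherwise a significant type main effect means body size; nothing retained
means no detectable effect. At α = 0.05 a spurious higher-order term
survives in roughly 5% of null crosses — the calibration suite checks both
this false-positive rate and ≥ 80% detection of a three-way effect at three
standard errors.

## The synthetic-data generator

The generator is first-class, tested code — the pipeline's testability
rests on it.

* **Genotypes** (`simulate_panel()`): homozygous 0/2 calls for 100–200
  lineages in LD blocks. Within a block, a Gaussian copula with a
  first-order autoregressive latent structure is thresholded at the
  empirical minor-frequency quantile; the latent correlation is calibrated
  through the bivariate-normal orthant probability so the *emitted
  genotypes* attain the requested correlation (defaults: blocks of 5,
  adjacent-pair correlation 0.8). One minor-allele frequency is drawn per
  block — with unequal frequencies a high binary correlation is not even
  attainable, so sharing the frequency inside a block is what makes the
  target well-posed. Missing calls are completely at random; downstream
  stages drop missing lineages per marker.
* **Covariates** (`simulate_covariates()`): Bernoulli Wolbachia status,
  inversion genotypes from the catalogue of common cosmopolitan inversions,
  and the leading principal components of the centered (mean-imputed)
  genotype matrix.
* **Phenotypes** (`simulate_individuals()`): the generative mirror of the
  stage-2 model — fixed sex/diet/sex-by-diet effects, independent lineage
  random intercept and sex/diet/sex-by-diet slopes, a block intercept, and
  Gaussian residuals. Planted marker effects are declared on the contrast
  scale (`sim_truth()`): class `G` shifts carriers' mean size, `GxD` their
  diet contrast, `GxS` their sex contrast, `GxSxD` their sex-by-diet
  contrast — each leaving the other contrasts untouched, which is exactly
  the private-QTL structure. In the noise-free limit every planted
  coefficient equals its cell-mean contrast to machine precision (tested).

Default parameters were fixed once, on realism grounds, and are the
conditions under which the calibration suite runs: within-line residual SD
0.1 log units (typical for repeated pupal-size measures), lineage intercept
SD 0.06, sex slope SD 0.02, diet slope SD 0.03, sex-by-diet slope SD 0.015
(the higher-order genetic variation is the smallest component of the
hierarchy), block SD 0.02; fixed effects: sex contrast +0.10
(females larger), diet contrast +0.15 (fed larger), sex-by-diet +0.05
(female-biased plasticity). The panel's LD structure and variance
magnitudes are plausible stand-ins, not estimates from any particular data
set.

What the generator does *not* emulate — and hence what passing tests do not
certify about real data: genotype coding is strictly biallelic and
homozygous (no residual heterozygosity), LD is block-local with no
long-range structure or recombination map, covariates are independent of
the phenotype unless planted, missingness is uninformative, and residuals
are Gaussian with equal variance across cells. Real panels violate most of
these mildly; the scan's robustness to such violations is untested here.

## Problem sizes and calibration results

The test suite runs the heavy calibrations at the following sizes, chosen
to bound the whole suite at desk scale: type-I calibration of the
three-way test on a null panel of 100 lineages × 400 independent markers
with 10 records per cell; effect recovery over 50 replicate experiments of
100 lineages × 20 per cell; prescreen completeness on a 5,000-marker panel
of 80 lineages × 4 per cell with 10 planted markers against a top-500
prescreen; gene-level oracles at 10⁵ Monte-Carlo replicates; enrichment
calibration over 200 random sets at 2,000 permutations; knockdown power
and size over 200 simulated crosses.

One calibration nuance is worth recording. The type-I check compares the
fraction of null markers with p < 0.05 against the 95% binomial band for
400 independent draws. All 400 markers are, however, tested against the
*same* realized phenotype vector: conditional on a panel whose realized
lineage contrasts are atypically small or large, every marker's test is
conservative or liberal together, so the fraction has extra-binomial
dispersion across panel realizations. Together with the mild conservatism
of Wald tests built on zero-truncated REML variance components (across
several independent panels we observe fractions in the 0.03–0.06 range,
averaging slightly below 0.05), a single-panel draw can fall just outside
the binomial band without any miscalibration of the test itself. The
distribution-level check (Kolmogorov–Smirnov distance to uniform < 0.1) is
the more stable diagnostic.

## Limitations

* Wald z inference on REML fits is asymptotic in the number of lineages;
  below ~50 lineages a finite-sample reference would be preferable.
* The stage-1 screen's covariate correction is additive only; covariate
  interactions are handled at stage 2.
* The VEGAS null is simulated per gene; resolving p-values near 10⁻⁵
  honestly requires 10⁶ replicates per gene (the default), which is the
  dominant cost of a full gene scan.
* Backward elimination tests each term once per reduction step; its
  classification is a label, not a controlled multiple-testing procedure
  across genes.
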