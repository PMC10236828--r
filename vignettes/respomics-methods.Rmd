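---
title: "Models and methods in respomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in respomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`respomics` is a pipeline for relating genetic and epigenetic risk to
antipsychotic treatment response in schizophrenia trials. This vignette
documents the statistical models, the tunable parameters and their
defaults, the synthetic-cohort generator, and the design choices made where
the methodology left the design open. It states no empirical claim that the
package's tests and acceptance script do not themselves compute.

## The outcome model

The primary endpoint is the PANSS reduction rate. Because the PANSS total
has a floor of 30 (every item scored 1), the attainable improvement from a
baseline $b$ is $b - 30$, and

$$\mathrm{rate} = \frac{b - e}{b - 30} \times 100,$$

with endpoint $e$. Responders (RES) have rate $\ge 50\%$; the boundary is
inclusive. For regression the rate is mapped to $[-1, 1]$ by the fixed
affine $\mathrm{clip}(\mathrm{rate}, -100, 100)/100$. We deliberately use a
fixed map rather than per-cohort min–max scaling: per-cohort scaling leaks
evaluation-set statistics into the transform and makes predictions
non-comparable across cohorts. Whether negative rates should be clipped
before scaling is not externally specified; we clip at $-100$ (a patient
would have to double their attainable-range severity to hit it) and note
that no simulated or plausible clinical record approaches the bound.
Chlorpromazine-equivalent dose conversion is a pure table lookup
(`dose × multiplier`); the multipliers are study configuration, not package
constants.

## Risk scores

**PRS.** Standard clumping + thresholding: greedy clumping by ascending
GWAS p with defaults $r^2 = 0.1$ within 250 kb (common practice; the
methodology we follow does not fix them), then a score
$\sum_j G_{sj}\hat\beta_j$ over SNPs with $p \le$ each threshold in
$\{5\times10^{-8}, 10^{-6}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.5, 1\}$.
The best threshold maximizes the incremental association $R^2$ on top of
covariates — Nagelkerke pseudo-$R^2$ from a logistic fit for case–control
phenotypes, OLS $R^2$ otherwise. The permutation empirical P uses the
add-one rule $(1 + \#\{p_{\text{perm}} \le p_{\text{obs}}\})/(B+1)$,
permuting phenotype labels and re-running the whole threshold scan each
time, so it is never exactly zero. $B$ defaults to 1000 at desk scale (configurable to 10,000 for a
confirmatory run) and is set much lower inside simulation loops. Genotype PCs come from `prcomp` on standardized dosages, keeping the
smallest set explaining 95% of variance. Allele harmonization is by
sign-flip re-expression on the panel's effect allele, which makes scores
exactly invariant to swapping a weight file's alleles and negating its
weights; strand-ambiguous A/T and C/G SNPs are dropped by default.

**PMS.** The polymethylation score is a two-stage stack: per pathway, a
ridge-penalized logistic model (glmnet, $\alpha = 0$, $\lambda = 0.1$) on
the pathway's CpG M-values produces out-of-fold case probabilities averaged
over bootstrap refits; a probability forest on the pathway-score matrix
then produces the final out-of-fold PMS in $[0, 1]$. No sample is ever
scored by a model that saw it — the leak test duplicates a sample and
asserts its score is unmoved. The stage learners (penalized logistic +
ensemble of trees) are our concrete reading of the two-step
pathway-stacking scheme; both are pluggable. Bootstrap count defaults to 25 here (configurable to 1000) purely as a
compute-scale choice; the estimator is the same.

**Epigenetic clock.** A generic linear clock (intercept + per-CpG weights
on betas) with an optional inverse log-linear age transform (`adult-log`:
exponential below the adult threshold, linear above, threshold 20 years).
Age acceleration is the OLS residual of clock age on chronological age,
mean-zero by construction. We do not reproduce any specific published
clock's coefficients or its normalization; coefficients are an input table.

## Methylome association

All regressions use M-values $\log_2(\beta/(1-\beta))$ (betas clipped at
$\varepsilon = 10^{-6}$) for variance stabilization. Site-level tests are
OLS of M on the group indicator plus covariates, computed for all CpGs in
one vectorized pass and unit-checked against `lm()`; with no covariates the
statistic is exactly the equal-variance two-sample t.

DMRs use seed-and-extend: maximal runs of CpGs with $p <$ `seed_p` (0.05)
whose inter-CpG gaps are at most `max_gap_bp` (500), kept at
`min_cpgs` $\ge 3$. The region p combines signed z-scores by
Stouffer–Liptak under an exponential distance-decay correlation
$\rho_{ij} = \rho_0 e^{-d_{ij}/d_0}$ ($\rho_0 = 0.5$, $d_0 = 500$ bp, the
comb-p convention), and the Šidák-style correction uses
$n_\text{eff} = \lfloor n_\text{sites}/n_\text{region}\rfloor$. The
detection geometry is checked against a permutation oracle (same algorithm
on position-permuted maps) under the null. The DMR algorithm itself is a package design choice,
fully parameterized and documented.

The EWAS regresses the scaled reduction rate on each CpG's M-value plus
covariates via Frisch–Waugh residualization. "Genome-wide significant"
uses adjusted $p < 10^{-8}$; the adjustment is Benjamini–Hochberg by
default with Bonferroni behind a flag. A site-subset argument supports
running the scan over ASM-gene CpGs only as well as epigenome-wide.

## meQTL integration

The cis scan (window 1 Mb; trans off — no window was defined for it)
residualizes dosages and M-values on covariates once and forms per-pair OLS
statistics from cross-products; meQTLs are pairs with BH-adjusted
$p < 10^{-8}$. ASM genes are genes implicated jointly by meQTLs, risk-DMRs
and response-DMRs; because it is unstated whether the joint evidence must
coincide on a single CpG, both a gene-level mode (default, conditions may
be met by different CpGs) and a CpG-level mode are provided.

**Colocalization** uses per-SNP Wakefield approximate Bayes factors
$\sqrt{1-r}\,\exp(r z^2/2)$ with $r = W^2/(W^2 + \mathrm{se}^2)$ and
single-causal-variant configuration sums for H0–H4, all in log space;
priors default to $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (field
convention) and $W = 0.15$ for binary / $0.20$ for quantitative traits.
The implementation is verified against exhaustive configuration enumeration
to $10^{-9}$ on every test region.

**SMR/HEIDI.** At the top exposure SNP (instrument $p < 5\times10^{-8}$),
$\hat b_{xy} = \hat b_{\text{out}}/\hat b_{\text{exp}}$ and
$T_{\mathrm{SMR}} = z_\text{exp}^2 z_\text{out}^2 / (z_\text{exp}^2 +
z_\text{out}^2) \sim \chi^2_1$. HEIDI takes up to 20 SNPs in intermediate
LD with the top SNP ($0.05 < r^2 < 0.9$, exposure $p < 1.6\times10^{-3}$),
forms $d_i = \hat b_{xy}(i) - \hat b_{xy}(\text{top})$ with a delta-method
LD covariance (exposure and outcome treated as independent samples), and
refers $\sum_i d_i^2/\mathrm{var}(d_i)$ to a Satterthwaite-matched scaled
chi-square using the eigenvalues of the correlation of $d$. Fewer than 3
eligible SNPs leave the HEIDI p undefined (flagged). The instrument
threshold and SNP cap follow the established SMR methodology. PAI
(promoter-anchored chromatin interaction) strengths are consumed as an
input table of $-\log_{10}$ values — predicting them from epigenomic
tracks is out of scope — and compared by a two-tailed Wilcoxon rank-sum,
exact for combined $n \le 20$ without ties.

Candidate refinement takes the union of three routes with provenance:
COLOC (any region PP4 > 0.8), PAI (SMR p under 5% BH-FDR **and** HEIDI
p > 0.01 **and** a significant strength comparison), and EWAS (genome-wide
CpG).

## Proxy methylation and response models

The preprocessor fits, on training data only, a rank-based inverse-normal
transform per feature, re-standardized by the training moments of the
mapped values so the training output is exactly mean 0 / SD 1; test values
pass through linear interpolation of the training empirical CDF with
boundary clamping. A rank-INT is our concrete choice for
"Gaussian-distributed mapping" — it is deterministic and leakage-safe.
Leak probes assert that perturbing test data changes nothing fitted.

Proxy models regress a CpG's M-value on its significant cis-meQTL dosages
(clumped at $r^2 = 0.8$ to drop duplicated columns) plus age and sex, with
quantile random forest (scored at the median), random forest, or a
polynomial-kernel SVM. Hyperparameters are tuned by random search
(default 25 draws; trees 100–1000, depth 2–20, min leaf 1–10, mtry
fraction 0.3–1; SVM C $10^{-2}$–$10^2$, degree 2–4, gamma
$10^{-3}$–$10^0$) over repeated k-fold CV by mean RMSE, falling back to
LOOCV under 30 training samples, then refit on all training data. We wrote
a compact tuner with exactly this scheme rather than delegating to a
generic training framework, for seed-stable determinism and speed inside
simulation loops. Selection applies the gate — held-out Pearson
p ≤ 0.05 — keeping the highest-r selected model per CpG; the gate's
type-I rate is verified ≈ 5% over null CpGs. Response models use the same
machinery with a radial-basis SVM replacing the polynomial one, regress the
scaled rate, and reuse the continuous prediction as the ROC score, so one fit per pattern
serves both the regression and classification readings (a separate
classifier mode is a flag, deliberately out of the default path). AUC CIs are
DeLong (deterministic, cross-checked against pROC); MAPE excludes targets
with $|y| < 10^{-8}$, with the exclusion count reported — MAPE values
above 1 simply reflect near-zero targets, which the metric handles poorly.
For decision curves, scaled predictions map to $[0,1]$ scores by the
invertible $(s+1)/2$.

## The synthetic cohort generator

The generator's defaults are the study conditions, fixed once:

* **Genotypes:** haplotypes from block-correlated latent Gaussians
  (compound symmetry $\rho$ within blocks, default 0.8, block size 10)
  thresholded at MAF-matched quantiles, summed over two haplotypes; MAF
  uniform on $[0.05, 0.5]$. SNPs sit on one chromosome at 5 kb spacing.
* **Methylome:** $M = \mu + \beta_{\text{meQTL}} G + \gamma_a\,\text{age} +
  \gamma_s\,\text{sex} + N(0, \sigma_m^2)$ with $\sigma_m = 0.6$,
  $\beta_{\text{meQTL}} = 1.0$ on 30 planted cis pairs by default; betas
  are the inverse logit, hence in $(0,1)$.
* **Case–control:** liability $= \sum w G + \sum v M + N(0,1)$; the top
  fraction matching the case:control ratio are cases.
* **Trial outcomes:** baselines $\mathrm{round}(N(90, 15^2))$ truncated at
  61 (inclusion requires PANSS > 60; acute-phase trial baselines
  typically average near 90 with SDs near 15). Cases are randomized
  uniformly over the seven APD arms, whose default mean reduction rates
  span the range seen across such arms (olanzapine 55.9, aripiprazole
  47.8, risperidone 55.3, quetiapine 48.2, haloperidol 53.4, ziprasidone
  46.6, perphenazine 49.2 percentage points). The generating rate adds a genetic
  burden term, a causal-CpG term (causal CpGs drawn among meQTL targets
  first — the mediation structure proxy imputation relies on), an age
  term, and $N(0, \sigma_r^2)$ with $\sigma_r = 18$ percentage points (total
  realized rate SDs then land in the low-to-mid 20s, typical of such
  trials); endpoints are back-computed and
  rounded, so recorded rates differ from generating rates only within the
  rounding bound $100/(2(b-30))$. Doses play no causal role in the
  generator, so the dose table exists only for the CPZ conversion
  utility.
* **Summary statistics:** analytic draws $\hat\beta \sim N(\beta, se^2)$,
  $se = 1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ (standardized-trait
  approximation), or a regression on a simulated reference population.

What the generator does **not** emulate: population stratification, batch
and probe-chemistry artifacts, cell-type composition, haplotype panels
with realistic recombination, and trans-meQTLs. Tests passing on this
generator therefore demonstrate estimator correctness and pipeline
integrity under the assumed generative model — not robustness to the
technical structure of real array data.

## External-validation experiment and problem sizes

`external_validation_experiment()` mirrors a discovery → external
validation design: one generative population, disjoint discovery
(n = 800) and validation (n = 400) samples, every trainable component
(PRS threshold, proxy models and their selection split, response models)
fitted on discovery data only, validation scored untouched. We treat
"independently drawn from the same population within one simulation run"
as the right notion of an external cohort here, because an independently
re-seeded run would re-draw the planted biology itself, which a real
validation cohort shares with discovery. The test suite and acceptance
script run 20 seeds of this experiment; simulation panels are 300 SNPs ×
150 CpGs with 20 planted meQTLs and 6 causal response CpGs, random-search
budget 3 and 5-fold CV per fit — sizes chosen so a replicate completes in
well under a minute on one core while keeping the planted mediation
comfortably detectable. Calibration suites use 200 null CpGs (selection
gate), 200 HEIDI replicates per regime, 200 colocalization oracle regions
and 100 clumping oracle instances.

## Numerical choices and degenerate inputs

* Beta clipping $\varepsilon = 10^{-6}$ keeps M finite without moving any
  realistic value; logsumexp arithmetic throughout colocalization.
* Constant CpGs → p = 1 with a warning; constant dosages → pair skipped;
  constant predictions → proxy model unselected; constant chronological
  age → age-acceleration error; all-tied Wilcoxon input → p = 1.
* Ties in the rank-INT knots are collapsed by averaging the empirical CDF;
  zero-variance features pass through with a warning.
* Missing dosages are mean-imputed per SNP (a dosage-scoring convention);
  a drop-samples alternative sits behind a flag. CpGs with more than 5%
  missingness are dropped at load.
* Greedy tie-break in clumping: equal p resolved by SNP id for
  determinism.
* All simulation and fitting functions require an explicit seed; there is
  no unseeded path.

## Known limitations

Single-causal-variant colocalization only; no cell-type deconvolution or
surrogate-variable adjustment; PAI strengths are inputs, not predictions;
the PMS stage learners are one concrete instantiation of the two-step
scheme; the per-CpG proxy inventory of any specific study cannot be
reproduced without its restricted cohort data, so tests quantify recovery
of planted effects instead.
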