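---
title: "Nonlinear polygenic prediction with nlprs: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear polygenic prediction with nlprs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Standard polygenic risk scores (PRS) are weighted sums of allele counts,
$\mathrm{PRS}_s = \sum_v w_v\, g_{sv}$, with weights taken from
genome-wide association study (GWAS) summary statistics. By construction
they are linear and additive: they cannot represent dominance, epistasis
(SNP-by-SNP interaction), or joint-carrier effects. `nlprs` implements a
prediction pipeline that keeps the PRS where it is strong — aggregating
many weak additive signals — and adds a gradient-boosted-trees stage that
can pick up non-additive structure among a focused set of candidate SNPs.

The package provides four model families over the same adjusted phenotype:

1. **Linear PRS model** — OLS of the phenotype on a tuned
   clump-and-threshold (C+T) score plus genetic principal components (PCs).
2. **LASSO baseline** — an L1-penalized linear model on exactly the SNPs
   the ensemble selected; the linear comparator with the same inputs.
3. **Boosted trees alone** — gradient-boosted regression trees on the
   LASSO-selected SNPs plus PCs.
4. **Boosted trees with PRS** — the same booster with the standardized PRS
   as an additional feature.

Comparing 3 vs 2 isolates non-linearity and interactions (same SNPs, same
phenotype); comparing 4 vs 1 asks whether the combined model beats the best
linear score.

# Pipeline stages

## Phenotype harmonization (`harmonize`)

Raw phenotype → adjusted phenotype in five steps: (i) mask values strictly
below the 1st or above the 99th percentile of the pooled cohort;
(ii) medication rules (`set_missing` for systolic-blood-pressure-style
phenotypes, `add_constant`, e.g. +10 mmHg, for diastolic-style ones);
(iii) optional natural-log transform (lipid-style phenotypes);
(iv) OLS residuals on age, sex, study, and group; (v) rank-inverse-normal
transform of the residuals.

Open choices we fixed (all configurable):

* **Quantile definition**: type-7 linear interpolation of order statistics,
  R's default; "the 99th quantile" does not pin down an estimator.
* **Strict exclusion** (`<` / `>`), computed on the pooled multi-group
  vector, not per group.
* **Rank-normal offsets**: Blom, $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$;
  van der Waerden available. Ties share the mean of their tied ranks.
* **Order**: trimming happens on raw values before medication rules by
  default (`trim_first = FALSE` swaps them). The difference matters only
  for samples whose value a medication rule would remove anyway.
* **LDL-style phenotypes**: no medication adjustment by default; add a rule
  if your protocol has one.

## Genetic statistics (`filter_maf`, `marginal_gwas`, `compute_grm`, `reml_h2`)

Variants are filtered at pooled minor allele frequency (MAF) < 0.01 and
re-oriented so the counted (effect) allele is always the minor allele;
flipping a variant complements its counts ($g \to 2-g$) and negates any
attached weight. The marginal GWAS is one OLS per variant with covariates,
implemented by projecting genotypes and phenotype off the covariate design
once (Frisch–Waugh–Lovell); it is numerically identical to the per-variant
`lm` fit. p-values are clamped into $(0, 1]$ at `1e-300`.

The genetic relationship matrix (GRM) is the standard
$K = ZZ^\top/M$ on centered, frequency-scaled counts, so $K_{ij}$
estimates twice the kinship coefficient. Two caveats drive design choices:

* **Ancestry vs relatedness.** In a multi-ancestry cohort the plain GRM
  puts every same-group pair at a positive offset; with realistic
  differentiation that offset alone crosses the third-degree cut
  (kinship 0.0625). Ancestry-robust kinship estimators exist but are a
  method of their own; as a light-weight stand-in, `compute_grm(adjust_pcs = k)`
  projects the top $k$ principal axes out of $Z$ before forming $K$, which
  zeroes the group offset while close relatives stay visible. The pipeline
  uses this adjusted matrix for the unrelatedness filter and for
  heritability.
* **Panel size.** GRM off-diagonal noise scales like $1/\sqrt{M}$; with
  very small panels the noise itself approaches the kinship cut. Our
  end-to-end runs use panels of 1–2 thousand variants, which keeps the
  noise more than 5 standard deviations below the cut.

The unrelatedness filter (`select_unrelated`) is a greedy
maximum-independent-set heuristic: repeatedly drop the sample with the
most remaining violating pairs, ties broken toward the smaller sample id,
and hard-assert the result against the threshold. On random 12-sample
instances it is within one sample of the exhaustive optimum.

**REML heritability** fits $y = X\beta + \epsilon$,
$\mathrm{cov}(\epsilon) = \sigma^2_\epsilon I + \sigma^2_k K$, and reports
$\hat h^2 = \hat\sigma^2_k / (\hat\sigma^2_k + \hat\sigma^2_e)$. One
eigendecomposition of $K$ makes every restricted-likelihood evaluation
$O(np)$; the likelihood is profiled over $h^2$ on a 0.01-step grid and
refined with Brent's method, so the optimizer is global on $[0, 1)$ and
cannot be trapped by a flat boundary. The standard error comes from the
observed information (numerical Hessian in $(\sigma^2_k, \sigma^2_e)$,
delta method for $h^2$); we validated it against the exact Fisher
information on family-block designs. The 95% CI is
$\hat h^2 \pm 1.96\,\mathrm{SE}$, truncated to $[0, 1]$ — the asymptotic
normal interval can cross the parameter space, and we truncate rather than
re-parametrize. A kinship matrix numerically proportional to the identity
makes $(\sigma^2_k, \sigma^2_e)$ unidentifiable and raises an error rather
than returning a silent estimate.

## Clump-and-threshold PRS (`tune_ct`)

Strand-ambiguous variants (A/T, C/G) are removed, summary statistics are
aligned to the cohort (allele-order flips negate the effect size), and
greedy clumping walks the p-value-sorted list: take the best remaining
variant as index, prune everything on the same chromosome within the
window whose $r^2$ with the index exceeds the threshold. The training
cohort itself is the LD reference. Tie-breaks are fully specified
(p-value, then chromosome, then position) for reproducibility.

The tuning grid is windows {250, 500} kb × clump $r^2$ {0.1, 0.2, 0.3} ×
p-value thresholds {0.5, 0.1, 0.05, 0.01, $10^{-3}, \dots, 10^{-10}$}; the
cell whose PRS model (OLS on score + PCs) has the smallest **training**
MSE wins, ties toward fewer variants, then the smaller window. Cells with
no surviving variants are skipped with a warning. Missing genotypes
contribute the variant's mean count to the score. The downstream "PRS"
slot accepts any externally computed per-sample score vector, so scores
from other PRS methods can be plugged in without re-implementing them.

## The LASSO → boosted-trees ensemble (`fit_ensemble`)

Candidate SNPs are those with discovery-GWAS $p < 10^{-4}$. For each
penalty $\alpha$ in the grid:

1. **Chunked LASSO selection.** Chromosomes are assigned whole to (default
   5) chunks, largest count first into the currently smallest chunk, so no
   chromosome is split and sizes stay balanced. Per chunk, an L1 model
   with standardized SNPs and unpenalized covariates (PCs) is fit at
   $\alpha$; the union of non-zero SNPs across chunks is the selection.
2. **Booster cross-validation.** 3-fold CV of gradient-boosted trees on
   the selected SNPs + PCs (+ standardized PRS when configured), up to
   10,000 rounds with early stopping after 10 rounds without improvement
   of the mean held-out squared error. $\theta_\alpha$ is the argmin of
   the mean held-out MSE curve.

The $(\alpha^\ast, \theta_{\alpha^\ast})$ pair minimizing the
cross-validated MSE wins (ties toward the larger penalty, i.e. fewer
SNPs), and the booster is refit on the full training data for
$\theta_{\alpha^\ast}$ rounds. Booster settings are fixed throughout:
learning rate 0.01, maximum depth 5, column subsample per tree 0.9,
minimum child weight 10, row subsample 0.5.

Choices worth knowing:

* **Penalty grid.** Default: 8 geometric values over $10^{-3}$–$1$ on the
  `glmnet` $\lambda$ scale. On standardized features and a rank-normalized
  outcome this spans dense-to-empty selections. Heavy simulation tests in
  the suite use a 3-point subgrid and a 1,500-round tree cap; those sizes
  are stated in the test code and were chosen for the simulated
  architectures, which are far sparser than real traits.
* **Per-fold vs mean early stopping.** Folds are monitored jointly through
  the mean held-out error (that is also what `xgb.cv` stops on); a
  per-fold variant would end folds at different rounds and leave
  $\theta_\alpha$ ill-defined. The argmin-of-mean-curve definition is
  well-defined regardless of where stopping occurred.
* **A separate 10-fold CV while fitting the LASSO at a fixed $\alpha$ has
  no selection role** (the penalty is tuned downstream by the booster
  CV); the default is a single fit per penalty. An optional
  `lasso_mode = "majority"` averages selection over 10 leave-one-fold-out
  fits and keeps SNPs chosen in a majority, for stability analyses.
* **PRS standardization.** The PRS feature is standardized with training
  mean/SD before entering the booster. Trees are scale-indifferent, but
  this keeps linear diagnostics comparable; test samples reuse the
  training constants.
* **Optional modes.** Clump-before-selection: pass `clump()` output as the
  candidate set. PC-removal: `include_pcs = FALSE`. LASSO-loss tuning for
  the baseline: `lasso_baseline(mode = "cv")`.
* **Degenerate outcomes.** A zero-variance phenotype yields constant
  predictors in both the ensemble and the baseline rather than an error
  deep inside a fitting routine.

## Evaluation (`pve`, `relative_pve`, `stratified_report`)

Performance is the percentage of variance explained,
$\mathrm{PVE} = \big(1 - \mathrm{var}(y^0 - \hat y)/\mathrm{var}(y^0)\big)
\times 100\%$, with the sample ($n-1$) variance in both places — the ratio
is invariant to the convention as long as it is consistent, which the
suite asserts. A model worse than the mean predictor goes negative; we
report it unclipped because it is diagnostic. Model comparisons use the
relative PVE, $(\mathrm{PVE}_2 - \mathrm{PVE}_1)/\mathrm{PVE}_1$.

The 80/20 train/test split is stratified by group; an `"unrelated"` mode
additionally drops from training any sample related (kinship ≥ 0.0625) to
a test sample, so training may contain internal relatives but none of the
test set. Reports carry PVE per model per group plus pooled, the pairwise
relative-PVE table, the heritability estimate for context, and the split
manifest; they serialize to JSON losslessly.

# The synthetic-data generator

Real genotype and phenotype data of the kind this method targets are
access-controlled, so the package ships a simulator that reproduces the
*structural* features the pipeline exercises:

* **Differentiated populations.** Per-group allele frequencies follow the
  Balding–Nichols Beta model around shared ancestral frequencies drawn
  from $U(0.05, 0.5)$, with per-group $F_{ST}$ (default 0.1, three
  groups). Frequencies are clipped to $[0.01, 0.99]$ so every variant
  stays polymorphic.
* **LD blocks.** Each haplotype is a latent AR(1) Gaussian along the
  panel (correlation `ld_rho`, reset at block and chromosome boundaries)
  thresholded at the frequency-matched quantile; two independent
  haplotypes per individual. This gives cheap, tunable $r^2$ without
  coalescent machinery.
* **Trait architectures.** Additive per-allele effects, dominance
  deviations for heterozygotes, pairwise epistasis as the product of
  allele counts $e \cdot g_1 g_2$, and joint-carrier effects (an effect
  fires when every variant of a set carries at least one effect allele) —
  the closest unphased analogue of a haplotype effect, since phasing is
  out of scope. Noise variance is set so genetic/(genetic+noise) variance
  equals `target_h2`; covariate effects sit on top and are removed again
  by harmonization. Note that the *product* encoding of epistasis leaves a
  marginal additive component (unless allele frequencies are at 0.5 the
  product correlates with each count), which is what makes such pairs
  discoverable by a marginal GWAS at all — a purely centered interaction
  would be invisible to the candidate filter, and to any real GWAS-based
  pipeline.
* **Discovery GWAS.** Summary statistics come from an independently drawn
  cohort on the same variant panel, with configurable group sampling
  weights (e.g. 70/20/10 to emulate a European-ancestry-skewed discovery
  study), analysed by the package's own marginal GWAS adjusted for age and
  sex. Cohort and discovery samples come from disjoint random-number
  streams derived from one seed, so no leakage is possible and every
  stage is reproducible bit-for-bit.
* **Medication and missingness.** Medication-use flags follow a logistic
  model on the standardized raw trait (treated people have higher raw
  values), and phenotypes can be set missing at random.

What it does **not** emulate — so what passing tests do not show:
realistic recombination maps or long-range LD, rare-variant architecture,
genotyping or imputation error, winner's curse in the discovery effect
sizes, assortative mating, gene–environment interaction, or real
phenotype measurement protocols. Results on this simulator demonstrate
that the machinery is correct and that the ensemble detects planted
non-additive signal; they say nothing quantitative about any real trait.

# Problem sizes in the test suite

The statistical property tests run at sizes chosen to make the planted
effects detectable with comfortable margins on one CPU: epistasis and
null-calibration scenarios use cohorts of 4,000 samples (3 groups) on
400-variant panels with a 6,000-sample discovery GWAS; heritability
recovery uses 1,000 samples (family blocks of 4, or 1,000-variant GRMs);
the selection-vs-random comparison uses 1,500 samples. The end-to-end
demonstration in `scripts/acceptance.R` uses 4,001 samples on a
2,000-variant panel. Replicate streams are decorrelated by spacing seeds
(`1009 r + 17`-style), not by consecutive integers.

# Known limitations

* The C+T implementation enumerates a fixed p-value threshold grid; the
  exact enumeration used by dedicated PRS software differs and is not
  reproduced.
* Model-based PRS methods (joint-effect shrinkage over an LD panel) are
  not implemented; external score vectors can be supplied instead.
* The ancestry adjustment of the GRM is a projection, not a full
  ancestry-robust kinship estimator; with admixed individuals the residual
  structure can still bias the relatedness cut.
* Boosting over hundreds of thousands of SNPs is out of scope; the
  ensemble presumes the candidate filter has reduced the SNP set to
  thousands at most.
* PVE is reported without bootstrap confidence intervals.
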