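---
title: "Pleiotropic meta-analysis with antagonistic heterogeneity: methods"
author: "pleiometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pleiotropic meta-analysis with antagonistic heterogeneity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiometa)
```

# The problem

A single variant can be associated with several correlated age-related
phenotypes. Pooling those associations is more powerful than testing one
phenotype at a time, but *how* the pooling treats correlation decides what
the combined p-value means. `pleiometa` implements a two-stage design:

* **Stage 1** — univariate association of every SNP with every phenotype in
  every cohort under the additive genetic model (dosage 0–2, effect per
  allele copy), adjusted for age and sex. Quantitative markers use their
  repeated visits through a random-intercept model; skewed markers are
  analysed as $100 \log y$; diseases and death are analysed as age-at-onset
  outcomes with Cox proportional hazards (and as 0/1 indicators with
  logistic regression where a binary view is wanted).
* **Stage 2** — meta-analysis along two pathways. Pathway 1 first combines
  each phenotype across cohorts (fixed-effects inverse-variance pooling and
  Fisher's method), then across phenotypes. Pathway 2 first combines across
  phenotypes within each cohort, then across cohorts with Fisher's method.

Seven stage-2 statistics result, named by their combination operators:
`MOp`, `MOb`, `MFp`, `FcFp` (pathway 1) and `OpFc`, `ObFc`, `FpFc`
(pathway 2), where `M` = fixed-effects meta, `F` = Fisher, `O` = omnibus,
subscript `p` = across phenotypes, `c` = across cohorts.

# The tests

**Fixed-effects meta-test.** With per-cohort effects $\hat\beta_j$ and
standard errors $\hat\sigma_j$, weights $w_j = 1/\hat\sigma_j^2$ give the
pooled effect $\sum_j w_j \hat\beta_j / \sum_j w_j$ with variance
$1/\sum_j w_j$ and a two-sided Wald p-value. Cochran's
$Q = \sum_j w_j(\hat\beta_j - \hat\beta_{meta})^2$ and
$I^2 = \max(0, (Q - (k-1))/Q) \times 100\%$ quantify between-cohort
heterogeneity ($I^2$ is reported as missing, not zero, for a single
cohort).

**Fisher's method.** $-2\sum_i \ln p_i \sim \chi^2_{2m}$ under independent
nulls. It ignores effect directions, which lets it out-signal the
fixed-effects pool under strong between-cohort heterogeneity — and it is
anticonservative when the combined tests are positively dependent, which
is precisely the contrast the omnibus tests expose.

**Omnibus test.** For the z-score vector $z$ of one SNP against $K$
phenotypes, with $\Sigma$ the correlation matrix of those z-scores,
$z'\Sigma^{-1}z \sim \chi^2_K$ under the null. In two dimensions

$$z'\Sigma^{-1}z \;=\;
\frac{z_1^2\Sigma_{22} - z_1 z_2 \Sigma_{21} + z_2^2\Sigma_{11}
      - z_1 z_2 \Sigma_{12}}{\det\Sigma},$$

so same-sign z-scores on positively correlated phenotypes are *penalized*
($z_1 z_2 \Sigma_{12} > 0$ shrinks the statistic) while opposite-sign
z-scores on positively correlated phenotypes are *rewarded*. Genetic
effects pointing in antagonistic directions for directly correlated
phenotypes therefore give the omnibus test a smaller p-value than
Fisher's — the signature the classification rules key on.

**Two estimates of $\Sigma$.**

* $\Sigma^P$ — Pearson correlation of the phenotypes themselves:
  per-subject visit-averaged values on the analysis scale for quantitative
  markers, 0/1 event indicators for outcomes (point-biserial). Cohort
  scope uses one cohort's subjects; meta scope pools all subjects,
  pairwise-complete across cohort-specific phenotype gaps.
* $\Sigma^B$ — correlation of association statistics of *permuted*
  dosages: the SNP's dosage vector is permuted $R = 250$ times within each
  cohort, the same permutation reused against all of that cohort's
  phenotypes (this preserves the cross-phenotype dependence that is the
  whole point), each permuted vector is scored against every phenotype,
  and $\Sigma^B$ is the correlation of the $R$ resulting z-vectors. At
  meta scope the per-cohort z-scores of each replicate are first pooled by
  inverse-variance (sample-size) weighting.

The permutation fits are score-type statistics: each phenotype is reduced
once to null-model residuals (OLS residuals of visit-averaged markers,
response residuals of a covariate-only logistic fit, martingale residuals
of a covariate-only Cox fit), and the z-score of a permuted dosage $g$ is
$\sqrt{n}\,\mathrm{cor}(g, r)$. Under the permutation null this is the
standard score statistic; any per-phenotype scale factor cancels in the
correlation. This keeps 250 permutations $\times$ 20 phenotypes $\times$ 5
cohorts a matrix multiplication instead of thousands of model refits.

# Classification rules

Genome-wide (GW) significance is $p < 5\times10^{-8}$ in any test. For a
SNP's best pathway, with $(p_{Op}, p_{Ob}, p_F)$ the $\Sigma^P$-omnibus,
$\Sigma^B$-omnibus and Fisher pleiotropic p-values (`MOp`/`MOb`/`MFp` for
pathway 1, `OpFc`/`ObFc`/`FpFc` for pathway 2):

* **HP** — $p_{Op}$ GW-significant and $p_F$ at least 2 orders of
  magnitude larger than $p_{Op}$;
* **HB** — the same for $p_{Ob}$;
* **HP/HB** — both; **M** — neither, but some test GW-significant;
* SNPs with no GW test are unclassified and excluded from outputs.

*Resolution of the 2-order rule.* The battery p-values circulate printed
to three significant figures, so order-of-magnitude gaps are judged at
one-decimal resolution: the rule is $\log_{10} p_F - \log_{10} p_{Op}
\ge 2 - 0.05$. This is the operationalization under which the package's
regression fixture of 115 published classifications is reproduced row for
row; a literal $\ge 10^2$ ratio misclassifies a boundary row whose gap is
1.98 orders. The resolution (`orders_resolution`) is a threshold field and
can be set to 0 for the literal rule.

Three further rules:

* **Validation.** Pathway 1: automatically validated when every
  contributing univariate meta p-value is above the GW level (the GW
  pleiotropy was assembled from sub-threshold parts). Pathway 2:
  automatically validated when no single cohort is GW; otherwise at least
  one additional cohort must reach the Bonferroni level
  $0.05/(N_{cohorts}-1)$.
* **Antagonism replication.** A cohort replicates when its pleiotropic
  tests reach suggestive significance ($p < 0.1$) and the Fisher p-value
  exceeds the smaller omnibus p-value by $\ge 0.2$ orders; replication
  requires two or more cohorts.
* **Novelty.** Prior evidence per phenotype is Fisher-combined over all
  $K$ study phenotypes, substituting a flat $p = 0.4$ for phenotypes with
  no reported result (penalizing sparse prior records). A SNP is novel
  when neither this combination nor any reported univariate prior p-value
  reaches the GW level. How many phenotypes to penalize over is a genuine
  open choice; `K_total` is a parameter, defaulting to the study's
  phenotype count.

Stage-1 prioritization Fisher-combines only p-values below 0.05 (pooled
over cohorts and phenotypes — pooling level is not dictated by the design,
so the simplest reading is implemented), ranks ascending with ties broken
by the smallest single p-value then SNP id, and keeps the top 1,000.

# The synthetic study generator

Real consortium data of this kind are access-controlled, so the package
carries a generator that reproduces the *statistical structure* the
pipeline assumes, making every stage testable:

* **Design**: five cohorts (default sizes 9,612 / 3,182 / 8,628 / 2,527 /
  9,482 — 33,431 subjects, scalable), 20 phenotypes (12 quantitative
  markers with repeated visits, 6 of them log-scale; 8 age-at-onset
  outcomes), with per-cohort phenotype gaps mirroring real availability.
* **Copula**: a latent multivariate-normal trait vector with the study
  correlation matrix drives all phenotype kinds — the standard structure a
  Pearson-based $\Sigma^P$ assumes. Off-diagonals default to "weak to
  modest" (0.3; the real magnitudes are not public, so this is a
  configurable choice, not a calibration).
* **Genetics**: HWE dosages Binomial(2, MAF), MAF $\ge$ 0.02 by default;
  per-phenotype effects in SD units per allele copy (log-odds / log-hazard
  for outcomes) with per-cohort multipliers for inter-cohort
  heterogeneity; aligned, antagonistic, null and custom geometries.
* **Visits**: independent Gaussian visit noise with intraclass correlation
  `icc` (default 0.5). A single measured visit then carries correlation
  $\rho \cdot icc$ — attenuation the estimator inherits consistently, since
  $\Sigma^P$ is estimated from the same averaged measurements whose
  correlation the z-scores carry.
* **Outcomes**: binary events threshold a logistic liability
  ($y = \mathbf{1}\{\eta + e > 0\}$, $e$ logistic), so the injected effect
  *is* the log-odds ratio the logistic fit estimates; ages at onset are
  exponential from age 30 with hazard scaled by
  $\exp(0.3\,L + \beta g + \text{covariates})$, administratively censored
  at 85 years (defaults; both configurable).
* **Determinism**: all randomness flows from one study seed, expanded
  deterministically per cohort.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population stratification, imputation uncertainty, familial
relatedness, informative dropout, or non-Gaussian trait tails beyond the
log-scale markers. Passing tests therefore demonstrate correctness of the
statistical machinery under the model's own assumptions, not robustness to
those real-data complications.

# Numerical choices

* **Log-scale p-values.** Every test carries an exact $\log_{10} p$
  alongside a probability floored at $10^{-300}$ (floor logged with a
  warning); genome-wide batteries routinely underflow doubles, and the
  classification compares orders of magnitude, so comparisons always use
  the log scale.
* **Matrix repair.** A correlation matrix with condition number
  $\ge 10^8$ (or a non-PD estimate) is shrunk $(1-\lambda)\Sigma +
  \lambda I$ with the smallest $\lambda \in \{0.01, 0.02, \dots\}$ that
  restores conditioning; degrees of freedom stay $K$.
* **Random-intercept fit.** Compound-symmetry GLS: the within-subject
  variance comes from the pooled within-subject mean square; the
  between-subject variance solves a moment equation on the weighted
  subject-mean residuals, iterated to a $10^{-8}$ fixed point on the
  variance ratio. With one visit this is exactly OLS; on balanced designs
  it agrees with REML to well within estimation error (cross-checked
  against `lme4` in the test suite).
* **Wald p-values** are two-sided normal throughout; Cox fits use Breslow
  tie handling and no frailty term (the generator's subjects are
  unrelated).
* **Tie-breaks**: the best test of a SNP follows the fixed order `MOp`,
  `MOb`, `MFp`, `FcFp`, `OpFc`, `ObFc`, `FpFc`; prioritization ties break
  by smallest single p, then SNP id.
* **Allele harmonization** flips records to the first cohort's effect
  allele, flags strand-ambiguous A/T and C/G pairs, and excludes
  irreconcilable pairs with a log entry; missing cohorts are dropped
  (effective $k$ reduced), never imputed.

# Problem sizes in the test suite

The shipped tests run the calibration studies at sizes chosen to make the
measured quantities statistically meaningful on a single CPU: the null
calibration uses 10,000 SNPs across 2 cohorts of 1,000 subjects with 5
phenotypes (batch routines, $\Sigma^B$ estimated once per scope — valid
under that study's exchangeable null); the antagonism-direction study uses
100 replicates of 5 cohorts $\times$ 2,000 subjects; parameter recovery
uses 200 replicates per phenotype kind. The per-SNP pipeline (with
per-SNP $\Sigma^B$) is exercised on smaller panels and pinned to the batch
routines by an exact consistency test.

# Known limitations

* Fisher-based tests (`MFp`, `FcFp`, `FpFc`) are anticonservative under
  positively correlated phenotypes — by design they are the uncorrected
  reference the omnibus tests are contrasted against, not calibrated
  tests in their own right.
* $\Sigma^B$ at $R = 250$ has per-entry sampling error
  $\approx (1-\rho^2)/\sqrt{R}$; with many phenotypes the worst entry can
  deviate from $\Sigma^P$ by more than 0.1 even though both estimate the
  same matrix. Increase `R` where tighter agreement matters.
* The gamma-family fit for heavily skewed inflammatory markers is out of
  scope; such markers are handled by the log-transform route.
* No genome-wide orchestration: the stage-2 battery targets a prioritized
  panel (thousands of SNPs), not millions.
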