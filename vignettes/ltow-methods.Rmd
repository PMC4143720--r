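---
title: "Region-based association testing for longitudinal phenotypes with optimally weighted variants"
author: "ltow package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based association testing for longitudinal phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltow)
```

## The problem

Single-variant association tests are underpowered for rare variants, so
region-based tests aggregate all variants in a gene or window into one
statistic. The TOW family does this with a *weighted burden*: the genotype
score of individual $i$ is $x_i = \sum_{m=1}^M w_m x_{im}$, where $x_{im} \in
[0, 2]$ is the minor-allele dosage at variant $m$, and the weights $w_m$ are
chosen to maximize a score-type statistic — so the data decide which variants
matter and with which sign, instead of a fixed burden scheme.

Cohorts increasingly measure quantitative traits (blood pressure, BMI,
lipids) at several visits. Using one visit discards information; averaging
visits ignores the correlation structure. This package tests a region against
*all* measurements jointly: a mixed linear model accounts for the
within-individual correlation across visits, the data are whitened with the
fitted null covariance, and the optimally weighted statistic is evaluated on
the whitened residuals by permutation.

## Model

For individual $i = 1 \ldots n$ at visit $j = 1 \ldots K$,

$$y_{ij} = Z_{ij}^T \alpha + \beta x_i + v_{ij} + e_{ij},$$

with covariates $Z_{ij} = (1, z_{ij}^T)^T$ (sex, age, medication, ...), a
per-individual environmental process $v_{i\cdot} \sim N(0, \sigma_v^2 D_0)$
that carries the correlation between visits, and iid noise $e_{ij} \sim
N(0, \sigma_e^2)$. Stacked individual-major (all of individual 1's visits,
then individual 2's, ...), $y = Z\alpha + x\beta + v + e$ with total
covariance $\Sigma = \sigma_v^2 D + \sigma_e^2 I$, $D =
\mathrm{diag}(D_0, \ldots, D_0)$. The genetic effect $\beta$ is a single
average effect over time; genotypes are constant within an individual, so the
expanded genotype column repeats each dosage $K$ times.

The null fit ($H_0: \beta = 0$) proceeds in three steps:

1. **$D_0$** is estimated by the pairwise Pearson correlations of the
   phenotype columns (`estimateTimeCorrelation`), repaired to positive
   semidefiniteness by eigenvalue clipping at $10^{-8}$ and diagonal
   renormalization. By default the *raw* phenotype columns are used; a
   `adjustCovariates = TRUE` switch correlates OLS residuals instead, which
   matters when a covariate (like age) trends strongly across visits and
   inflates the raw correlations.
2. **$(\sigma_v^2, \sigma_e^2)$** are maximum-likelihood estimates under the
   null (`fitNullVarianceComponents`), maximizing the $\alpha$-profiled
   Gaussian likelihood. Everything is computed blockwise from one $K \times
   K$ eigendecomposition of $D_0$; the $nK \times nK$ covariance is never
   formed. REML is available behind a flag; plain ML is the default.
3. **Whitening**: with $\hat\Sigma = \hat\sigma_v^2 D + \hat\sigma_e^2 I$,
   the phenotype, the design and every expanded variant column are multiplied
   blockwise by $(\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I_K)^{-1/2}$
   (symmetric eigendecomposition, `inverseSqrtBlock`).

After whitening, $y^*$ and $X_m^*$ are the OLS residuals of the whitened
phenotype and variant columns on the whitened design. The statistic is

$$T \;=\; y^{*T} X^* A_0^{-1} X^{*T} y^*
     \;=\; \sum_{m=1}^M \frac{(y^{*T} X_m^*)^2}{X_m^{*T} X_m^*},
\qquad A_0 = \mathrm{diag}(X^{*T} X^*),$$

which is the maximum over $w$ of the ratio $T_0(w) = (w^T X^{*T} y^*)^2 /
(w^T A_0 w)$, attained at $w^o = A_0^{-1} X^{*T} y^*$ (Cauchy–Schwarz; the
diagonal $A_0$ replaces the full cross-product matrix, which is unstable for
sparse rare-variant columns). The per-observation error scale
$y^{*T}y^*/(nK)$ that appears in the score-test form is omitted: it is
invariant under permutations of $y^*$ and cancels from the rank ordering
that determines the p-value.

Significance comes from permutation: $\hat\Sigma$, $\hat\alpha$ and the
residual projector are computed once from the observed data and held fixed;
in each of $B$ rounds the entries of $y^*$ are shuffled uniformly
(Fisher–Yates via R's generator, one seed per call, bit-reproducible) and
$T$ recomputed. The p-value uses the add-one convention $(1 + \#\{T_b \ge
T\})/(B + 1)$, never zero, floored at $1/(B+1)$; ties count as exceedances.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nPerm` | 1000 | permutations; the p-value resolution is $1/(B+1)$ |
| `seed` | 1 | RNG seed; scans derive per-region seeds from it so results are independent of scan order |
| `adjustCovariates` | `FALSE` | estimate $D_0$ from covariate-adjusted residuals instead of raw phenotypes |
| `blockPermute` | `FALSE` | permute whole individuals ($K$-blocks) instead of single entries |
| `reml` | `FALSE` | restricted likelihood for the variance components |

Variants whose residual column is numerically zero (residual sum of squares
$\le 10^{-10}$: monomorphic, or fully explained by covariates) are dropped
from the sum, reported in `nVariantsDropped`, and given weight 0. Dosages
are taken verbatim in $[0, 2]$ — fractional imputed dosages included — and a
`flipMajor` option re-orients columns whose mean dosage exceeds 1; since the
statistic squares covariances, orientation affects only the sign and
readability of the reported weights.

## The single-time-point baseline

`towSingle` is the classical one-measurement test, and `towAverage` runs it
on the per-individual visit average. Both are implemented as the exact
$K = 1$ special case of the longitudinal pipeline: with one time point
$\sigma_v^2$ and $\sigma_e^2$ are confounded, so the fit fixes
$\sigma_v^2 = 0$, estimates $\sigma_e^2$ by ML ($\mathrm{RSS}/n$), and the
"whitening" is the scalar $1/\hat\sigma_e$ — constant across permutations,
hence irrelevant to the p-value, but it makes `ltowTest` on $K = 1$ data and
`towSingle` return *identical* statistics, which is the cleanest consistency
contract between the two code paths.

## Identifiability and degenerate inputs

- $K = 1$, or an estimated $D_0$ that is numerically the identity
  (max off-diagonal $< 10^{-6}$): $\sigma_v^2$ and $\sigma_e^2$ enter only
  through their sum, so the fit collapses to OLS with $\sigma_v^2 = 0$.
- The 2-parameter likelihood search is a bounded quasi-Newton (L-BFGS-B) on
  $(\sigma_v^2, \sigma_e^2)$ with two starts — method-of-moments (matching
  the average within-individual covariance to $\sigma_v^2 D_0$) and a
  pure-error start $(0, \widehat{\mathrm{var}})$ — followed by a
  Nelder–Mead polish, which also certifies boundary solutions such as
  $\hat\sigma_e^2 \to 0$ (these arise when $D_0$ is estimated from the same
  residuals it is fitted to, making the model family saturate the empirical
  covariance). Objective tolerance is $\sim 10^{-9}$ relative.
- A zero-variance phenotype column, a rank-deficient design (the collinear
  column is named), and a region with no polymorphic variants after
  residualization all raise informative errors rather than propagating NaN.

## What the simulator emulates — and what it does not

`simulateGenotypes` draws one MAF per variant uniformly on $[0.005, 0.05]$
(a rare-leaning spectrum typical of sequencing studies) and genotypes as
Binomial(2, MAF) under Hardy–Weinberg, independently across variants.
`simulateLongitudinalPhenotypes` draws a binary sex-like covariate, an
age-like covariate from $N(45, 10^2)$ years increasing by 5 years per visit,
and phenotypes exactly from the mixed model above, with defaults $n = 142$,
$K = 3$, $M = 100$, $\sigma_v^2 = \sigma_e^2 = 1$, compound-symmetric $D_0$
with $\rho = 0.5$, and fixed effects $\alpha = (10, 0.5, 0.05)$ (intercept;
sex difference; per-year age slope). Causal variants (the first 20% of
columns when $\beta \ne 0$) act through a signed sum of dosages, by default
scaled by $1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})}$ so rarer variants carry
larger per-allele effects — the standard rare-variant convention. The
moderate-power operating point used by the power harness is $\beta = 0.12$,
chosen once so the longitudinal test sits near 50% power at these defaults.

The generator deliberately does *not* emulate: linkage disequilibrium
(variants are independent), non-Gaussian phenotypes, unbalanced designs
(every individual has all $K$ visits), time-varying genetic effects, or
family structure. Passing calibration and power checks on these synthetic
conditions therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to real-data violations of them.

## Calibration behavior of the permutation schemes

The element-wise shuffle of $y^*$ is exact when the whitened residual
entries are exchangeable — which they are when the *true* covariance is used
for whitening. In practice $\hat\Sigma$ is fitted to the same data, and at
the default study scale ($n = 142$, $K = 3$) the fitted
$\hat\sigma_v^2 D_0 + \hat\sigma_e^2 I$ family nearly saturates the
empirical $3 \times 3$ residual covariance. Whitening by a covariance fitted
to the very data being tested pins the realized ratio of between-individual
to within-individual variation — exactly the quantity the statistic
measures, because expanded genotype columns are constant within an
individual. The observed statistic is then slightly *under*-dispersed
relative to its element-permutation reference, and the test is mildly
conservative: in the calibration harness (`estimateType1Error`; also
recomputed by `scripts/acceptance.R`) the empirical size at nominal 0.05 is
around 0.02–0.03 rather than 0.05, with p-values depleted at both tails.
This is a property of the published recipe itself at this sample size, not
of the implementation: with oracle whitening the same code is calibrated,
and the p-values remain valid in the conservative direction (the test never
over-rejects). The `blockPermute = TRUE` mode instead permutes whole
individuals, preserving within-individual structure on both sides of the
comparison, and is the appropriate choice when exact size matters more than
squeezing power from within-individual contrasts.

A second consequence of plug-in whitening: since the raw phenotype
correlations are attenuated by $\sigma_e^2$ (off-diagonal
$\sigma_v^2\rho/(\sigma_v^2 + \sigma_e^2)$), the individual components
$\hat\sigma_v^2, \hat\sigma_e^2$ under an *estimated* $D_0$ are a
reparametrization, not consistent estimates, of the generative components —
the fitted $\hat\Sigma$ is what matters, and it is consistent. Parameter
*recovery* therefore requires fitting with the true $D_0$, which is how the
recovery study in the acceptance script is defined.

## Power behavior

With a persistent (time-constant) genetic effect, the longitudinal test
dominates every single-time-point analysis: each visit contributes signal,
and the whitening downweights redundant correlated noise. Under compound
symmetry the per-individual visit *average* is itself a near-sufficient
summary of a persistent effect, so `towAverage` is highly competitive there
— the power study written by `scripts/acceptance.R` reports all three
(`power_ltow`, `power_tow_ave`, `power_tow_single`, the last being the
average over the $K$ single-visit analyses). The advantage of the joint test
over averaging appears when visits have unequal information (unequal
variances, non-exchangeable correlation, missing-by-design visits), which
the default generator intentionally does not simulate.

## Numerical choices

- Stacking is individual-major, time-minor everywhere; `whiten` is one
  matrix multiplication by reshaping the stacked matrix to $K$-row form.
- Permutation statistics are evaluated in batches: a $nK \times B$ matrix of
  shuffled $y^*$ columns against $X^{*T}$ in one BLAS call, chunked to
  bound memory at a few MB.
- Per-region seeds are `regionSeed(masterSeed, label)`, a polynomial hash of
  the label folded into the master seed below $2^{31}$ — results are
  independent of scan order and identical between a scan row and a direct
  call.
- The tie tolerance in the permutation comparison is $10^{-12}$ absolute,
  so a permutation reproducing the observed statistic exactly (e.g. a
  constant $y^*$) counts as an exceedance and drives $p$ to 1.

## Known limitations

- Balanced designs only: individuals missing any visit are dropped by the
  reader (complete-case), matching the method's derivation.
- No asymptotic p-values; cost is linear in `nPerm`.
- The family extension (a shared random effect between relatives) and
  binary traits are out of scope.
- Conservative size of the element-wise permutation default at small $n$,
  as analyzed above.
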