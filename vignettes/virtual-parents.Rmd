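---
title: "Virtual parental genotypes: model, power theory, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual parental genotypes: model, power theory, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parimpute)
```

## The generative models

`parimpute` works with three family designs at biallelic loci. All
genotype dosages and phenotypes are standardized to mean 0 and variance 1
(the segregation deviations η then have variance 0.5 on the autosomes).

**Autosomal full siblings.** Phenotypes are generated as

$$Y_{1} = b X_1 + d X_m + f X_f + \tau + \varepsilon_1, \qquad
  Y_{2} = b X_2 + d X_m + f X_f + \tau + \varepsilon_2,$$

with $X_s = 0.5(X_m + X_f) + \eta_s$, shared family effect
$\tau \sim N(0, \varphi^2)$, and independent residuals with
$\sigma^2 = 1 - (b^2 + d^2 + f^2 + bd + bf) - \varphi^2$ so that
$\mathrm{Var}(Y) = 1$. Here $b$ is the direct offspring effect and $d$,
$f$ the indirect maternal and paternal effects.

**Maternal half siblings** share the mother; each sib has their own
father, so the paternal regressor differs between the two rows of a
family. Paternal half sibs are the mirror image.

**X-linked full siblings.** Females carry 0/1/2 copies and are
standardized to unit variance; males are hemizygous, coded 0/2 on the
same scale, and therefore carry variance 2 — with equal coefficients a
locus explains twice the variance in males. Effect coefficients are
assumed equal across sexes, and per-sex residual variances are chosen so
each sex's phenotypic variance is 1. The sex-dependent dosage
covariances (mother–son 1, father–daughter 1, father–son 0,
brother–brother 1, sister–sister 0.75, brother–sister 0.5) all emerge
from the enumeration engine rather than being hard-coded; opposite-sex
pairs are ordered male-first.

## Imputation by exact enumeration

Rather than transcribing conditional dosage tables, the package
enumerates the full joint distribution of parental and offspring
genotypes under HWE, random mating and Mendelian transmission
(`enumerate_family_joint`) — 81 configurations for autosomal sib pairs,
243 for half sibs, fewer on X — and conditions on the observed pair.
This makes every imputed dosage, covariance identity and power formula
self-verifying: closed forms are *checked against* the enumeration in
the test suite rather than trusted.

```{r}
C <- genotype_moments(enumerate_family_joint("full_sib", locus_spec(0.3)))
round(C, 4)
```

Two facts visible here drive the power analysis: the imputed dosage
covaries 0.5 with each sib's genotype (exactly as a true parental dosage
would), but its variance is below 1,

$$\mathrm{Var}(X_p') = \frac{2H^2 + 5H + 12}{4(H+2)(H+4)}, \qquad
  H = 2p(1-p),$$

falling from 3/8 at rare alleles to 1/3 at $p = 0.5$. The imputed
dosage is a shrunken estimate: $\mathrm{Cov}(X_m, X_p') =
\mathrm{Var}(X_p')$. The printed rendering of this rational function is
ambiguous about the extent of the fraction bar; the form above was
selected by fitting candidates against the enumeration oracle, which
remains authoritative (they agree to 1e-12 across the frequency grid in
the tests).

Male sibling pairs are uninformative about their father's X genotype:
the paternal posterior equals the population prior for every observable
configuration, so the imputed paternal dosage is constant and any
paternal test on imputed male-male X data has non-centrality exactly
zero. The package drops such degenerate regressors rather than failing.

## Power theory

For a fitted term set, asymptotic GLS expectations give the expected
coefficients $\hat g = E(X^T\Omega^{-1}X)^{-1}E(X^T\Omega^{-1}Y)$, the
expected residual covariance
$\Sigma = \Sigma_Y - E(X\hat g Y^T) - E(Y\hat g^T X^T) + E(X \hat g \hat g^T X^T)$,
and the expected deviance per family $E(-2\ln L) = \ln|\Sigma| + 2$ (the
"+2" is the trace term, attained exactly because the fitted exchangeable
covariance can match $\Sigma$ for these designs). The per-family
non-centrality of a test is
$\zeta = E(-2\ln L_{\text{nested}}) - E(-2\ln L_{\text{full}})$, the
total NCP for $N$ i.i.d. families is $N\zeta$, and power is the upper
tail of the noncentral $\chi^2$ beyond the central critical value.
GLS weighting uses the generative model's $\Omega$ in both full and
nested models; the coefficient expectations are invariant to this choice
for the supported designs.

```{r}
ts <- test_spec("full_sib", "imputed", "cond_parental")
model <- trait_model(d = sqrt(0.001), phi2 = 0.2)
required_n(ts, locus_spec(0.3), model, target_power = 0.8, alpha = 0.05)
```

Partitioning even a large (0.1% of variance) indirect effect requires
tens of thousands of imputed-parent pairs — the central practical
message of the power machinery. Conditional tests default to
$\alpha = 0.05$; genome-wide detection tests conventionally use
$5\times10^{-8}$, and both are plain arguments.

**Effect-size interface.** Users state variances explained ($b^2$,
$d^2$, $f^2$) plus signs; coefficients are signed square roots
(`coef_from_ve`). The implied phenotypic variance decomposition includes
the cross terms $bd$, $bf$ (siblings share parents, so offspring and
parental dosages covary); whether alternative calculators include these
cross terms when converting variance explained is not standardized, so
the convention here is documented and the coefficients themselves are
always exposed. On the X, the offspring variance explained refers to the
male (variance-2) dosage scale.

## The simulator, and what passing tests do not show

`simulate_families` draws parents from HWE and transmits alleles by
coin-flip, so segregation variance arises mechanically, not by adding a
variance term. Loci are independent (linkage equilibrium); multi-locus
phenotypes sum per-locus effects. The simulator emulates the idealized
conditions of the theory: random mating, no assortment, no population
stratification, no LD, no ascertainment, Gaussian residuals. Agreement
between simulation and the analytic power surface (which the test suite
checks within simultaneous binomial intervals at a reduced grid of
N = 2000 families and 250–400 replicates per condition) therefore
validates internal consistency, not robustness to violations of these
assumptions in real cohorts.

One deliberate violation is covered: genotype-dependent parental
missingness (`apply_parental_missingness`, multiplicative 20/30/40%,
dominant 20/40/40%, recessive 20/20/40% triples). Under strong
differential missingness coefficient estimates can be modestly biased,
but the type-1 error of the conditional tests is preserved — the tests
assert the calibration, not a specific bias magnitude.

The paper-scale simulation grid (1000 replicates per condition) runs in
the same harness via `simulate_study`; the suite uses the reduced sizes
above so the default check completes in minutes, a choice about test
granularity rather than about the science.

## Mixed-model fitting

`fit_pair_mixed_model` maximizes the exact FIML likelihood with
per-family covariance $\sigma^2 I + \varphi^2 J$. Pairs are rotated to
within-family sum/difference coordinates (variances
$\sigma^2 + 2\varphi^2$ and $\sigma^2$), singletons contribute a
marginal term with variance $\sigma^2 + \varphi^2$ — this is how
families where only one sibling has a phenotype are retained.
Coefficients are profiled out by weighted least squares at each variance
evaluation; the two-dimensional profile deviance is maximized by
L-BFGS-B on $(\log\sigma^2, \varphi^2 \ge 0)$ with a tight factr so the
deviance is resolved well below LRT resolution. P-values use the
$\chi^2$ reference with df equal to the number of dropped terms; no
boundary correction is applied because the tests concern fixed effects,
not $\varphi^2$. The fitter is cross-checked against `lme4` maximum
likelihood in the tests (agreement in deviance to ~1e-5), including the
singleton case, but `lme4` is never on the analysis path.

Numerical conventions worth knowing:

- Regressors may be standardized with the true or sample-estimated
  allele frequency (`use_sample_freq`); LRTs are invariant to this
  affine choice, coefficient scales are not. Genotype-only pipelines
  (the scan, the CLI) use sample frequencies, each individual counted
  once.
- Monomorphic or sub-MAF variants are skipped with a logged message in
  scans, never fatal; collinear or zero-variance regressors raise
  errors naming the offending columns.
- LRTs are clipped at zero against convergence jitter.
- $\varphi^2 = 0$ is a valid boundary solution; estimates then match
  pooled OLS.

## Polygenic scores

`prs_analysis` forms unweighted scores — sums of trait-increasing-allele
raw dosages, with a per-locus orientation vector — for each sibling and
for the imputed parent(s), and fits phenotype on own score, parental
score(s) and covariates with the family random intercept. With loci at a
common frequency $p$, the expected raw-score coefficients are the
per-locus standardized effects divided by $\sqrt{2pq}$; the recovery
tests use this identity. Weighted scores are out of scope.

## File formats and the CLI

The PLINK .bed/.bim/.fam codec is implemented in-package (variant-major
2-bit encoding; het male-X calls are set missing with a logged count).
Imputed dosages are written as a plain-text table (SNP, A1, A2, one
column per virtual parent, raw 0–2 scale). Pair definitions come from an
explicit pairs file — relationship inference from genotypes is out of
scope. The CLI (`cli_main`, wrapped by `inst/cli/parimpute.R`) exposes
`impute`, `assoc`, `power` and `simulate` subcommands over these
functions and nothing else, so every CLI path is testable in-process.

## Known limitations

- Family structure is limited to two (half-)siblings; no trios/duos, no
  >2 sib sibships, no multi-allelic markers, no haplotype information.
- Half-sib X-linked imputation is not offered (the required conditional
  distributions are not derived for this design); requesting it is an
  explicit unsupported-design error.
- The random-effects structure is a family intercept only; genome-wide
  relatedness matrices (GRM) for stratification/cryptic relatedness are
  not implemented.
- Binary traits, assortative mating, and selected samples are out of
  scope; the power theory assumes the generative models above.
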