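# parimpute

Estimating indirect parental genetic effects on offspring phenotypes when
the parents themselves were never genotyped.

## The problem

A parent's genotype can influence a child's phenotype through the rearing
environment, over and above the alleles the child inherits — an *indirect
parental genetic effect*. Separating these maternal/paternal effects from
the direct offspring effect normally requires genotyped parent–offspring
trios, which are scarce in adult cohorts (parents of middle-aged
participants are often deceased). Large biobanks do, however, contain tens
of thousands of sibling and half-sibling pairs.

`parimpute` exploits the fact that a sibling's genotype is informative
about the parents. At a biallelic locus with counted-allele frequency *p*
under Hardy–Weinberg equilibrium and random mating, Bayes' theorem gives
the posterior distribution of a parent's genotype G\_P given the pair
(G₁, G₂):

    P(G_P = i | G1 = j, G2 = k) ∝ P(G1 = j, G2 = k | G_P = i) P(G_P = i)

The posterior mean is a "virtual parent" dosage (Xp′ for the combined
parent of full sibs, Xm′/Xf′ where mother and father are resolvable —
half-sib designs and the X chromosome). These expected dosages enter a
linear mixed model alongside the offspring genotypes:

    Y1 = b·X1 + c·Xp′ + τ + ε1,   Y2 = b·X2 + c·Xp′ + τ + ε2

with a family random intercept τ (variance φ²). For autosomal full sibs
maternal and paternal dosages are indistinguishable, so the combined
parameter c = d + f is estimated; half-sib pairs and X-linked loci resolve
d (maternal) and f (paternal) separately. Likelihood-ratio tests cover
locus detection (omnibus, offspring-only) and effect partitioning
(conditional 1-df tests).

Because every covariance among phenotypes, true dosages and imputed
dosages is available in closed form by exact enumeration of the family
genotype distribution, the package also computes asymptotic power from
non-centrality parameters: ζ per family is the difference in expected
−2 log-likelihood between nested and full models, and power is the
noncentral χ² tail beyond the central critical value. A key quantity is
the variance of the standardized imputed dosage,

    Var(Xp′) = (2H² + 5H + 12) / (4(H + 2)(H + 4)),   H = 2p(1 − p),

verified against the enumeration engine to 1e-12.

## What's inside

- **Imputation** (`impute_sib_parent`, `impute_halfsib_parents`,
  `impute_xsib_parents`, `impute_parents`): posterior parental genotype
  distributions and expected dosages, driven by the exact enumeration
  engine (`enumerate_family_joint`, `genotype_moments`).
- **Moments & power** (`joint_moments`, `model_expectations`,
  `test_spec`, `ncp_per_family`, `power_calc`, `required_n`,
  `required_variance_explained`, `power_grid`): the analytic power
  calculator for all designs and tests.
- **Simulation** (`simulate_families`, `apply_parental_missingness`,
  `simulate_study`): generative family simulator, genotype-dependent
  parental missingness, replication harness.
- **Association** (`fit_pair_mixed_model`, `run_test`,
  `genomewide_scan`, `prs_analysis`): FIML mixed models with a family
  random intercept, LRTs, genome-wide scans, unweighted polygenic-score
  analysis with imputed parental scores.
- **I/O & CLI** (`read_plink`, `write_plink`, `write_parental_dosages`,
  `cli_main` and `inst/cli/parimpute.R`): PLINK .bed/.bim/.fam codec,
  dosage files, and `impute`/`assoc`/`power`/`simulate` subcommands.

## Worked example

```r
library(parimpute)

# Opposite-homozygote siblings force both parents to be heterozygous:
impute_sib_parent(2, 0, locus_spec(0.3))
#> <genotype_distribution>
#> 1
#> 1
#> expected dosage: 1

# How many imputed-parent sibling pairs to partition a parental effect
# explaining 0.1% of phenotypic variance (p = 0.3, phi^2 = 0.2)?
ts <- test_spec("full_sib", "imputed", "cond_parental")
required_n(ts, locus_spec(0.3), trait_model(d = sqrt(0.001), phi2 = 0.2))
#> [1] 40721

# Simulate a cohort, impute the parents, and test:
fam <- simulate_families(5000, "full_sib", 0.3,
                         trait_model(b = sqrt(0.01), d = sqrt(0.01), phi2 = 0.2),
                         seed = 42)
fam <- impute_parents(fam)
run_test(fam, "omnibus", "imputed")
#> <assoc_result> omnibus (imputed parents): LRT=203.2986, df=2, p=7.15e-45, 5000 families
#>               estimate         se
#> (Intercept) 0.003206102 0.01101677
#> offspring   0.122499551 0.01785294
#> parental    0.056719288 0.03253906
```

The omnibus 2-df test detects the locus; `offspring` estimates the direct
effect b (truth 0.1) and `parental` the combined indirect effect c = d + f
(truth 0.1), both on the standardized-dosage scale, each within sampling
error of the truth at this sample size.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/parimpute.R simulate --config sim.cfg --out cohort --seed 7
Rscript inst/cli/parimpute.R impute   --bfile cohort --pairs cohort.pairs --out parents.dosage
Rscript inst/cli/parimpute.R assoc    --bfile cohort --pheno cohort.pheno \
                                      --pairs cohort.pairs --model 1 --out assoc.tsv
```

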