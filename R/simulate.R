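# Generative family simulator: genotypes by Mendelian transmission from HWE
# parents, phenotypes from the additive trait models, genotype-dependent
# parental missingness, and the replication harness used to check the
# asymptotic theory.

.transmit <- function(g, n) stats::rbinom(n, 1L, g / 2)

# Per-locus genetic variance of one phenotype, in standardized units.
# Autosomal designs: b^2 + d^2 + f^2 + bd + bf (independent of p).
# X designs: sex-specific, male dosages carry variance 2.
.genetic_variance <- function(model, chrom_type, sex = NULL) {
  b <- model$b; d <- model$d; f <- model$f
  if (chrom_type == "autosomal") {
    b^2 + d^2 + f^2 + b * d + b * f
  } else if (sex == "male") {
    2 * b^2 + d^2 + 2 * f^2 + 2 * b * d
  } else {
    b^2 + d^2 + 2 * f^2 + b * d + 2 * b * f
  }
}

#' Simulate relative-pair families
#'
#' Draws parental genotypes from Hardy-Weinberg equilibrium at each locus
#' (loci independent, i.e. linkage equilibrium), generates offspring by
#' Mendelian transmission (so segregation variance arises naturally), and
#' builds phenotypes as the sum over loci of standardized genetic effects
#' plus a shared N(0, phi2) family effect and independent residuals scaled so
#' each phenotype has unit variance.
#'
#' @param n_families Number of families.
#' @param design `"full_sib"`, `"maternal_half_sib"` or
#'   `"paternal_half_sib"`.
#' @param p Allele frequency, or a vector of per-locus frequencies.
#' @param model A [trait_model()]; coefficients apply per locus.
#' @param chrom_type `"autosomal"` or `"X"` (X only for full sibs).
#' @param sexes For X loci, `c(sex1, sex2)` applied to every pair.
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @param pheno_missing Probability that a sibling's phenotype is masked
#'   (singleton families).
#' @return Object of class `family_table`: list with `design`, `chrom_type`,
#'   `sexes`, `p` (per locus), `geno` (matrices n_families x n_loci: `sib1`,
#'   `sib2` and the design's parents), `parent_obs` (logical matrices, TRUE =
#'   genotype observed), `pheno` (n x 2, NA where masked), `model`, and
#'   `imp` (imputed parental dosages, filled by [impute_parents()]).
#' @export
simulate_families <- function(n_families, design, p, model,
                              chrom_type = "autosomal", sexes = NULL,
                              seed = NULL, pheno_missing = 0) {
  .check_design(design)
  stopifnot(inherits(model, "trait_model"), n_families >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_families
  L <- length(p)
  for (pp in p) locus_spec(pp, chrom_type)  # validates frequencies

  draw_parent <- function() {
    m <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
    matrix(m, nrow = n)
  }
  draw_hemi <- function() {
    m <- vapply(p, function(pp) 2L * stats::rbinom(n, 1L, pp), integer(n))
    matrix(m, nrow = n)
  }
  child_from <- function(gm, gf) {
    g <- matrix(0L, n, L)
    for (l in seq_len(L)) {
      g[, l] <- .transmit(gm[, l], n) + .transmit(gf[, l], n)
    }
    g
  }

  if (chrom_type == "X") {
    if (design != "full_sib") {
      stop("unsupported design: X-linked simulation is defined for full sibs")
    }
    if (is.null(sexes) || !all(sexes %in% c("male", "female"))) {
      stop("X-linked simulation requires sexes = c(sex1, sex2)")
    }
    gm <- draw_parent(); gf <- draw_hemi()
    child_x <- function(sex) {
      g <- matrix(0L, n, L)
      for (l in seq_len(L)) {
        mat <- .transmit(gm[, l], n)
        g[, l] <- if (sex == "male") 2L * mat else mat + gf[, l] / 2L
      }
      g
    }
    geno <- list(sib1 = child_x(sexes[1]), sib2 = child_x(sexes[2]),
                 mother = gm, father = gf)
    parents <- c("mother", "father")
  } else if (design == "full_sib") {
    gm <- draw_parent(); gf <- draw_parent()
    geno <- list(sib1 = child_from(gm, gf), sib2 = child_from(gm, gf),
                 mother = gm, father = gf)
    parents <- c("mother", "father")
  } else if (design == "maternal_half_sib") {
    gm <- draw_parent(); gf1 <- draw_parent(); gf2 <- draw_parent()
    geno <- list(sib1 = child_from(gm, gf1), sib2 = child_from(gm, gf2),
                 mother = gm, father1 = gf1, father2 = gf2)
    parents <- c("mother", "father1", "father2")
  } else {
    gf <- draw_parent(); gm1 <- draw_parent(); gm2 <- draw_parent()
    geno <- list(sib1 = child_from(gm1, gf), sib2 = child_from(gm2, gf),
                 father = gf, mother1 = gm1, mother2 = gm2)
    parents <- c("father", "mother1", "mother2")
  }

  # phenotypes: sum of per-locus standardized effects + shared + residual
  std <- function(mat) sweep(sweep(mat, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  genetic_part <- function(sib_idx) {
    b <- model$b; d <- model$d; f <- model$f
    if (design == "full_sib") {
      mother <- "mother"; father <- "father"
    } else if (design == "maternal_half_sib") {
      mother <- "mother"; father <- paste0("father", sib_idx)
    } else {
      mother <- paste0("mother", sib_idx); father <- "father"
    }
    own <- std(geno[[paste0("sib", sib_idx)]])
    rowSums(b * own + d * std(geno[[mother]]) + f * std(geno[[father]]))
  }
  sex_of <- function(i) if (chrom_type == "X") sexes[i] else NULL
  gv1 <- L * .genetic_variance(model, chrom_type, sex_of(1))
  gv2 <- L * .genetic_variance(model, chrom_type, sex_of(2))
  sigma2 <- 1 - c(gv1, gv2) - model$phi2
  if (any(sigma2 <= 0)) {
    stop("invalid model: total genetic + shared variance >= 1 (sigma^2 = ",
         paste(signif(sigma2, 4), collapse = "/"), ")")
  }
  tau <- stats::rnorm(n, 0, sqrt(model$phi2))
  Y1 <- genetic_part(1) + tau + stats::rnorm(n, 0, sqrt(sigma2[1]))
  Y2 <- genetic_part(2) + tau + stats::rnorm(n, 0, sqrt(sigma2[2]))
  pheno <- cbind(Y1 = Y1, Y2 = Y2)
  if (pheno_missing > 0) {
    pheno[matrix(stats::runif(2 * n) < pheno_missing, n, 2)] <- NA_real_
  }

  parent_obs <- lapply(stats::setNames(parents, parents),
                       function(nm) matrix(TRUE, n, L))
  structure(list(design = design, chrom_type = chrom_type,
                 sexes = if (chrom_type == "X") sexes else NULL,
                 n = n, p = p, geno = geno, parent_obs = parent_obs,
                 pheno = pheno, model = model, imp = NULL),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("<family_table> %d %s families, %d locus/loci (%s)%s\n",
              x$n, x$design, length(x$p), x$chrom_type,
              if (is.null(x$imp)) "" else ", parents imputed"))
  invisible(x)
}

#' Genotype-dependent parental missingness mechanism
#'
#' @param mode `"multiplicative"`, `"dominant"`, `"recessive"` or `"none"`.
#'   The named modes default to the standard probability triples
#'   (AA/Aa/aa, where AA carries two copies of the counted allele):
#'   multiplicative 20/30/40\%, dominant 20/40/40\%, recessive 20/20/40\%.
#' @param probs Optional length-3 override `c(pAA, pAa, paa)`.
#' @return Object of class `missingness_mechanism`.
#' @export
missingness_mechanism <- function(mode = c("none", "multiplicative",
                                           "dominant", "recessive"),
                                  probs = NULL) {
  mode <- match.arg(mode)
  if (is.null(probs)) {
    probs <- switch(mode,
                    none = c(0, 0, 0),
                    multiplicative = c(0.2, 0.3, 0.4),
                    dominant = c(0.2, 0.4, 0.4),
                    recessive = c(0.2, 0.2, 0.4))
  }
  stopifnot(length(probs) == 3, all(probs >= 0), all(probs <= 1))
  structure(list(mode = mode, probs = stats::setNames(probs, c("AA", "Aa", "aa"))),
            class = "missingness_mechanism")
}

#' Mask parental genotypes with genotype-dependent probability
#'
#' Each parent is masked independently per locus with the probability
#' attached to their genotype (AA = two copies of the counted allele).
#' Masked parents are flagged in `parent_obs` and require imputation
#' downstream; genotype matrices are left intact so simulation truth remains
#' available for bias assessment.
#'
#' @param fam A [simulate_families()] table.
#' @param mech A [missingness_mechanism()].
#' @param seed Optional seed.
#' @return The family table with updated `parent_obs`.
#' @export
apply_parental_missingness <- function(fam, mech, seed = NULL) {
  stopifnot(inherits(fam, "family_table"),
            inherits(mech, "missingness_mechanism"))
  if (!is.null(seed)) set.seed(seed)
  if (mech$mode == "none" && all(mech$probs == 0)) return(fam)
  # probs indexed AA, Aa, aa = genotype codes 2, 1, 0
  pr_by_code <- c(mech$probs["aa"], mech$probs["Aa"], mech$probs["AA"])
  for (nm in names(fam$parent_obs)) {
    g <- fam$geno[[nm]]
    # raw codes index the triple directly (hemizygous 0/2 map to aa/AA)
    miss <- matrix(stats::runif(length(g)) < pr_by_code[g + 1],
                   nrow(g), ncol(g))
    fam$parent_obs[[nm]] <- fam$parent_obs[[nm]] & !miss
  }
  fam
}

#' Fill imputed parental dosages for a family table
#'
#' Computes the Bayes-posterior expected parental dosages for every family
#' and locus from the sibling-pair genotypes, via the enumeration engine.
#' Autosomal full sibs get a single combined-parent dosage; half sibs get
#' shared- and own-parent dosages; X-linked full sibs get separate maternal
#' and paternal dosages.
#'
#' @param fam A `family_table`.
#' @param use_sample_freq If TRUE, allele frequencies are estimated from the
#'   sibling genotypes (each individual counted once) instead of the
#'   generative truth, as a genotypes-only pipeline would do.
#' @return The family table with `imp` filled (list of matrices, raw 0--2
#'   scale).
#' @export
impute_parents <- function(fam, use_sample_freq = FALSE) {
  stopifnot(inherits(fam, "family_table"))
  n <- fam$n; L <- length(fam$p)
  p_use <- if (use_sample_freq) {
    colMeans(rbind(fam$geno$sib1, fam$geno$sib2)) / 2
  } else fam$p
  roles <- .imputed_roles(fam$design, fam$chrom_type)
  imp <- lapply(stats::setNames(roles$out, roles$out),
                function(nm) matrix(NA_real_, n, L))
  for (l in seq_len(L)) {
    loc <- locus_spec(p_use[l], fam$chrom_type)
    hat <- .impute_pair_vec(fam$geno$sib1[, l], fam$geno$sib2[, l],
                            roles$design, loc, sexes = fam$sexes)
    for (i in seq_along(roles$out)) {
      imp[[roles$out[i]]][, l] <- hat[[roles$hat_cols[i]]]
    }
  }
  fam$imp <- imp
  fam$imp_freq <- p_use
  fam
}

.imputed_roles <- function(design, chrom_type) {
  if (chrom_type == "X") {
    list(design = "full_sib", out = c("mother", "father"),
         hat_cols = c("gm_hat", "gf_hat"))
  } else if (design == "full_sib") {
    list(design = "full_sib", out = "parent", hat_cols = "gp_hat")
  } else if (design == "maternal_half_sib") {
    list(design = design, out = c("mother", "father1", "father2"),
         hat_cols = c("gm_hat", "gf1_hat", "gf2_hat"))
  } else {
    list(design = design, out = c("father", "mother1", "mother2"),
         hat_cols = c("gf_hat", "gm1_hat", "gm2_hat"))
  }
}

#' Replication study of bias, power and type 1 error
#'
#' Runs the full simulate -> impute -> fit -> test pipeline over a grid of
#' generative conditions, with per-replication seeds derived from the master
#' seed by counter so individual replicates are independently reproducible.
#' Reports mean and SD of the fitted coefficients and empirical rejection
#' rates per test, alongside the asymptotic power from the moment engine.
#'
#' @param conditions Data frame with columns `b2`, `d2`, `f2` (variances
#'   explained; optional `sign_b` etc. for discordant effects), `p`, `phi2`.
#' @param design,parent_mode Study design and parental availability.
#' @param model_ids Tests to run each replicate.
#' @param n_families,n_reps,alpha Study dimensions.
#' @param seed Master seed.
#' @return Data frame, one row per condition x test, with empirical and
#'   asymptotic operating characteristics and coefficient summaries.
#' @export
simulate_study <- function(conditions, design = "full_sib",
                           parent_mode = "imputed",
                           model_ids = c("omnibus", "cond_parental"),
                           n_families = 2000, n_reps = 1000, alpha = 0.05,
                           seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L,
                          nrow(conditions) * n_reps)
  out <- list()
  ctr <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    sgn <- function(nm) if (nm %in% names(cond)) cond[[nm]] else 1
    model <- trait_model(b = sgn("sign_b") * sqrt(cond$b2),
                         d = sgn("sign_d") * sqrt(cond$d2),
                         f = sgn("sign_f") * sqrt(cond$f2),
                         phi2 = cond$phi2)
    loc <- locus_spec(cond$p)
    rejections <- matrix(0, n_reps, length(model_ids),
                         dimnames = list(NULL, model_ids))
    est <- NULL
    n_err <- 0L
    for (r in seq_len(n_reps)) {
      ctr <- ctr + 1L
      res <- tryCatch({
        fam <- simulate_families(n_families, design, cond$p, model,
                                 seed = rep_seeds[ctr])
        if (parent_mode == "imputed") fam <- impute_parents(fam)
        lapply(model_ids, function(mid) run_test(fam, mid, parent_mode))
      }, error = function(e) e)
      if (inherits(res, "error")) { n_err <- n_err + 1L; next }
      for (j in seq_along(model_ids)) {
        rejections[r, j] <- res[[j]]$p_value < alpha
      }
      full_est <- res[[1]]$estimates
      gen <- setdiff(names(full_est), "(Intercept)")
      if (is.null(est)) {
        est <- matrix(NA_real_, n_reps, length(gen),
                      dimnames = list(NULL, gen))
      }
      est[r, gen] <- full_est[gen]
    }
    for (j in seq_along(model_ids)) {
      ts <- test_spec(design, parent_mode, model_ids[j])
      asym <- power_calc(ts, loc, model, n_families, alpha)
      row <- data.frame(cond, test = model_ids[j],
                        n_families = n_families, n_reps = n_reps,
                        alpha = alpha,
                        empirical_power = mean(rejections[, j]),
                        asymptotic_power = asym$power,
                        zeta_per_family = asym$zeta_per_family,
                        df = asym$df, n_errors = n_err,
                        row.names = NULL)
      if (!is.null(est)) {
        for (g in colnames(est)) {
          row[[paste0("mean_", g)]] <- mean(est[, g], na.rm = TRUE)
          row[[paste0("sd_", g)]] <- stats::sd(est[, g], na.rm = TRUE)
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
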