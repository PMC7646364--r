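# FIML mixed-model fitting, likelihood-ratio tests, and the polygenic-score
# analysis.

test_that("FIML fit agrees with lme4 maximum likelihood on the same data", {
  fam <- impute_parents(simulate_families(1500, "full_sib", 0.3,
                                          std_model(b2 = 0.004, d2 = 0.004),
                                          seed = 14))
  loc <- locus_spec(0.3)
  y <- as.vector(t(fam$pheno))
  x1 <- as.vector(rbind(standardize_dosage(fam$geno$sib1[, 1], loc),
                        standardize_dosage(fam$geno$sib2[, 1], loc)))
  xp <- standardize_dosage(fam$imp$parent[, 1], loc)
  xp <- as.vector(rbind(xp, xp))
  id <- rep(seq_len(fam$n), each = 2)
  fit <- fit_pair_mixed_model(y, cbind(own = x1, par = xp), id)
  lm4 <- lme4::lmer(y ~ x1 + xp + (1 | id), REML = FALSE)
  expect_equal(fit$m2ll, -2 * as.numeric(stats::logLik(lm4)), tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lm4)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(fit$phi2, vc$vcov[vc$grp == "id"], tolerance = 1e-3)
  expect_equal(fit$sigma2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
})

test_that("singleton families contribute through the marginal likelihood", {
  fam <- impute_parents(simulate_families(1200, "full_sib", 0.3,
                                          std_model(), seed = 15,
                                          pheno_missing = 0.15))
  res <- run_test(fam, "omnibus", "imputed")
  expect_equal(res$df, 2)
  expect_true(res$lrt >= 0)
  # cross-check against lme4 with the same incomplete data
  loc <- locus_spec(0.3)
  y <- as.vector(t(fam$pheno))
  x1 <- as.vector(rbind(standardize_dosage(fam$geno$sib1[, 1], loc),
                        standardize_dosage(fam$geno$sib2[, 1], loc)))
  id <- rep(seq_len(fam$n), each = 2)
  keep <- is.finite(y)
  fit <- fit_pair_mixed_model(y, cbind(x1 = x1), id)
  dd <- data.frame(y = y[keep], x1 = x1[keep], id = id[keep])
  lm4 <- lme4::lmer(y ~ x1 + (1 | id), data = dd, REML = FALSE)
  expect_equal(fit$m2ll, -2 * as.numeric(stats::logLik(lm4)), tolerance = 1e-5)
})

test_that("degenerate and collinear designs raise informative errors", {
  fam <- impute_parents(simulate_families(300, "full_sib", 0.3, std_model(),
                                          seed = 16))
  y <- as.vector(t(fam$pheno))
  id <- rep(seq_len(fam$n), each = 2)
  expect_error(fit_pair_mixed_model(y, cbind(flat = rep(1, length(y))), id),
               "zero-variance")
  x <- rnorm(length(y))
  expect_error(fit_pair_mixed_model(y, cbind(a = x, b = 2 * x), id),
               "collinear")
  expect_error(fit_pair_mixed_model(y[1:2], NULL, id[1:2]), "2 families")
})

test_that("zero shared variance pushes phi2 to the boundary and matches OLS", {
  fam <- impute_parents(simulate_families(4000, "full_sib", 0.3,
                                          trait_model(b = sqrt(0.005)),
                                          seed = 17))
  loc <- locus_spec(0.3)
  y <- as.vector(t(fam$pheno))
  x1 <- as.vector(rbind(standardize_dosage(fam$geno$sib1[, 1], loc),
                        standardize_dosage(fam$geno$sib2[, 1], loc)))
  id <- rep(seq_len(fam$n), each = 2)
  fit <- fit_pair_mixed_model(y, cbind(x1 = x1), id)
  expect_lt(fit$phi2, 0.01)
  ols <- stats::lm(y ~ x1)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 0.02)
})

test_that("LRT is invariant to affine transformation of regressors", {
  fam <- impute_parents(simulate_families(800, "full_sib", 0.4,
                                          std_model(b2 = 0.005, d2 = 0.005),
                                          seed = 18))
  r_std <- run_test(fam, "omnibus", "imputed")
  r_raw <- run_test(fam, "omnibus", "imputed", use_sample_freq = TRUE)
  expect_equal(r_std$lrt, r_raw$lrt, tolerance = 1e-4)
})

test_that("null LRT follows its chi-square reference distribution", {
  reps <- 300; n <- 400
  set.seed(19)
  seeds <- sample.int(1e7, reps)
  lrt <- t(vapply(seeds, function(s) {
    fam <- impute_parents(simulate_families(n, "full_sib", 0.5,
                                            trait_model(phi2 = 0.2),
                                            seed = s))
    c(run_test(fam, "omnibus", "imputed")$lrt,
      run_test(fam, "cond_parental", "imputed")$lrt)
  }, numeric(2)))
  expect_lt(abs(mean(lrt[, 1]) - 2), 4 * sqrt(2 * 2 * 2 / reps))
  ks1 <- stats::ks.test(lrt[, 1], stats::pchisq, df = 2)
  ks2 <- stats::ks.test(lrt[, 2], stats::pchisq, df = 1)
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
})

test_that("parameter recovery with imputed parents is unbiased at scale", {
  b <- sqrt(0.001); d <- sqrt(0.001); f <- sqrt(0.001)
  fam <- impute_parents(simulate_families(20000, "full_sib", 0.3,
                                          trait_model(b, d, f, 0.2),
                                          seed = 20))
  res <- run_test(fam, "omnibus", "imputed")
  expect_lt(abs(res$estimates[["offspring"]] - b), 3 * res$se[["offspring"]])
  expect_lt(abs(res$estimates[["parental"]] - (d + f)),
            3 * res$se[["parental"]])
  # half-sib design resolves the maternal term
  hs <- impute_parents(simulate_families(20000, "maternal_half_sib", 0.3,
                                         trait_model(b, d, 0, 0.2),
                                         seed = 22))
  rhs <- run_test(hs, "omnibus", "imputed")
  expect_lt(abs(rhs$estimates[["maternal"]] - d), 3 * rhs$se[["maternal"]])
})

test_that("male-male X pairs yield a degenerate imputed paternal test", {
  fam <- impute_parents(simulate_families(500, "full_sib", 0.3,
                                          std_model(), chrom_type = "X",
                                          sexes = c("male", "male"),
                                          seed = 23))
  expect_equal(stats::var(fam$imp$father[, 1]), 0)
  res <- run_test(fam, "cond_paternal", "imputed")
  expect_equal(res$lrt, 0)
  expect_equal(res$p_value, 1)
})

test_that("PRS analysis recovers own and parental score effects", {
  L <- 500
  b <- sqrt(2e-4); d <- sqrt(2e-4)
  model <- trait_model(b = b, d = d, phi2 = 0.1)
  fam <- impute_parents(simulate_families(2000, "full_sib", rep(0.3, L),
                                          model, seed = 24))
  sexcov <- rep(rep(c(1, 0), length.out = 2), fam$n)  # Table-1-style 1/0 sex
  fit <- prs_analysis(fam, covariates = cbind(sex = sexcov))
  # raw unweighted scores: coefficients are the per-locus standardized
  # effects rescaled by the common raw-dosage SD
  scale <- sqrt(2 * 0.3 * 0.7)
  expect_lt(abs(fit$beta[["own_score"]] - b / scale),
            3 * fit$se[["own_score"]])
  expect_lt(abs(fit$beta[["parental_score"]] - d / scale),
            3 * fit$se[["parental_score"]])
  # orientation flip negates the score effect
  fit2 <- prs_analysis(fam, orientation = rep(-1, L))
  expect_lt(abs(fit2$beta[["own_score"]] + b / scale),
            3 * fit2$se[["own_score"]])
  # all-reference individual scores are zero under positive orientation
  own0 <- prs_analysis(impute_parents(simulate_families(
    10, "full_sib", rep(0.5, 3), trait_model(phi2 = 0.1), seed = 1)))
  expect_true(is.finite(own0$m2ll))
  expect_message(prs_analysis(fam, snp_subset = c(1:10, 9999)), "absent")
})
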