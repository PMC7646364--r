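# Bayes posteriors for parental genotypes, the enumeration engine, and the
# covariance identities that the power theory relies on.

test_that("enumeration tables are proper joint distributions with HWE margins", {
  for (design in c("full_sib", "maternal_half_sib", "paternal_half_sib")) {
    for (p in c(0.1, 0.3, 0.5, 0.8)) {
      fj <- enumerate_family_joint(design, locus_spec(p))
      tab <- fj$table
      expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
      hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      marg <- tapply(tab$prob, tab$g1, sum)
      expect_equal(as.numeric(marg), hwe, tolerance = 1e-12)
    }
  }
  for (sx in x_sex_configs) {
    fj <- enumerate_family_joint("full_sib", locus_spec(0.3, "X"), sexes = sx)
    expect_equal(sum(fj$table$prob), 1, tolerance = 1e-12)
  }
})

test_that("opposite sibling homozygotes force heterozygous parents", {
  for (p in c(0.05, 0.3, 0.9)) {
    d <- impute_sib_parent(2, 0, locus_spec(p))
    expect_equal(d$support, 1)
    expect_equal(d$probs, 1)
    expect_equal(d$expected_dosage, 1)
  }
  # shared mother of opposite-homozygote half sibs must also be Aa
  hs <- impute_halfsib_parents(2, 0, locus_spec(0.4))
  expect_equal(hs$shared$support, 1)
  expect_equal(hs$shared$expected_dosage, 1)
})

test_that("double-homozygote sib pair posterior matches hand enumeration", {
  # g1 = g2 = 2 at p = 0.5: parent posterior {AA: 2/3, Aa: 1/3}
  d <- impute_sib_parent(2, 2, locus_spec(0.5))
  expect_equal(d$probs[match(2, d$support)], 2 / 3, tolerance = 1e-12)
  expect_equal(d$probs[match(1, d$support)], 1 / 3, tolerance = 1e-12)
  expect_equal(d$expected_dosage, 5 / 3, tolerance = 1e-12)
  # allele-flip mirror
  d0 <- impute_sib_parent(0, 0, locus_spec(0.5))
  expect_equal(d0$expected_dosage, 1 / 3, tolerance = 1e-12)
})

test_that("half-sib father posteriors split by which child carries the allele", {
  hs <- impute_halfsib_parents(2, 0, locus_spec(0.5))
  # father of the AA child: prior x P(transmit A) -> {AA: 1/2, Aa: 1/2}
  expect_equal(hs$other1$expected_dosage, 1.5, tolerance = 1e-12)
  expect_equal(hs$other2$expected_dosage, 0.5, tolerance = 1e-12)
  # swap symmetry
  hs2 <- impute_halfsib_parents(0, 2, locus_spec(0.5))
  expect_equal(hs2$other1$expected_dosage, 0.5, tolerance = 1e-12)
  expect_equal(hs2$other2$expected_dosage, 1.5, tolerance = 1e-12)
})

test_that("X-linked posteriors: sons are uninformative for fathers", {
  locx <- locus_spec(0.3, "X")
  mm <- impute_xsib_parents(2, 0, "male", "male", locx)
  expect_equal(mm$mother$support, 1)
  expect_equal(mm$mother$expected_dosage, 1)
  # paternal posterior equals the HWE prior
  expect_equal(mm$father$expected_dosage, 2 * 0.3, tolerance = 1e-12)
  expect_equal(mm$father$probs[match(2, mm$father$support)], 0.3,
               tolerance = 1e-12)

  # two AA sisters force a hemizygous-A father; mother as in the autosomal
  # double-transmission case
  ff <- impute_xsib_parents(2, 2, "female", "female", locus_spec(0.5, "X"))
  expect_equal(ff$father$support, 2)
  expect_equal(ff$father$expected_dosage, 2)
  expect_equal(ff$mother$expected_dosage, 5 / 3, tolerance = 1e-12)

  # brother AA, sister aa: father must lack the allele, mother heterozygous
  mf <- impute_xsib_parents(2, 0, "male", "female", locus_spec(0.3, "X"))
  expect_equal(mf$father$expected_dosage, 0)
  expect_equal(mf$mother$expected_dosage, 1)
})

test_that("invalid genotype codes and designs are rejected", {
  expect_error(locus_spec(0), "degenerate locus")
  expect_error(locus_spec(1), "degenerate locus")
  expect_error(impute_xsib_parents(1, 0, "male", "female", locus_spec(0.3, "X")),
               "hemizygote")
  expect_error(impute_halfsib_parents(2, 0, locus_spec(0.3, "X")),
               "unsupported design")
  expect_error(enumerate_family_joint("avuncular", locus_spec(0.3)),
               "unsupported design")
  expect_error(impute_sib_parent(3, 0, locus_spec(0.3)), "invalid g1")
})

test_that("posteriors are exchangeable in the sibs and allele-flip symmetric", {
  loc <- locus_spec(0.23)
  flip <- locus_spec(0.77)
  for (g1 in 0:2) for (g2 in 0:2) {
    a <- impute_sib_parent(g1, g2, loc)
    bb <- impute_sib_parent(g2, g1, loc)
    expect_equal(a$expected_dosage, bb$expected_dosage, tolerance = 1e-12)
    fl <- impute_sib_parent(2 - g1, 2 - g2, flip)
    expect_equal(a$expected_dosage, 2 - fl$expected_dosage, tolerance = 1e-12)
    expect_true(all(a$probs >= 0), info = "nonnegative posterior")
    expect_equal(sum(a$probs), 1, tolerance = 1e-12)
    expect_true(a$expected_dosage >= 0 && a$expected_dosage <= 2)
  }
})

test_that("imputed dosages average to the population mean over sib pairs", {
  for (p in c(0.1, 0.5, 0.72)) {
    fj <- enumerate_family_joint("full_sib", locus_spec(p))
    expect_equal(sum(fj$table$prob * fj$table$gp_hat), 2 * p,
                 tolerance = 1e-12)
    hj <- enumerate_family_joint("maternal_half_sib", locus_spec(p))
    expect_equal(sum(hj$table$prob * hj$table$gm_hat), 2 * p,
                 tolerance = 1e-12)
    expect_equal(sum(hj$table$prob * hj$table$gf1_hat), 2 * p,
                 tolerance = 1e-12)
  }
})

test_that("Cov(actual parent, imputed parent) equals Var(imputed parent)", {
  C <- genotype_moments(enumerate_family_joint("full_sib", locus_spec(0.3)))
  expect_equal(C["Xm", "Xp_hat"], C["Xp_hat", "Xp_hat"], tolerance = 1e-12)
  expect_equal(C["Xf", "Xp_hat"], C["Xp_hat", "Xp_hat"], tolerance = 1e-12)
  H <- genotype_moments(enumerate_family_joint("maternal_half_sib",
                                               locus_spec(0.3)))
  expect_equal(H["Xm", "Xm_hat"], H["Xm_hat", "Xm_hat"], tolerance = 1e-12)
  expect_equal(H["Xf1", "Xf1_hat"], H["Xf1_hat", "Xf1_hat"], tolerance = 1e-12)
})

test_that("closed-form Var(Xp') matches the enumeration oracle across p", {
  for (p in p_grid) {
    loc <- locus_spec(p)
    expect_equal(imputed_parent_variance(loc),
                 imputed_parent_variance(loc, "enumeration"),
                 tolerance = 1e-12)
  }
  # monotone decreasing in H, bracketed by the normal-projection bound 1/3
  vals <- sapply(sort(2 * p_grid * (1 - p_grid)), function(H) {
    p <- (1 - sqrt(1 - 2 * H)) / 2
    imputed_parent_variance(locus_spec(max(p, 1e-6)))
  })
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 1 / 3 - 1e-12 & vals <= 0.375 + 1e-12))
  expect_equal(imputed_parent_variance(locus_spec(0.5)), 1 / 3,
               tolerance = 1e-12)
})

test_that("autosomal and X covariance identities hold exactly by enumeration", {
  C <- genotype_moments(enumerate_family_joint("full_sib", locus_spec(0.3)))
  for (pair in list(c("X1", "X2"), c("X1", "Xm"), c("X2", "Xm"),
                    c("X1", "Xf"), c("X2", "Xf"),
                    c("Xp_hat", "X1"), c("Xp_hat", "X2"))) {
    expect_equal(C[pair[1], pair[2]], 0.5, tolerance = 1e-12,
                 info = paste(pair, collapse = "-"))
  }
  # X: seven printed sex-dependent covariances
  Cmm <- genotype_moments(enumerate_family_joint("full_sib",
                                                 locus_spec(0.3, "X"),
                                                 sexes = x_sex_configs$mm))
  Cff <- genotype_moments(enumerate_family_joint("full_sib",
                                                 locus_spec(0.3, "X"),
                                                 sexes = x_sex_configs$ff))
  Cmf <- genotype_moments(enumerate_family_joint("full_sib",
                                                 locus_spec(0.3, "X"),
                                                 sexes = x_sex_configs$mf))
  expect_equal(Cff["X2", "Xm"], 0.5, tolerance = 1e-12)   # mother-daughter
  expect_equal(Cmm["X1", "Xm"], 1, tolerance = 1e-12)     # mother-son
  expect_equal(Cff["X2", "Xf"], 1, tolerance = 1e-12)     # father-daughter
  expect_equal(Cmm["X1", "Xf"], 0, tolerance = 1e-12)     # father-son
  expect_equal(Cmm["X1", "X2"], 1, tolerance = 1e-12)     # brother-brother
  expect_equal(Cff["X1", "X2"], 0.75, tolerance = 1e-12)  # sister-sister
  expect_equal(Cmf["X1", "X2"], 0.5, tolerance = 1e-12)   # brother-sister
  # male dosages carry twice the female variance
  expect_equal(Cmm["X1", "X1"], 2, tolerance = 1e-12)
  expect_equal(Cff["X1", "X1"], 1, tolerance = 1e-12)
})

test_that("standardization constants behave as documented", {
  loc <- locus_spec(0.3)
  expect_equal(standardize_dosage(2 * 0.3, loc), 0)
  g <- 0:2
  w <- c(0.7^2, 2 * 0.3 * 0.7, 0.3^2)
  z <- standardize_dosage(g, loc)
  expect_equal(sum(w * z), 0, tolerance = 1e-12)
  expect_equal(sum(w * z^2), 1, tolerance = 1e-12)
  # male X raw codes 0/2 under the female constants: variance 2
  zx <- standardize_dosage(c(0, 2), locus_spec(0.3, "X"))
  wx <- c(0.7, 0.3)
  expect_equal(sum(wx * zx^2) - sum(wx * zx)^2, 2, tolerance = 1e-12)
})
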