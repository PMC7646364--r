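# Full-information maximum-likelihood fitting of the conditional association
# models on family data, likelihood-ratio tests, genome-wide scan, and
# polygenic-score analysis.

#' Fit a linear mixed model with a family random intercept by FIML
#'
#' Maximizes the exact multivariate-normal likelihood of per-family phenotype
#' vectors with mean `X beta` and covariance `sigma2 * I + phi2 * J` (J the
#' all-ones matrix), families independent. Pairs contribute a bivariate term;
#' families with a single phenotyped member contribute a univariate term with
#' variance `sigma2 + phi2`. Coefficients are profiled out by GLS at each
#' variance-component evaluation; the two-parameter profile likelihood is
#' maximized by bounded quasi-Newton with `phi2` constrained to be
#' nonnegative.
#'
#' @param y Numeric response vector (one element per phenotyped individual).
#' @param X Design matrix (same rows as `y`), or NULL for an intercept-only
#'   model.
#' @param fam_id Family identifier per row; members of a family share the
#'   random intercept. At most 2 phenotyped members per family.
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @return Object of class `fiml_fit`: `beta`, `se`, `vcov`, `sigma2`,
#'   `phi2`, `m2ll` (minus two log-likelihood), `n_obs`, `n_fam`,
#'   `converged`.
#' @export
fit_pair_mixed_model <- function(y, X = NULL, fam_id, add_intercept = TRUE) {
  keep <- is.finite(y)
  if (!is.null(X)) keep <- keep & stats::complete.cases(X)
  y <- y[keep]; fam_id <- fam_id[keep]
  X <- if (is.null(X)) matrix(numeric(0), length(y), 0) else as.matrix(X)[keep, , drop = FALSE]
  if (add_intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  n <- length(y)
  uf <- unique(fam_id)
  if (length(uf) < 2) stop("need at least 2 families")
  if (ncol(X) > 0) {
    zv <- apply(X, 2, function(col) stats::var(col) < 1e-14) &
      colnames(X) != "(Intercept)"
    if (any(zv)) {
      stop("collinear design: zero-variance regressor(s): ",
           paste(colnames(X)[zv], collapse = ", "))
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("collinear design: ", paste(bad, collapse = ", "),
           " linearly dependent on the other regressors")
    }
  }

  # orthogonal within-family rotation: pair (sum, diff)/sqrt(2) have
  # variances sigma2 + 2*phi2 and sigma2; singletons sigma2 + phi2
  ord <- order(match(fam_id, uf))
  y <- y[ord]; X <- X[ord, , drop = FALSE]; fam_id <- fam_id[ord]
  sizes <- table(factor(fam_id, levels = uf))
  if (any(sizes > 2)) stop("families with more than 2 phenotyped members are not supported")
  first <- cumsum(c(1, sizes[-length(sizes)]))
  is_pair <- sizes == 2
  i1 <- first[is_pair]; i2 <- i1 + 1L
  is1 <- first[!is_pair]
  r2 <- 1 / sqrt(2)
  Ty <- c((y[i1] + y[i2]) * r2, (y[i1] - y[i2]) * r2, y[is1])
  TX <- rbind((X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) * r2,
              (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) * r2,
              X[is1, , drop = FALSE])
  cls <- rep(1:3, c(length(i1), length(i1), length(is1)))

  profile <- function(par) {
    s <- exp(par[1]); f <- par[2]
    v <- c(s + 2 * f, s, s + f)[cls]
    w <- 1 / v
    if (ncol(TX) > 0) {
      XtW <- TX * w
      A <- crossprod(XtW, TX)
      beta <- solve(A, crossprod(XtW, Ty))
      r <- Ty - drop(TX %*% beta)
    } else {
      beta <- numeric(0); r <- Ty
    }
    m2ll <- sum(log(v)) + sum(r^2 * w) + n * log(2 * pi)
    list(m2ll = m2ll, beta = beta, w = w)
  }
  v0 <- stats::var(y)
  opt <- stats::optim(c(log(0.7 * v0 + 1e-8), 0.2 * v0),
                      function(par) profile(par)$m2ll,
                      method = "L-BFGS-B",
                      lower = c(log(1e-10), 0),
                      upper = c(log(1e6 * v0 + 1), 50 * v0 + 1),
                      control = list(factr = 1e4))
  fit <- profile(opt$par)
  s <- exp(opt$par[1]); f <- opt$par[2]
  if (ncol(TX) > 0) {
    A <- crossprod(TX * fit$w, TX)
    vc <- solve(A)
    beta <- stats::setNames(drop(fit$beta), colnames(X))
    se <- stats::setNames(sqrt(diag(vc)), colnames(X))
  } else {
    vc <- matrix(0, 0, 0); beta <- numeric(0); se <- numeric(0)
  }
  structure(list(beta = beta, se = se, vcov = vc, sigma2 = s, phi2 = f,
                 m2ll = fit$m2ll, n_obs = n, n_fam = length(uf),
                 converged = opt$convergence == 0,
                 optim_message = opt$message),
            class = "fiml_fit")
}

#' @export
print.fiml_fit <- function(x, ...) {
  cat(sprintf("<fiml_fit> n=%d (%d families), -2lnL=%.4f, sigma2=%.4f, phi2=%.4f\n",
              x$n_obs, x$n_fam, x$m2ll, x$sigma2, x$phi2))
  if (length(x$beta)) {
    print(data.frame(estimate = x$beta, se = x$se))
  }
  invisible(x)
}

# Build stacked (sib1, sib2 interleaved) regressor columns for a term set on
# a family table, standardized with the table's allele frequencies.
.term_columns <- function(fam, terms, locus_index, use_sample_freq) {
  n <- fam$n
  l <- locus_index
  p_std <- if (use_sample_freq && !is.null(fam$imp_freq)) {
    fam$imp_freq[l]
  } else if (use_sample_freq) {
    mean(c(fam$geno$sib1[, l], fam$geno$sib2[, l])) / 2
  } else fam$p[l]
  loc <- locus_spec(p_std, fam$chrom_type)
  std <- function(v) standardize_dosage(v, loc)
  paircol <- function(v1, v2) as.vector(rbind(std(v1), std(v2)))
  g <- fam$geno; imp <- fam$imp
  need_imp <- function() {
    if (is.null(imp)) stop("imputed parental dosages missing; call impute_parents() first")
  }
  cols <- lapply(names(terms), function(tn) {
    switch(paste(tn, fam$design, fam$chrom_type),
      `offspring full_sib autosomal` = ,
      `offspring full_sib X` = ,
      `offspring maternal_half_sib autosomal` = ,
      `offspring paternal_half_sib autosomal` =
        paircol(g$sib1[, l], g$sib2[, l]),
      `parental full_sib autosomal` = { need_imp()
        paircol(imp$parent[, l], imp$parent[, l]) },
      `maternal full_sib autosomal` = paircol(g$mother[, l], g$mother[, l]),
      `paternal full_sib autosomal` = paircol(g$father[, l], g$father[, l]),
      `maternal full_sib X` = if (identical(terms[[tn]][1], "Xm_hat")) {
        need_imp(); paircol(imp$mother[, l], imp$mother[, l])
      } else paircol(g$mother[, l], g$mother[, l]),
      `paternal full_sib X` = if (identical(terms[[tn]][1], "Xf_hat")) {
        need_imp(); paircol(imp$father[, l], imp$father[, l])
      } else paircol(g$father[, l], g$father[, l]),
      `maternal maternal_half_sib autosomal` = if (identical(terms[[tn]][1], "Xm_hat")) {
        need_imp(); paircol(imp$mother[, l], imp$mother[, l])
      } else paircol(g$mother[, l], g$mother[, l]),
      `paternal maternal_half_sib autosomal` = if (identical(terms[[tn]][1], "Xf1_hat")) {
        need_imp(); paircol(imp$father1[, l], imp$father2[, l])
      } else paircol(g$father1[, l], g$father2[, l]),
      `paternal paternal_half_sib autosomal` = if (identical(terms[[tn]][1], "Xf_hat")) {
        need_imp(); paircol(imp$father[, l], imp$father[, l])
      } else paircol(g$father[, l], g$father[, l]),
      `maternal paternal_half_sib autosomal` = if (identical(terms[[tn]][1], "Xm1_hat")) {
        need_imp(); paircol(imp$mother1[, l], imp$mother2[, l])
      } else paircol(g$mother1[, l], g$mother2[, l]),
      stop("no data mapping for term '", tn, "' in this design")
    )
  })
  names(cols) <- names(terms)
  cols
}

#' Run one association test on a family table
#'
#' Fits the full and nested mixed models of the requested test by FIML and
#' forms the likelihood-ratio statistic. Regressors are standardized
#' genotype/imputed dosages; degenerate (zero-variance) imputed terms — such
#' as the virtual father of male-male sib pairs at X loci — are dropped from
#' both models.
#'
#' @param fam A `family_table` (with `imp` filled when
#'   `parent_mode = "imputed"`).
#' @param model_id Test name, see [test_spec()].
#' @param parent_mode Parental genotype availability.
#' @param locus_index Which locus to test.
#' @param covariates Optional matrix with `2 * n_families` rows (sib1/sib2
#'   interleaved) of fixed covariates.
#' @param use_sample_freq Standardize using sample-estimated allele
#'   frequencies.
#' @return Object of class `assoc_result`: `estimates` and `se` from the
#'   full model, `sigma2`, `phi2`, `lrt`, `df`, `p_value`, `n_fam`,
#'   `model_id`.
#' @export
run_test <- function(fam, model_id, parent_mode, locus_index = 1,
                     covariates = NULL, use_sample_freq = FALSE) {
  stopifnot(inherits(fam, "family_table"))
  ts <- test_spec(fam$design, parent_mode, model_id, fam$chrom_type)
  full_cols <- .term_columns(fam, ts$full, locus_index, use_sample_freq)
  nz <- vapply(full_cols, function(v) stats::var(v) > 1e-12, logical(1))
  full_cols <- full_cols[nz]
  nested_names <- intersect(names(ts$nested), names(full_cols))
  df <- length(full_cols) - length(nested_names)
  y <- as.vector(t(fam$pheno))
  fam_id <- rep(seq_len(fam$n), each = 2)
  build_X <- function(cols) {
    X <- if (length(cols)) do.call(cbind, cols) else NULL
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
    X
  }
  if (df == 0) {
    # every tested term is degenerate in this design; LRT identically 0
    fit_full <- fit_pair_mixed_model(y, build_X(full_cols), fam_id)
    return(structure(list(estimates = fit_full$beta, se = fit_full$se,
                          sigma2 = fit_full$sigma2, phi2 = fit_full$phi2,
                          lrt = 0, df = length(ts$tested), p_value = 1,
                          n_fam = fit_full$n_fam, model_id = model_id,
                          parent_mode = parent_mode),
                     class = "assoc_result"))
  }
  fit_full <- fit_pair_mixed_model(y, build_X(full_cols), fam_id)
  fit_nested <- fit_pair_mixed_model(y, build_X(full_cols[nested_names]), fam_id)
  lrt <- max(fit_nested$m2ll - fit_full$m2ll, 0)
  structure(list(estimates = fit_full$beta, se = fit_full$se,
                 sigma2 = fit_full$sigma2, phi2 = fit_full$phi2,
                 lrt = lrt, df = df,
                 p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
                 n_fam = fit_full$n_fam, model_id = model_id,
                 parent_mode = parent_mode),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s (%s parents): LRT=%.4f, df=%d, p=%.3g, %d families\n",
              x$model_id, x$parent_mode, x$lrt, x$df, x$p_value, x$n_fam))
  if (length(x$estimates)) print(data.frame(estimate = x$estimates, se = x$se))
  invisible(x)
}

#' Genome-wide association scan on relative pairs
#'
#' For each variant in a PLINK-format dataset: retains the defined relative
#' pairs with complete genotypes, estimates the allele frequency from the
#' retained individuals (each counted once), imputes virtual parental
#' dosages, fits the mixed model and forms the requested LRT. Monomorphic or
#' sub-MAF variants and non-converging fits are skipped with a message, not
#' an error.
#'
#' @param dataset A `genotype_dataset` from [read_plink()] or
#'   [as_genotype_dataset()].
#' @param pairs Data frame with columns `fid`, `iid1`, `iid2`, `pair_type`
#'   (`"sib"`, `"msib"`, `"psib"`).
#' @param pheno Data frame with columns `fid`, `iid`, `pheno`.
#' @param model_id Test to run per SNP.
#' @param covariates Optional data frame `fid`, `iid`, then covariate
#'   columns.
#' @param maf_min Minimum minor allele frequency (variants below are
#'   skipped).
#' @return Data frame: one row per retained SNP with columns `snp`, `chr`,
#'   `bp`, `a1`, `freq_a1`, per-term `beta_*`/`se_*`, `lrt`, `df`, `p`,
#'   `n_fam`.
#' @export
genomewide_scan <- function(dataset, pairs, pheno, model_id = "omnibus",
                            covariates = NULL, maf_min = 1e-6) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  need <- c("fid", "iid1", "iid2", "pair_type")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(dataset$fam$fid, dataset$fam$iid)
  idx1 <- match(paste(pairs$fid, pairs$iid1), key)
  idx2 <- match(paste(pairs$fid, pairs$iid2), key)
  ok <- !is.na(idx1) & !is.na(idx2)
  if (!any(ok)) stop("no valid pairs: none of the ", nrow(pairs),
                     " pair definitions matched the genotype data")
  if (any(!ok)) message(sum(!ok), " pair(s) dropped: members absent from genotype data")
  pairs <- pairs[ok, , drop = FALSE]; idx1 <- idx1[ok]; idx2 <- idx2[ok]
  if (length(unique(pairs$pair_type)) > 1) {
    stop("mixed pair types in one scan are not supported; split the pairs file")
  }
  design <- switch(pairs$pair_type[1], sib = "full_sib",
                   msib = "maternal_half_sib", psib = "paternal_half_sib",
                   stop("unknown pair_type '", pairs$pair_type[1], "'"))
  pk <- paste(pheno$fid, pheno$iid)
  y1 <- pheno$pheno[match(paste(pairs$fid, pairs$iid1), pk)]
  y2 <- pheno$pheno[match(paste(pairs$fid, pairs$iid2), pk)]
  covmat <- NULL
  if (!is.null(covariates)) {
    ck <- paste(covariates$fid, covariates$iid)
    cv <- as.matrix(covariates[, setdiff(names(covariates), c("fid", "iid")),
                               drop = FALSE])
    c1 <- cv[match(paste(pairs$fid, pairs$iid1), ck), , drop = FALSE]
    c2 <- cv[match(paste(pairs$fid, pairs$iid2), ck), , drop = FALSE]
    covmat <- matrix(NA_real_, 2 * nrow(c1), ncol(cv),
                     dimnames = list(NULL, colnames(cv)))
    covmat[seq(1, nrow(covmat), 2), ] <- c1
    covmat[seq(2, nrow(covmat), 2), ] <- c2
  }
  rows <- list()
  for (j in seq_len(nrow(dataset$bim))) {
    g1 <- dataset$geno[idx1, j]; g2 <- dataset$geno[idx2, j]
    keep <- !is.na(g1) & !is.na(g2) & is.finite(y1 + y2)
    if (sum(keep) < 2) { message("SNP ", dataset$bim$snp[j], " skipped: <2 complete pairs"); next }
    chrom_type <- if (as.character(dataset$bim$chr[j]) %in% c("X", "23")) "X" else "autosomal"
    p_hat <- mean(c(g1[keep], g2[keep])) / 2
    if (min(p_hat, 1 - p_hat) < maf_min) {
      message("SNP ", dataset$bim$snp[j], " skipped: MAF ",
              signif(min(p_hat, 1 - p_hat), 3), " below threshold")
      next
    }
    fam <- .scan_family_table(design, chrom_type, g1[keep], g2[keep],
                              y1[keep], y2[keep], p_hat,
                              sexes = if (chrom_type == "X") {
                                c(ifelse(dataset$fam$sex[idx1[keep][1]] == 1, "male", "female"),
                                  ifelse(dataset$fam$sex[idx2[keep][1]] == 1, "male", "female"))
                              } else NULL)
    res <- tryCatch(
      run_test(fam, model_id, "imputed", covariates = if (is.null(covmat)) NULL else {
        covmat[rep(keep, each = 2), , drop = FALSE]
      }, use_sample_freq = TRUE),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("SNP ", dataset$bim$snp[j], " skipped: ", conditionMessage(res))
      next
    }
    row <- data.frame(snp = dataset$bim$snp[j], chr = dataset$bim$chr[j],
                      bp = dataset$bim$bp[j], a1 = dataset$bim$a1[j],
                      freq_a1 = p_hat, lrt = res$lrt, df = res$df,
                      p = res$p_value, n_fam = res$n_fam,
                      stringsAsFactors = FALSE)
    for (tn in setdiff(names(res$estimates), "(Intercept)")) {
      row[[paste0("beta_", tn)]] <- res$estimates[[tn]]
      row[[paste0("se_", tn)]] <- res$se[[tn]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no valid pairs/variants: every SNP was skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# single-SNP family table assembled from scan-level vectors
.scan_family_table <- function(design, chrom_type, g1, g2, y1, y2, p_hat,
                               sexes = NULL) {
  fam <- structure(list(design = design, chrom_type = chrom_type,
                        sexes = sexes, n = length(g1), p = p_hat,
                        geno = list(sib1 = matrix(g1, ncol = 1),
                                    sib2 = matrix(g2, ncol = 1)),
                        parent_obs = list(),
                        pheno = cbind(Y1 = y1, Y2 = y2),
                        model = NULL, imp = NULL),
                   class = "family_table")
  impute_parents(fam, use_sample_freq = FALSE)  # p already sample-estimated
}

#' Unweighted polygenic-score analysis with imputed parental scores
#'
#' Builds unweighted polygenic scores as sums of trait-increasing-allele
#' dosages (raw 0--2 scale) for each sibling and for the imputed virtual
#' parent(s), then regresses the phenotype on own score, parental score(s)
#' and covariates with a family random intercept by FIML.
#'
#' @param fam A multi-locus `family_table` with imputed parents.
#' @param orientation Optional vector of +1/-1 per locus: +1 counts the A1
#'   allele as trait-increasing, -1 flips the dosage to `2 - g`. Default all
#'   +1.
#' @param covariates Optional matrix with `2 * n_families` interleaved rows.
#' @param snp_subset Optional integer indices of loci to include; indices
#'   outside the data are dropped with a message.
#' @return A `fiml_fit` with terms `own_score`, plus `parental_score` (full
#'   sibs) or `maternal_score`/`paternal_score` (designs resolving separate
#'   parents).
#' @export
prs_analysis <- function(fam, orientation = NULL, covariates = NULL,
                         snp_subset = NULL) {
  stopifnot(inherits(fam, "family_table"))
  if (is.null(fam$imp)) stop("imputed parental dosages missing; call impute_parents() first")
  L <- length(fam$p)
  idx <- if (is.null(snp_subset)) seq_len(L) else snp_subset
  bad <- idx < 1 | idx > L
  if (any(bad)) {
    message(sum(bad), " requested SNP(s) absent from data; dropped")
    idx <- idx[!bad]
  }
  if (!length(idx)) stop("no SNPs left for score construction")
  orient <- if (is.null(orientation)) rep(1, L) else orientation
  score <- function(gmat) {
    g <- gmat[, idx, drop = FALSE]
    o <- orient[idx]
    rowSums(sweep(g, 2, o, "*") + rep(ifelse(o < 0, 2, 0), each = nrow(g)))
  }
  own <- as.vector(rbind(score(fam$geno$sib1), score(fam$geno$sib2)))
  X <- cbind(own_score = own)
  if (fam$design == "full_sib" && fam$chrom_type == "autosomal") {
    ps <- score(fam$imp$parent)
    X <- cbind(X, parental_score = as.vector(rbind(ps, ps)))
  } else if (fam$chrom_type == "X") {
    ms <- score(fam$imp$mother); fs <- score(fam$imp$father)
    X <- cbind(X, maternal_score = as.vector(rbind(ms, ms)),
               paternal_score = as.vector(rbind(fs, fs)))
  } else if (fam$design == "maternal_half_sib") {
    ms <- score(fam$imp$mother)
    X <- cbind(X, maternal_score = as.vector(rbind(ms, ms)),
               paternal_score = as.vector(rbind(score(fam$imp$father1),
                                                score(fam$imp$father2))))
  } else {
    fs <- score(fam$imp$father)
    X <- cbind(X, paternal_score = as.vector(rbind(fs, fs)),
               maternal_score = as.vector(rbind(score(fam$imp$mother1),
                                                score(fam$imp$mother2))))
  }
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  y <- as.vector(t(fam$pheno))
  fit_pair_mixed_model(y, X, rep(seq_len(fam$n), each = 2))
}
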