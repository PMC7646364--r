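# Expected second-moment structure of phenotypes and regressors under the
# additive trait models, and asymptotic GLS expectations for fitted models.
# These exact moments drive the non-centrality-parameter power machinery.

#' Specify an additive trait model
#'
#' Standardized effect coefficients of the offspring (`b`), maternal (`d`)
#' and paternal (`f`) genotype dosages on the offspring phenotype, plus the
#' shared (family) residual variance `phi2`. The combined parental effect
#' `c = d + f` is derived. Independent residual variance is derived per
#' design so that each phenotype has unit variance; a model whose genetic
#' plus shared variance reaches 1 is invalid.
#'
#' @param b,d,f Standardized effect coefficients.
#' @param phi2 Shared residual variance, >= 0.
#' @return An object of class `trait_model`.
#' @examples
#' trait_model(b = sqrt(0.001), d = sqrt(0.001), phi2 = 0.2)
#' @export
trait_model <- function(b = 0, d = 0, f = 0, phi2 = 0) {
  stopifnot(is.numeric(b), is.numeric(d), is.numeric(f),
            is.numeric(phi2), phi2 >= 0)
  structure(list(b = b, d = d, f = f, c = d + f, phi2 = phi2),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model> b=%g d=%g f=%g (c=%g), phi2=%g\n",
              x$b, x$d, x$f, x$c, x$phi2))
  invisible(x)
}

# Genetic loadings of Y1 and Y2 on the design's true-dosage labels.
.loadings <- function(design, model, labels, chrom_type) {
  b <- model$b; d <- model$d; f <- model$f
  zero <- stats::setNames(numeric(length(labels)), labels)
  L1 <- zero; L2 <- zero
  if (design == "full_sib") {
    L1[c("X1", "Xm", "Xf")] <- c(b, d, f)
    L2[c("X2", "Xm", "Xf")] <- c(b, d, f)
  } else if (design == "maternal_half_sib") {
    L1[c("X1", "Xm", "Xf1")] <- c(b, d, f)
    L2[c("X2", "Xm", "Xf2")] <- c(b, d, f)
  } else if (design == "paternal_half_sib") {
    L1[c("X1", "Xm1", "Xf")] <- c(b, d, f)
    L2[c("X2", "Xm2", "Xf")] <- c(b, d, f)
  } else stop("unsupported design '", design, "'")
  list(L1 = L1, L2 = L2)
}

#' Exact joint moment matrix of phenotypes and dosages
#'
#' Builds the expected covariance matrix of (Y1, Y2) and every true and
#' imputed standardized dosage in the design, by combining the exact genotype
#' covariances from the enumeration engine with the trait model through
#' linearity. Residual variances are chosen so each phenotype has unit
#' variance (per sex for X-linked designs, where male dosages carry variance
#' 2 and hence explain twice the variance at equal coefficients).
#'
#' @param design `"full_sib"`, `"maternal_half_sib"`, `"paternal_half_sib"`.
#' @param locus A [locus_spec()].
#' @param model A [trait_model()].
#' @param sexes For X-linked loci, `c(sex1, sex2)`; opposite-sex pairs are
#'   conventionally ordered male-first.
#' @return Object of class `moment_matrix`: list with `M` (labelled
#'   covariance matrix including Y1, Y2), `sigma2` (length-2 independent
#'   residual variances), `phi2`, `design`, `locus`, `sexes`, `model`.
#' @export
joint_moments <- function(design, locus, model, sexes = NULL) {
  locus <- as_locus(locus)
  stopifnot(inherits(model, "trait_model"))
  joint <- enumerate_family_joint(design, locus, sexes = sexes)
  G <- genotype_moments(joint)
  ld <- .loadings(design, model, colnames(G), locus$chrom_type)
  gvar1 <- drop(t(ld$L1) %*% G %*% ld$L1)
  gvar2 <- drop(t(ld$L2) %*% G %*% ld$L2)
  sigma2 <- 1 - c(gvar1, gvar2) - model$phi2
  if (any(sigma2 <= 0)) {
    stop("invalid model: residual variance sigma^2 = ",
         paste(signif(sigma2, 4), collapse = "/"),
         " is not positive (genetic + shared variance >= 1)")
  }
  labs <- c("Y1", "Y2", colnames(G))
  M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  M[colnames(G), colnames(G)] <- G
  M["Y1", colnames(G)] <- drop(ld$L1 %*% G)
  M["Y2", colnames(G)] <- drop(ld$L2 %*% G)
  M[colnames(G), "Y1"] <- M["Y1", colnames(G)]
  M[colnames(G), "Y2"] <- M["Y2", colnames(G)]
  M["Y1", "Y1"] <- 1
  M["Y2", "Y2"] <- 1
  M["Y1", "Y2"] <- M["Y2", "Y1"] <-
    drop(t(ld$L1) %*% G %*% ld$L2) + model$phi2
  structure(list(M = M, sigma2 = sigma2, phi2 = model$phi2, design = design,
                 locus = locus, sexes = joint$sexes, model = model),
            class = "moment_matrix")
}

#' @export
print.moment_matrix <- function(x, ...) {
  cat(sprintf("<moment_matrix> %s%s, p=%g\n", x$design,
              if (!is.null(x$sexes)) paste0(" X [", paste(x$sexes, collapse = "-"), "]") else "",
              x$locus$p))
  print(round(x$M, 4))
  invisible(x)
}

#' Write a moment matrix to TSV
#' @param mom A `moment_matrix`.
#' @param path Output file.
#' @export
write_moments_tsv <- function(mom, path) {
  utils::write.table(data.frame(label = rownames(mom$M), mom$M,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Regressor term sets available for a design / parent-availability mode.
# Each term maps to the pair of moment labels entering rows (sib1, sib2) of
# the per-family design matrix.
design_terms <- function(design, parent_mode, chrom_type = "autosomal") {
  off <- c("X1", "X2")
  x <- chrom_type == "X"
  terms <- switch(
    parent_mode,
    both_genotyped = {
      if (design == "full_sib") {
        list(offspring = off, maternal = c("Xm", "Xm"), paternal = c("Xf", "Xf"))
      } else if (design == "maternal_half_sib") {
        list(offspring = off, maternal = c("Xm", "Xm"), paternal = c("Xf1", "Xf2"))
      } else {
        list(offspring = off, maternal = c("Xm1", "Xm2"), paternal = c("Xf", "Xf"))
      }
    },
    mother_only = {
      if (design != "full_sib") stop("mother_only mode is defined for full sibs")
      list(offspring = off, maternal = c("Xm", "Xm"))
    },
    father_only = {
      if (design != "full_sib") stop("father_only mode is defined for full sibs")
      list(offspring = off, paternal = c("Xf", "Xf"))
    },
    imputed = {
      if (design == "full_sib" && !x) {
        list(offspring = off, parental = c("Xp_hat", "Xp_hat"))
      } else if (design == "full_sib" && x) {
        list(offspring = off, maternal = c("Xm_hat", "Xm_hat"),
             paternal = c("Xf_hat", "Xf_hat"))
      } else if (design == "maternal_half_sib") {
        list(offspring = off, maternal = c("Xm_hat", "Xm_hat"),
             paternal = c("Xf1_hat", "Xf2_hat"))
      } else {
        list(offspring = off, maternal = c("Xm1_hat", "Xm2_hat"),
             paternal = c("Xf_hat", "Xf_hat"))
      }
    },
    none = list(offspring = off),
    stop("unknown parent_mode '", parent_mode, "'")
  )
  terms
}

#' Asymptotic GLS expectations for a fitted term set
#'
#' Given the exact joint moments and a set of fitted regressor terms,
#' computes the asymptotic (expected) GLS coefficient vector, the expected
#' residual covariance matrix of the sib pair, and the expected minus two
#' log-likelihood per family, `E(-2lnL) = ln|Sigma| + 2`. GLS weighting uses
#' the generative model's residual covariance (independent + shared
#' components); coefficient expectations are invariant to this weighting for
#' the supported designs.
#'
#' @param mom A [joint_moments()] result.
#' @param fitted_terms Named list mapping term names to the pair of moment
#'   labels for sibs 1 and 2 (see `design_terms`), or a character vector of
#'   term names resolved against the moment matrix's design with a
#'   `parent_mode`. Empty list fits the null (no-association) model.
#' @param parent_mode Used only when `fitted_terms` is a character vector.
#' @return List with `coef` (named), `Sigma` (2x2), `e2ll`.
#' @export
model_expectations <- function(mom, fitted_terms, parent_mode = NULL) {
  stopifnot(inherits(mom, "moment_matrix"))
  if (is.character(fitted_terms)) {
    all_terms <- design_terms(mom$design, parent_mode, mom$locus$chrom_type)
    fitted_terms <- all_terms[fitted_terms]
  }
  M <- mom$M
  Y <- c("Y1", "Y2")
  Omega <- diag(mom$sigma2) + mom$phi2
  k <- length(fitted_terms)
  if (k == 0) {
    Sigma <- M[Y, Y]
    return(list(coef = numeric(0), Sigma = Sigma,
                e2ll = log(det(Sigma)) + 2))
  }
  Winv <- solve(Omega)
  A <- matrix(0, k, k)
  v <- numeric(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      A[i, j] <- sum(Winv * M[fitted_terms[[i]], fitted_terms[[j]]])
    }
    v[i] <- sum(Winv * M[fitted_terms[[i]], Y])
  }
  if (rcond(A) < 1e-10) {
    stop("collinear regressors: ", paste(names(fitted_terms), collapse = ", "),
         " are linearly dependent in expectation for this design")
  }
  g <- solve(A, v)
  Sigma <- matrix(0, 2, 2)
  for (r in 1:2) for (s in 1:2) {
    val <- M[Y[r], Y[s]]
    for (j in seq_len(k)) {
      val <- val - g[j] * (M[fitted_terms[[j]][r], Y[s]] +
                           M[fitted_terms[[j]][s], Y[r]])
      for (l in seq_len(k)) {
        val <- val + g[j] * g[l] * M[fitted_terms[[j]][r], fitted_terms[[l]][s]]
      }
    }
    Sigma[r, s] <- val
  }
  list(coef = stats::setNames(g, names(fitted_terms)), Sigma = Sigma,
       e2ll = log(det(Sigma)) + 2)
}
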