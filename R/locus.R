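#' Describe a biallelic locus
#'
#' A locus is characterised by the frequency `p` of the counted allele "A"
#' (PLINK A1 convention) and its chromosome type. Expected heterozygosity
#' `H = 2p(1-p)` is derived, never stored independently.
#'
#' @param p Frequency of the counted allele, strictly inside (0, 1).
#' @param chrom_type `"autosomal"` or `"X"` (non-pseudoautosomal).
#' @return An object of class `locus_spec` with fields `p`, `q`, `H`,
#'   `chrom_type`.
#' @examples
#' loc <- locus_spec(0.3)
#' loc$H  # 2 * 0.3 * 0.7
#' @export
locus_spec <- function(p, chrom_type = c("autosomal", "X")) {
  chrom_type <- match.arg(chrom_type)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("degenerate locus: allele frequency p must lie strictly in (0, 1), got ",
         format(p))
  }
  structure(
    list(p = p, q = 1 - p, H = 2 * p * (1 - p), chrom_type = chrom_type),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s locus, p(A1) = %g, H = %g\n",
              x$chrom_type, x$p, x$H))
  invisible(x)
}

as_locus <- function(locus, chrom_type = "autosomal") {
  if (inherits(locus, "locus_spec")) return(locus)
  locus_spec(locus, chrom_type)
}

#' Standardize a genotype dosage
#'
#' Centers raw A1-allele counts at the population mean `2p` and scales by the
#' autosomal/female-X standard deviation `sqrt(2p(1-p))`. Hemizygous male X
#' genotypes (raw codes 0/2) use the same constants, so that standardized
#' male-X dosages have variance 2 under Hardy-Weinberg equilibrium. Imputed
#' dosages are standardized with the same constants as true dosages, so
#' imputed-dosage variances are below 1.
#'
#' @param raw Numeric vector of raw dosages on the 0--2 scale (expected
#'   dosages are allowed, so any value in \[0, 2\]).
#' @param locus A [locus_spec()] (or bare allele frequency).
#' @param sex Unused for scaling (male X shares the female constants); kept so
#'   callers can be explicit about hemizygote handling.
#' @return Standardized dosages.
#' @export
standardize_dosage <- function(raw, locus, sex = NULL) {
  locus <- as_locus(locus)
  (raw - 2 * locus$p) / sqrt(locus$H)
}

#' Convert variance explained to a standardized effect coefficient
#'
#' The simulation and power interfaces are parameterised by the proportion of
#' phenotypic variance explained by each genetic term together with a sign;
#' the standardized regression coefficient is the signed square root, divided
#' by the standard deviation of the regressor when that regressor does not
#' have unit variance (male-X and paternal-X dosages have variance 2).
#'
#' @param ve Variance explained (e.g. 0.001 for 0.1\%).
#' @param sign +1 or -1.
#' @param regressor_variance Variance of the standardized regressor (1 for
#'   autosomal dosages, 2 for male/paternal X dosages).
#' @return The coefficient.
#' @export
coef_from_ve <- function(ve, sign = 1, regressor_variance = 1) {
  stopifnot(ve >= 0, sign %in% c(-1, 1), regressor_variance > 0)
  sign * sqrt(ve / regressor_variance)
}
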