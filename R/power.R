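# Asymptotic power machinery: non-centrality parameters from expected
# log-likelihood differences, noncentral chi-square power, sample-size and
# effect-size inversion. Mirrors the web-calculator functionality.

.model_ids <- c("omnibus", "offspring_only", "cond_offspring",
                "cond_parental", "cond_maternal", "cond_paternal")

#' Define a likelihood-ratio test on a family design
#'
#' Resolves one of the five association tests into the full and nested
#' regressor term sets it compares, given the design and which parental
#' genotypes are available. Degrees of freedom equal the number of dropped
#' terms.
#'
#' * `omnibus` — all available genetic terms vs none (locus detection).
#' * `offspring_only` — offspring term vs none, parental terms unmodelled.
#' * `cond_offspring` — full model vs full minus the offspring term.
#' * `cond_parental` — full vs full minus the combined parental term
#'   (autosomal full sibs with imputed parents, where maternal and paternal
#'   dosages are indistinguishable).
#' * `cond_maternal` / `cond_paternal` — full vs full minus that term.
#'
#' @param design Family design string.
#' @param parent_mode `"both_genotyped"`, `"mother_only"`, `"father_only"`,
#'   `"imputed"` or `"none"`.
#' @param model_id One of the test names above.
#' @param chrom_type `"autosomal"` or `"X"`.
#' @return Object of class `test_spec` with `full`, `nested` (term lists),
#'   `df`, `tested` (names of dropped terms).
#' @export
test_spec <- function(design, parent_mode, model_id,
                      chrom_type = "autosomal") {
  model_id <- match.arg(model_id, .model_ids)
  terms <- design_terms(design, parent_mode, chrom_type)
  pick <- function(nms) terms[intersect(nms, names(terms))]
  sets <- switch(
    model_id,
    omnibus = list(full = terms, nested = terms[0]),
    offspring_only = list(full = pick("offspring"), nested = terms[0]),
    cond_offspring = list(full = terms, nested = terms[setdiff(names(terms), "offspring")]),
    cond_parental = {
      if (!"parental" %in% names(terms)) {
        stop("cond_parental requires the combined parental term ",
             "(autosomal full sibs with imputed parents); this design has: ",
             paste(names(terms), collapse = ", "))
      }
      list(full = terms, nested = terms[setdiff(names(terms), "parental")])
    },
    cond_maternal = {
      if (!"maternal" %in% names(terms)) {
        stop("cond_maternal unsupported: no separate maternal term for this ",
             "design/parent_mode (autosomal imputed sibs expose only the ",
             "combined parental term)")
      }
      list(full = terms, nested = terms[setdiff(names(terms), "maternal")])
    },
    cond_paternal = {
      if (!"paternal" %in% names(terms)) {
        stop("cond_paternal unsupported: no separate paternal term for this ",
             "design/parent_mode")
      }
      list(full = terms, nested = terms[setdiff(names(terms), "paternal")])
    }
  )
  structure(list(design = design, parent_mode = parent_mode,
                 model_id = model_id, chrom_type = chrom_type,
                 full = sets$full, nested = sets$nested,
                 df = length(sets$full) - length(sets$nested),
                 tested = setdiff(names(sets$full), names(sets$nested))),
            class = "test_spec")
}

#' Per-family non-centrality parameter of a test
#'
#' The expected likelihood-ratio shift per family under the alternative:
#' `zeta = E(-2lnL_nested) - E(-2lnL_full)`, both computed from the exact
#' moment matrix. The total NCP for N independent families is `N * zeta`.
#' Regressor terms with (numerically) zero variance — e.g. the imputed
#' paternal dosage of a male-male sib pair at an X locus, which equals the
#' population prior for every genotype configuration — are dropped from both
#' models; a test whose tested term is degenerate has `zeta = 0`.
#'
#' @param test A [test_spec()].
#' @param locus A [locus_spec()].
#' @param model A [trait_model()].
#' @param sexes For X-linked designs.
#' @return Per-family NCP (>= 0 up to rounding).
#' @export
ncp_per_family <- function(test, locus, model, sexes = NULL) {
  stopifnot(inherits(test, "test_spec"))
  locus <- as_locus(locus, chrom_type = test$chrom_type)
  mom <- joint_moments(test$design, locus, model, sexes = sexes)
  drop_degenerate <- function(terms) {
    keep <- vapply(terms, function(lab) {
      min(mom$M[lab[1], lab[1]], mom$M[lab[2], lab[2]]) > 1e-10
    }, logical(1))
    terms[keep]
  }
  full <- drop_degenerate(test$full)
  nested <- drop_degenerate(test$nested)
  if (length(full) == length(nested)) return(0)
  zeta <- model_expectations(mom, nested)$e2ll -
    model_expectations(mom, full)$e2ll
  max(zeta, 0)
}

#' Power of a noncentral chi-square test
#'
#' Upper-tail probability of the noncentral chi-square distribution with
#' `df` degrees of freedom and non-centrality `zeta_total` beyond the central
#' chi-square critical value at level `alpha`.
#'
#' @param zeta_total Total NCP (per-family NCP times number of families).
#' @param df Degrees of freedom.
#' @param alpha Type 1 error rate.
#' @return Power in \[alpha, 1\].
#' @export
power_from_ncp <- function(zeta_total, df, alpha) {
  stopifnot(zeta_total >= 0, df >= 1, alpha > 0, alpha < 1)
  stats::pchisq(stats::qchisq(1 - alpha, df), df, ncp = zeta_total,
                lower.tail = FALSE)
}

#' Asymptotic power of an association test on relative pairs
#'
#' End-to-end power calculation: builds the exact moment matrix for the
#' design, derives the per-family NCP of the requested test, scales by the
#' number of families and evaluates noncentral chi-square power.
#'
#' @inheritParams ncp_per_family
#' @param n_families Number of independent relative pairs.
#' @param alpha Type 1 error rate (0.05 for effect-partitioning tests;
#'   genome-wide detection conventionally uses 5e-8).
#' @return Object of class `power_result`: list with `zeta_per_family`,
#'   `n_families`, `df`, `alpha`, `power`.
#' @examples
#' ts <- test_spec("full_sib", "imputed", "cond_parental")
#' power_calc(ts, locus_spec(0.3),
#'            trait_model(d = sqrt(0.002), phi2 = 0.2), 20000, 0.05)
#' @export
power_calc <- function(test, locus, model, n_families, alpha = 0.05,
                       sexes = NULL) {
  zeta <- ncp_per_family(test, locus, model, sexes = sexes)
  structure(list(zeta_per_family = zeta, n_families = n_families,
                 df = test$df, alpha = alpha,
                 power = power_from_ncp(zeta * n_families, test$df, alpha)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> zeta/family=%.6g, N=%d, df=%d, alpha=%g, power=%.4f\n",
              x$zeta_per_family, as.integer(x$n_families), x$df, x$alpha,
              x$power))
  invisible(x)
}

#' Minimal number of families for target power
#'
#' Smallest integer N at which the test reaches the target asymptotic power,
#' found by bracketing and bisection (exact because power is nondecreasing
#' in N).
#'
#' @inheritParams power_calc
#' @param target_power Desired power.
#' @param max_n Search cap.
#' @return Minimal N (integer).
#' @export
required_n <- function(test, locus, model, target_power = 0.8, alpha = 0.05,
                       sexes = NULL, max_n = 1e8) {
  zeta <- ncp_per_family(test, locus, model, sexes = sexes)
  if (target_power <= alpha) return(1L)
  if (zeta <= 0) {
    stop("unreachable power: per-family NCP is zero for this test/model")
  }
  pw <- function(n) power_from_ncp(zeta * n, test$df, alpha)
  hi <- 1
  while (pw(hi) < target_power) {
    hi <- hi * 2
    if (hi > max_n) stop("unreachable power: need more than ", max_n, " families")
  }
  lo <- max(1, hi / 2)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  if (pw(lo) >= target_power) as.integer(lo) else as.integer(hi)
}

#' Variance explained needed to reach target power
#'
#' Inverts the power function over the variance explained by a single
#' genetic term (all other genetic effects held at zero) at a fixed sample
#' size. Used, for example, to ask how large an indirect parental effect
#' must be before a biobank-scale sibling sample can partition it from the
#' direct offspring effect.
#'
#' @inheritParams power_calc
#' @param term `"parental"`, `"maternal"`, `"paternal"` or `"offspring"`:
#'   which effect's variance explained is searched. The combined parental
#'   effect is realised as a maternal effect with the paternal effect zero
#'   (c = d).
#' @param n_families Sample size at which power is evaluated.
#' @param phi2 Shared residual variance.
#' @param target_power,alpha Test operating point.
#' @param interval Search interval for the variance explained.
#' @return Variance explained (proportion, e.g. 0.002 for 0.2\%).
#' @export
required_variance_explained <- function(test, locus, term = "parental",
                                        n_families, phi2 = 0,
                                        target_power = 0.8, alpha = 0.05,
                                        sexes = NULL,
                                        interval = c(1e-8, 0.5)) {
  make_model <- function(ve) {
    co <- sqrt(ve)
    switch(term,
           parental = trait_model(d = co, phi2 = phi2),
           maternal = trait_model(d = co, phi2 = phi2),
           paternal = trait_model(f = co, phi2 = phi2),
           offspring = trait_model(b = co, phi2 = phi2),
           stop("unknown term '", term, "'"))
  }
  fn <- function(ve) {
    power_calc(test, locus, make_model(ve), n_families, alpha,
               sexes = sexes)$power - target_power
  }
  stats::uniroot(fn, interval, tol = 1e-10)$root
}

#' Power grid over parameter combinations
#'
#' Evaluates asymptotic power over a grid of effect sizes, allele
#' frequencies, shared variances and sample sizes for one test; the shape of
#' table used to draw power curves.
#'
#' @param design,parent_mode,model_id Test definition.
#' @param grid Data frame with columns among `b2`, `d2`, `f2` (variances
#'   explained), `sign_b`, `sign_d`, `sign_f` (+1/-1, default +1), `p`,
#'   `phi2`, `n`, `alpha`.
#' @param chrom_type,sexes Chromosome context.
#' @return The grid with `zeta`, `df` and `power` columns appended.
#' @export
power_grid <- function(design, parent_mode, model_id, grid,
                       chrom_type = "autosomal", sexes = NULL) {
  ts <- test_spec(design, parent_mode, model_id, chrom_type)
  getcol <- function(nm, default) if (nm %in% names(grid)) grid[[nm]] else default
  b2 <- getcol("b2", 0); d2 <- getcol("d2", 0); f2 <- getcol("f2", 0)
  sb <- getcol("sign_b", 1); sd_ <- getcol("sign_d", 1); sf <- getcol("sign_f", 1)
  phi2 <- getcol("phi2", 0); alpha <- getcol("alpha", 0.05)
  out <- grid
  res <- t(mapply(function(b2, d2, f2, sb, sd_, sf, p, phi2, n, alpha) {
    model <- trait_model(b = sb * sqrt(b2), d = sd_ * sqrt(d2),
                         f = sf * sqrt(f2), phi2 = phi2)
    pr <- power_calc(ts, locus_spec(p, chrom_type), model, n, alpha,
                     sexes = sexes)
    c(zeta = pr$zeta_per_family, df = pr$df, power = pr$power)
  }, b2, d2, f2, sb, sd_, sf, grid$p, phi2, grid$n, alpha))
  cbind(out, as.data.frame(res))
}
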