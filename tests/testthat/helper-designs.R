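# Shared fixtures: small design/parameter grids used across test files.

p_grid <- seq(0.05, 0.95, by = 0.05)

x_sex_configs <- list(mm = c("male", "male"),
                      ff = c("female", "female"),
                      mf = c("male", "female"))

# binomial 95% interval half-width for a proportion; `k` comparisons give a
# simultaneous (Bonferroni-adjusted) family-wise 95% interval
binom_hw <- function(p, n, k = 1) {
  stats::qnorm(1 - 0.05 / (2 * k)) * sqrt(p * (1 - p) / n)
}

# quick standard sib-pair model used in several fitting tests
std_model <- function(b2 = 0.001, d2 = 0.001, f2 = 0, phi2 = 0.2,
                      sign_d = 1) {
  trait_model(b = sqrt(b2), d = sign_d * sqrt(d2), f = sqrt(f2), phi2 = phi2)
}
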