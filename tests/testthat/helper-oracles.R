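# Independent brute-force oracles for the Bayes factors. These deliberately
# take different numerical routes from the package:
#  - the JZS t-test BF integrates the noncentral-t density over the Cauchy
#    prior on the effect (theta-substitution, fixed Simpson grid), whereas
#    the package integrates the inverse-chi-square scale mixture adaptively;
#  - the correlation BF uses Simpson over rho with the Gauss hypergeometric
#    factor evaluated from its Euler integral representation (again by a
#    fixed Simpson grid), whereas the package sums the 2F1 series and
#    integrates rho adaptively.

oracle_jzs_bf <- function(t, n1, n2, rscale = 0.707, K = 40001L) {
  neff <- n1 * n2 / (n1 + n2)
  df <- n1 + n2 - 2
  theta <- seq(-pi / 2, pi / 2, length.out = K)
  ncp <- rscale * tan(theta) * sqrt(neff)
  f <- suppressWarnings(stats::dt(t, df, ncp)) / pi
  f[!is.finite(f)] <- 0
  h <- theta[2L] - theta[1L]
  w <- c(1, rep(c(4, 2), (K - 3L) %/% 2L), 4, 1) * h / 3
  sum(w * f) / stats::dt(t, df)
}

simpson_weights <- function(K, h) c(1, rep(c(4, 2), (K - 3L) %/% 2L), 4, 1) * h / 3

# 2F1(1/2, 1/2; c; x) via the Euler integral with t = u^2 substitution:
# Gamma(c) / (Gamma(1/2) Gamma(c - 1/2)) * Int_0^1 2 (1-u^2)^(c-3/2) (1-x u^2)^(-1/2) du
oracle_hyp2f1_half <- function(c_, x, K = 4001L) {
  u <- seq(0, 1, length.out = K)
  w <- simpson_weights(K, u[2L])
  vapply(x, function(xi) {
    f <- 2 * (1 - u^2)^(c_ - 1.5) * (1 - xi * u^2)^(-0.5)
    f[!is.finite(f)] <- 0
    exp(lgamma(c_) - lgamma(0.5) - lgamma(c_ - 0.5)) * sum(w * f)
  }, numeric(1))
}

oracle_corr_bf <- function(r, n, prior_scale = 0.707, K = 4001L) {
  a <- 1 / prior_scale
  kernel <- function(rho)
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
      oracle_hyp2f1_half(n - 0.5, (1 + rho * r) / 2)
  rho <- seq(-1, 1, length.out = K)
  w <- simpson_weights(K, rho[2L])
  f <- kernel(rho) * stats::dbeta((rho + 1) / 2, a, a) / 2
  f[!is.finite(f)] <- 0
  sum(w * f) / kernel(0)
}
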