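# Gauss hypergeometric 2F1(1/2, 1/2; c; z) for z in [0, 1), vectorised in z.
# The sampling density of a Pearson correlation only ever needs this special
# case, with c = n - 1/2, so a direct series is both simple and fast: term
# ratios tend to z and c is large in practice, making convergence quick.
# Returns the log of the series to keep downstream likelihoods overflow-safe.
log_hyp2f1_half <- function(c_par, z, tol = 1e-13, max_terms = 50000L) {
  stopifnot(c_par > 0, all(z >= 0), all(z < 1))
  s <- rep(1, length(z))
  term <- rep(1, length(z))
  active <- rep(TRUE, length(z))
  k <- 0L
  while (any(active) && k < max_terms) {
    ratio <- ((0.5 + k)^2 / ((c_par + k) * (k + 1))) * z[active]
    term[active] <- term[active] * ratio
    s[active] <- s[active] + term[active]
    active[active] <- term[active] > tol * s[active]
    k <- k + 1L
  }
  log(s)
}

# Log of f(r | rho, n) / f(r | 0, n): ratio of the exact sampling density of
# the Pearson correlation r under bivariate normality with population
# correlation rho to the density under rho = 0. All rho-free factors of the
# density cancel, leaving
#   ((n-1)/2) log(1 - rho^2) - (n - 3/2) log(1 - rho r)
#     + log 2F1(1/2, 1/2; n - 1/2; (1 + rho r)/2) - log 2F1(..., 1/2).
# Vectorised over rho for a fixed (r, n).
log_lik_ratio_r <- function(rho, r, n) {
  z <- (1 + rho * r) / 2
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log_hyp2f1_half(n - 0.5, z) - log_hyp2f1_half(n - 0.5, 0.5)
}
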