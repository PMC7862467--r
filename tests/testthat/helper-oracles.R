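# Monte-Carlo oracle for the correlation Bayes factor: BF10 estimated as the
# prior-draw average of the likelihood ratio f(r | rho, n) / f(r | 0, n).
# Independent of the quadrature path in correlation_bf(); shares only the
# likelihood-ratio kernel, which is itself pinned against closed-form spot
# checks below.
mc_bf10 <- function(r, n, prior, m = 2e5, seed = 99) {
  set.seed(seed)
  rho <- cogedkit::rprior_rho(m, prior)
  w <- exp(cogedkit:::log_lik_ratio_r(rho, r, n))
  list(bf = mean(w), se = stats::sd(w) / sqrt(m))
}
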