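#' Bayes factor and posterior summaries for a Pearson correlation
#'
#' Computes the Bayes factor \eqn{BF_{10}} contrasting a nonzero population
#' correlation against the point null \eqn{\rho = 0}, together with the
#' posterior median of \eqn{\rho} and a 95\% central credible interval.
#'
#' The likelihood is the exact sampling density of the observed Pearson
#' correlation under bivariate normality (a Gauss-hypergeometric expression),
#' so the observed `sample_r` and `n` are sufficient. The marginal likelihood
#' under the alternative is obtained by adaptive quadrature of the likelihood
#' ratio against the prior on a Fisher-z (atanh) transformed axis, which
#' tames the endpoint behaviour near \eqn{\rho = \pm 1}; the integral is
#' split at the sample estimate so the quadrature cannot step over a narrow
#' likelihood peak at large `n`. Posterior summaries are read off a dense
#' grid of the same integrand.
#'
#' @param sample_r Observed Pearson correlation, strictly inside
#'   \eqn{(-1, 1)}.
#' @param n Number of observations (at least 4).
#' @param prior A [prior_spec()]; defaults to a two-sided truncated Cauchy
#'   with scale \eqn{\sqrt 2/2}.
#' @param rel_tol Relative tolerance passed to the adaptive quadrature.
#' @return An object of class `bf_result`: a list with elements `bf10`,
#'   `log_bf10`, `posterior_median_rho`, `credible_interval_95`, `n`,
#'   `sample_r` and `prior`.
#' @examples
#' correlation_bf(0.52, 31)
#' correlation_bf(0.52, 31, prior_spec("stretched-beta", scale = 1))
#' @export
correlation_bf <- function(sample_r, n, prior = prior_spec(),
                           rel_tol = 1e-8) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n)) {
    stop("insufficient data: `n` must be an integer >= 4", call. = FALSE)
  }
  if (!is.numeric(sample_r) || length(sample_r) != 1L || !is.finite(sample_r)) {
    stop("`sample_r` must be a single finite number", call. = FALSE)
  }
  if (abs(sample_r) >= 1) {
    stop("degenerate input: |sample_r| must be strictly below 1",
         call. = FALSE)
  }
  log_bf <- .log_bf10(sample_r, n, prior, rel_tol)
  post <- .posterior_summaries(sample_r, n, prior)
  structure(
    list(bf10 = exp(log_bf),
         log_bf10 = log_bf,
         posterior_median_rho = post$median,
         credible_interval_95 = post$ci,
         posterior_density_at_zero = post$dens0,
         n = as.integer(n),
         sample_r = sample_r,
         prior = prior),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> r = %.4f, n = %d\n", x$sample_r, x$n))
  cat(sprintf("  BF10 = %.4g   posterior median rho = %.4f   95%% CI [%.4f, %.4f]\n",
              x$bf10, x$posterior_median_rho,
              x$credible_interval_95[1], x$credible_interval_95[2]))
  print(x$prior)
  invisible(x)
}

# rownames that are just 1..n carry no key information
.has_real_rownames <- function(df) {
  rn <- rownames(df)
  !is.null(rn) && !identical(rn, as.character(seq_len(nrow(df))))
}

# log BF10 by adaptive quadrature on the atanh scale, shifted by the
# log-likelihood-ratio at the sample value for overflow safety.
.log_bf10 <- function(r, n, prior, rel_tol = 1e-8) {
  z_lo <- if (prior$sided == "positive") 0 else -Inf
  z0 <- max(atanh(r), z_lo + 1e-8)
  shift <- log_lik_ratio_r(tanh(z0), r, n)
  f <- function(z) {
    rho <- tanh(z)
    exp(log_lik_ratio_r(rho, r, n) - shift) * dprior_rho(rho, prior) /
      cosh(z)^2
  }
  i1 <- stats::integrate(f, z_lo, z0, rel.tol = rel_tol,
                         stop.on.error = FALSE)
  i2 <- stats::integrate(f, z0, Inf, rel.tol = rel_tol,
                         stop.on.error = FALSE)
  shift + log(i1$value + i2$value)
}

# Posterior median, central 95% interval and density at rho = 0 from a dense
# grid on the atanh scale: a coarse global grid plus a fine grid around the
# sample estimate (posterior sd is ~ 1/sqrt(n - 3) on this scale).
.posterior_summaries <- function(r, n, prior, z_half_width = 9) {
  z_lo <- if (prior$sided == "positive") 0 else -z_half_width
  z0 <- min(max(atanh(r), z_lo), z_half_width)
  se <- 1 / sqrt(max(n - 3, 1))
  z <- sort(unique(c(
    seq(z_lo, z_half_width, length.out = 1501L),
    seq(max(z0 - 8 * se, z_lo), min(z0 + 8 * se, z_half_width),
        length.out = 1201L),
    0
  )))
  rho <- tanh(z)
  shift <- log_lik_ratio_r(tanh(z0), r, n)
  g <- exp(log_lik_ratio_r(rho, r, n) - shift) * dprior_rho(rho, prior) /
    cosh(z)^2
  dz <- diff(z)
  seg <- dz * (g[-1] + g[-length(g)]) / 2
  total <- sum(seg)
  cdf <- c(0, cumsum(seg)) / total
  qz <- function(p) {
    i <- findInterval(p, cdf, all.inside = TRUE)
    frac <- (p - cdf[i]) / pmax(cdf[i + 1] - cdf[i], .Machine$double.xmin)
    z[i] + frac * dz[i]
  }
  # density at rho = 0 on the rho scale (cosh(0)^2 = 1)
  dens0 <- g[which(z == 0)][1] / total
  list(median = tanh(qz(0.5)),
       ci = tanh(qz(c(0.025, 0.975))),
       dens0 = dens0)
}

#' Bayes factor for a partial Pearson correlation
#'
#' Residualises two participant-keyed vectors on a common set of control
#' variables (with an intercept), correlates the residuals, and applies
#' [correlation_bf()] with the sample size reduced by the number of controls
#' to account for the degrees of freedom they absorb.
#'
#' @param x,y Numeric vectors. If named, names are participant keys and must
#'   agree across `x`, `y` and the rows of `controls`.
#' @param controls A numeric matrix or data frame of control variables (one
#'   row per participant), e.g. working-memory-capacity and
#'   reward-sensitivity composites.
#' @param prior A [prior_spec()].
#' @param rel_tol Quadrature tolerance, as in [correlation_bf()].
#' @return A `bf_result`, with extra fields `partial_r` (the sample partial
#'   correlation) and `n_controls`.
#' @export
partial_correlation_bf <- function(x, y, controls, prior = prior_spec(),
                                   rel_tol = 1e-8) {
  cdf <- as.data.frame(controls, check.names = FALSE)
  ckeys <- NULL
  if ("participant_id" %in% names(cdf)) {
    ckeys <- as.character(cdf$participant_id)
    cdf$participant_id <- NULL
  } else if (.has_real_rownames(cdf)) {
    ckeys <- rownames(cdf)
  }
  controls <- as.matrix(cdf)
  storage.mode(controls) <- "double"
  rownames(controls) <- ckeys
  keys <- list(x = names(x), y = names(y), controls = ckeys)
  have <- !vapply(keys, is.null, logical(1))
  if (any(have)) {
    ref <- keys[have][[1]]
    for (nm in names(keys)[have]) {
      bad <- union(setdiff(keys[[nm]], ref), setdiff(ref, keys[[nm]]))
      if (length(bad)) {
        stop("participant keys do not align (", nm, "): ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      if (nm == "y") y <- y[ref]
      if (nm == "controls") controls <- controls[ref, , drop = FALSE]
    }
  }
  n_obs <- length(x)
  k <- ncol(controls)
  if (length(y) != n_obs || nrow(controls) != n_obs) {
    stop("x, y and controls must describe the same participants",
         call. = FALSE)
  }
  if (n_obs < 4 + k) {
    stop("insufficient data: need at least 4 + ", k, " observations",
         call. = FALSE)
  }
  design <- cbind(1, controls)
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  # a vector exactly explained by the controls leaves only float dust in its
  # residuals; its partial correlation is 0, not noise
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1e-300)) {
    pr <- 0
  } else {
    pr <- stats::cor(rx, ry)
  }
  out <- correlation_bf(pr, n_obs - k, prior, rel_tol)
  out$partial_r <- pr
  out$n_controls <- k
  out
}

#' Savage-Dickey density ratio for the correlation Bayes factor
#'
#' Independent numerical route to \eqn{BF_{10}}: the prior density at
#' \eqn{\rho = 0} divided by the posterior density at \eqn{\rho = 0}. Used as
#' a consistency check on the quadrature in the test suite; exposed because
#' it is occasionally useful for diagnostics.
#'
#' @inheritParams correlation_bf
#' @return The Savage-Dickey estimate of \eqn{BF_{10}}.
#' @export
savage_dickey_bf <- function(sample_r, n, prior = prior_spec()) {
  post <- .posterior_summaries(sample_r, n, prior)
  dprior_rho(0, prior) / post$dens0
}
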