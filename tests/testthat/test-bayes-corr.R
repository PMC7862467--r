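test_that("basic Bayes-factor behaviour: nulls, accumulation, symmetry", {
  b0 <- correlation_bf(0, 50)
  expect_lt(b0$bf10, 1)
  expect_equal(b0$posterior_median_rho, 0, tolerance = 1e-6)
  ci <- b0$credible_interval_95
  expect_lt(ci[1], b0$posterior_median_rho)
  expect_gt(ci[2], b0$posterior_median_rho)

  # same r, more data: more evidence
  expect_gt(correlation_bf(0.5, 200)$bf10, correlation_bf(0.5, 20)$bf10)

  # two-sided prior: BF invariant under sign flip of r
  expect_equal(correlation_bf(0.37, 40)$bf10,
               correlation_bf(-0.37, 40)$bf10, tolerance = 1e-6)

  expect_error(correlation_bf(0.5, 3), "insufficient")
  expect_error(correlation_bf(1, 30), "degenerate")
})

test_that("quadrature BF agrees with the Monte-Carlo prior-draw oracle", {
  cases <- list(
    list(r = 0.521, n = 31, prior = prior_spec(), m = 1e6, tol = 0.02),
    list(r = 0.3, n = 80, prior = prior_spec(), m = 2e5, tol = NA),
    list(r = -0.2, n = 40, prior = prior_spec(), m = 2e5, tol = NA),
    list(r = 0.5, n = 25,
         prior = prior_spec("stretched-beta", scale = 1), m = 2e5, tol = NA),
    list(r = 0.521, n = 31, prior = prior_spec(sided = "positive"),
         m = 2e5, tol = NA)
  )
  for (cs in cases) {
    got <- correlation_bf(cs$r, cs$n, cs$prior)$bf10
    mc <- mc_bf10(cs$r, cs$n, cs$prior, m = cs$m)
    if (!is.na(cs$tol)) {
      # registered-prior flagship case: within 2% of a 1e6-draw estimate
      expect_lt(abs(got - mc$bf) / mc$bf, cs$tol)
    }
    # all cases: inside the oracle's 99% Monte-Carlo interval
    expect_lt(abs(got - mc$bf), 2.58 * mc$se)
  }
})

test_that("independent implementation pins the stretched-beta Bayes factor", {
  # frozen reference values from pingouin 0.6.1 bayesfactor_pearson
  # (Ly et al. exact method, kappa = 1), computed once and hard-coded
  pb <- prior_spec("stretched-beta", scale = 1)
  expect_equal(correlation_bf(0.521, 31, pb)$bf10, 16.67967264668664,
               tolerance = 1e-6)
  expect_equal(correlation_bf(0, 100, pb)$bf10, 0.12501848174018393,
               tolerance = 1e-6)
  expect_equal(correlation_bf(0.3, 50, pb)$bf10, 1.5554512119209472,
               tolerance = 1e-6)
  expect_equal(correlation_bf(-0.4, 40, pb)$bf10, 4.622127283427608,
               tolerance = 1e-6)
})

test_that("Savage-Dickey density ratio matches the quadrature BF within 1%", {
  for (r in c(0, 0.2, 0.521, -0.4)) {
    for (n in c(20, 60, 150)) {
      bf <- correlation_bf(r, n)$bf10
      sd_bf <- savage_dickey_bf(r, n)
      expect_lt(abs(sd_bf - bf) / bf, 0.01)
    }
  }
})

test_that("95% credible intervals are calibrated under repeated sampling", {
  # 1000 draws of r at fixed rho, n = 100; the interval should cover rho
  # 95% +/- 2% of the time
  rho <- 0.4
  n <- 100
  set.seed(31)
  cover <- logical(1000)
  prior <- prior_spec()
  for (i in seq_along(cover)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- cor(x, y)
    ci <- cogedkit:::.posterior_summaries(r, n, prior)$ci
    cover[i] <- ci[1] <= rho && rho <= ci[2]
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("partial correlation reduces to the plain BF when controls are inert", {
  set.seed(5)
  n <- 60
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  names(x) <- names(y) <- sprintf("P%03d", seq_len(n))
  # controls exactly orthogonal to both vectors (in-sample)
  c1 <- residuals(lm(rnorm(n) ~ x + y))
  c2 <- residuals(lm(rnorm(n) ~ x + y + c1))
  controls <- data.frame(participant_id = names(x), a = c1, b = c2)
  got <- partial_correlation_bf(x, y, controls)
  plain_r <- cor(x, y)
  expect_equal(got$partial_r, plain_r, tolerance = 1e-10)
  expect_equal(got$n, n - 2L)
  expect_equal(got$bf10, correlation_bf(plain_r, n - 2)$bf10,
               tolerance = 1e-8)

  # y an exact linear function of the controls: partial r = 0, BF < 1
  y2 <- setNames(2 * c1 - c2 + 1, names(x))
  got2 <- partial_correlation_bf(x, y2, controls)
  expect_equal(got2$partial_r, 0, tolerance = 1e-8)
  expect_lt(got2$bf10, 1)

  # key misalignment is an error naming offenders
  xbad <- x; names(xbad)[1] <- "ZZZ"
  expect_error(partial_correlation_bf(xbad, y, controls), "ZZZ")
})

test_that("partial correlation recovers the generating rho with inert controls", {
  # 200 replicates at rho = 0.3, n = 150; controls carry no signal
  set.seed(77)
  meds <- numeric(200)
  for (i in seq_along(meds)) {
    n <- 150
    x <- rnorm(n)
    y <- 0.3 * x + sqrt(1 - 0.09) * rnorm(n)
    controls <- data.frame(a = rnorm(n), b = rnorm(n))
    meds[i] <- partial_correlation_bf(x, y, controls)$posterior_median_rho
  }
  se <- sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) - 0.3), 3 * se)
})
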