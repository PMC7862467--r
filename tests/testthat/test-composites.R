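test_that("z-score composites standardise in-sample and reject degeneracy", {
  df <- data.frame(participant_id = c("a", "b"),
                   m1 = c(10, 20), m2 = c(5, 1), m3 = c(0, 4))
  comp <- zscore_composite(df, c("m1", "m2", "m3"))
  # mirrored two-participant case: composites are +/- k and sum to zero
  expect_equal(sum(comp$composite), 0)
  expect_equal(comp$composite[1], -comp$composite[2])

  df$m2 <- c(3, 3)
  expect_error(zscore_composite(df, c("m1", "m2")), "m2")
  expect_error(zscore_composite(df[1, ], "m1"), "at least 2")
})

test_that("composites track the generating ability latent", {
  ch <- generate_cohort(cohort_config(n_participants = 1000, seed = 21))
  comp <- build_composites(ch$covariates)
  wm_lat <- vapply(ch$profiles, function(p) p$wm_capacity_latent, 0)
  # Monte-Carlo oracle: re-simulate the generator's span transform
  # (scaled logistic of 0.7*latent + N(0, 0.7), rounded) independently of
  # generate_cohort, at large m, to get the expected composite-latent r
  set.seed(8)
  m <- 2e5
  lat <- rnorm(m)
  z3 <- vapply(c(42, 75, 42), function(mx) {
    s <- round(mx * plogis(0.7 * lat + rnorm(m, 0, 0.7)))
    (s - mean(s)) / sd(s)
  }, numeric(m))
  oracle_r <- cor(rowSums(z3), lat)
  got_r <- cor(comp$wm_capacity, wm_lat)
  se <- sqrt((1 - oracle_r^2)^2 / 1000)
  expect_lt(abs(got_r - oracle_r), 3 * se)
  # reward composite loads on the reward latent, not the ability latent
  rew_lat <- vapply(ch$profiles, function(p) p$reward_sensitivity_latent, 0)
  expect_gt(cor(comp$reward_sensitivity, rew_lat), 0.5)
  expect_lt(abs(cor(comp$reward_sensitivity, wm_lat)), 0.12)
})

make_scored_cohort <- function(n = 80, rho = 0.5, seed = 3) {
  ch <- generate_cohort(cohort_config(n_participants = n,
                                      cross_domain_rho = rho, seed = seed))
  recs <- list()
  for (i in seq_along(ch$profiles)) {
    p <- ch$profiles[[i]]
    for (d in c("wm", "speech")) {
      recs <- c(recs, run_discounting(profile_agent(p, d), d,
                                      seed = i, participant_id = p$participant_id))
    }
  }
  list(svt = sv_table(recs), cov = ch$covariates, cohort = ch)
}

test_that("residualisation removes covariate-explained variance correctly", {
  sc <- make_scored_cohort(n = 60, seed = 13)
  res <- residualize_sv(sc$svt, sc$cov, "wm")
  expect_equal(mean(res$residual_sv), 0, tolerance = 1e-10)

  # constant covariates: collapses to the intercept + level model, so the
  # participant residual is their mean SV minus the grand level means' mean
  cov_const <- sc$cov
  cov_const[, c("dprime_2back", "dprime_3back", "dprime_4back")] <- 2
  cov_const[, c("rt_2back", "rt_3back", "rt_4back")] <- 700
  res_c <- residualize_sv(sc$svt, cov_const, "wm")
  lvl <- level_mean_sv(sc$svt, "wm")
  grand <- aggregate(sv ~ hard_level, lvl, mean)
  by_hand <- aggregate(sv ~ participant_id, lvl, mean)
  by_hand$expected <- by_hand$sv - mean(grand$sv)
  merged <- merge(res_c, by_hand)
  expect_equal(merged$residual_sv, merged$expected, tolerance = 1e-10)

  # SV exactly linear in d-prime, no noise: all residuals vanish
  sv_lin <- sc$svt[sc$svt$domain == "wm", ]
  suffix <- sub("-back", "back", sv_lin$hard_level)
  dp <- vapply(seq_len(nrow(sv_lin)), function(i) {
    sc$cov[[paste0("dprime_", suffix[i])]][
      match(sv_lin$participant_id[i], sc$cov$participant_id)]
  }, 0)
  sv_lin$sv <- 0.2 + 0.1 * dp
  res_lin <- residualize_sv(sv_lin, sc$cov, "wm")
  expect_lt(max(abs(res_lin$residual_sv)), 1e-10)
})

test_that("residualisation is idempotent and ignores orthogonal covariates", {
  sc <- make_scored_cohort(n = 50, seed = 17)
  # idempotence at matching grain: OLS residuals are orthogonal to the
  # participant-grain covariates, so residualising them again is a no-op
  res1 <- residualize_sv(sc$svt, sc$cov, "speech", grain = "participant")
  svt2 <- sc$svt[sc$svt$domain == "speech", ]
  svt2 <- merge(svt2[, setdiff(names(svt2), "sv")],
                data.frame(participant_id = res1$participant_id,
                           sv = res1$residual_sv))
  res2 <- residualize_sv(svt2, sc$cov, "speech", grain = "participant")
  expect_equal(res2$residual_sv[order(res2$participant_id)],
               res1$residual_sv[order(res1$participant_id)],
               tolerance = 1e-10)

  # a covariate orthogonal (in-sample) to the outcome and the level factor
  # must leave residuals untouched: compare against the level-only model
  # obtained by making intelligibility constant (constant columns drop out)
  lvl <- level_mean_sv(sc$svt, "speech")
  lvl <- lvl[order(lvl$participant_id, lvl$hard_level), ]
  X <- model.matrix(~ factor(hard_level), data = lvl)
  set.seed(4)
  v <- rnorm(nrow(lvl))
  v <- residuals(lm(v ~ X + lvl$sv))  # orthogonal to intercept, level, sv
  cov_orth <- sc$cov
  cov_orth[, c("intel_4", "intel_8", "intel_12")] <- 0
  for (i in seq_len(nrow(lvl))) {
    col <- paste0("intel_", gsub("[^0-9]", "", lvl$hard_level[i]))
    row <- match(lvl$participant_id[i], cov_orth$participant_id)
    cov_orth[row, col] <- v[i]
  }
  cov_const <- sc$cov
  cov_const[, c("intel_4", "intel_8", "intel_12")] <- 0.5
  r_orth <- residualize_sv(sc$svt, cov_orth, "speech")
  r_base <- residualize_sv(sc$svt, cov_const, "speech")
  expect_equal(r_orth$residual_sv, r_base$residual_sv, tolerance = 1e-10)

  expect_error(
    residualize_sv(sc$svt, within(sc$cov, {
      rt_2back <- dprime_2back; rt_3back <- dprime_3back
      rt_4back <- dprime_4back
    }), "wm"),
    "collinear")
})
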