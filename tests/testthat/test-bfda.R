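# boundary curves over a short horizon, shared by several blocks below
short_curves <- bf_boundary_curves(10:80, prior_spec(), 10, 0.1)

test_that("design specs validate their stopping rule", {
  expect_error(design_spec(bf_upper = 0.5), "configuration error")
  expect_error(design_spec(bf_lower = 2), "configuration error")
  expect_error(design_spec(n_min = 3), "configuration error")
  expect_error(design_spec(n_max = 5, n_min = 10), "configuration error")
  expect_error(design_spec(true_rho = 1), "configuration error")
  reg <- registered_design()
  expect_equal(c(reg$n_min, reg$n_step, reg$n_max), c(100L, 10L, 300L))
})

test_that("BF10 is monotone in |r|, so boundary curves are well-defined", {
  for (n in c(12, 40, 120)) {
    bfs <- vapply(seq(0, 0.9, by = 0.1),
                  function(r) correlation_bf(r, n)$log_bf10, 0)
    expect_true(all(diff(bfs) > 0))
  }
  # one-sided prior: monotone in signed r
  pos <- prior_spec(sided = "positive")
  bfs <- vapply(seq(-0.8, 0.8, by = 0.2),
                function(r) correlation_bf(r, n = 40, pos)$log_bf10, 0)
  expect_true(all(diff(bfs) > 0))
  # curves bracket the boundaries: BF just above r_upper exceeds bf_upper
  i <- match(40, short_curves$n)
  expect_gt(correlation_bf(short_curves$r_upper[i] + 1e-4, 40)$bf10, 10)
  expect_lt(correlation_bf(short_curves$r_upper[i] - 1e-4, 40)$bf10, 10)
})

test_that("overwhelming true effects stop at the first interim", {
  spec <- design_spec(true_rho = 0.999, n_min = 10, n_max = 80,
                      n_sims = 200, seed = 2)
  res <- simulate_sequential_design(spec, curves = short_curves)
  reps <- res$replicates
  expect_gte(mean(reps$boundary == "upper" & reps$stopping_n == 10), 0.99)
  # boundary labels agree with terminal BFs
  expect_true(all(reps$terminal_bf[reps$boundary == "upper"] >= 10))
})

test_that("degenerate horizon stops everyone at n_min", {
  spec <- design_spec(true_rho = 0.2, n_min = 12, n_max = 12, n_sims = 50,
                      seed = 3)
  res <- simulate_sequential_design(spec)
  expect_true(all(res$replicates$stopping_n == 12))
  expect_true(all(res$replicates$boundary %in%
                    c("upper", "lower", "ceiling")))
})

test_that("simulations are reproducible and summaries are coherent", {
  spec <- design_spec(true_rho = 0.4, n_min = 10, n_max = 80, n_sims = 100,
                      seed = 9)
  r1 <- simulate_sequential_design(spec, curves = short_curves)
  r2 <- simulate_sequential_design(spec, curves = short_curves)
  expect_identical(r1$replicates, r2$replicates)

  s <- summarize_design(r1)
  expect_equal(sum(s$by_boundary$proportion), 1)
  expect_equal(sum(s$by_boundary$n_replicates), 100L)
  ups <- r1$replicates[r1$replicates$boundary == "upper", ]
  expect_equal(s$by_boundary$median[s$by_boundary$boundary == "upper"],
               median(ups$stopping_n))
  # ceiling rows stopped exactly at n_max
  ceil <- r1$replicates[r1$replicates$boundary == "ceiling", ]
  expect_true(all(ceil$stopping_n == 80))
})

test_that("raising the upper threshold never shortens upper-boundary stops", {
  curves20 <- bf_boundary_curves(10:80, prior_spec(), 20, 0.1)
  spec10 <- design_spec(true_rho = 0.5, n_min = 10, n_max = 80,
                        n_sims = 150, seed = 11, bf_upper = 10)
  spec20 <- design_spec(true_rho = 0.5, n_min = 10, n_max = 80,
                        n_sims = 150, seed = 11, bf_upper = 20)
  r10 <- simulate_sequential_design(spec10, curves = short_curves,
                                    terminal_bf = FALSE)
  r20 <- simulate_sequential_design(spec20, curves = curves20,
                                    terminal_bf = FALSE)
  # same seed => same data paths; paired stopping times can only grow
  both_up <- r10$replicates$boundary == "upper" &
    r20$replicates$boundary == "upper"
  expect_true(all(r20$replicates$stopping_n[both_up] >=
                    r10$replicates$stopping_n[both_up]))
  expect_gte(median(r20$replicates$stopping_n[r20$replicates$boundary ==
                                                "upper"]),
             median(r10$replicates$stopping_n[r10$replicates$boundary ==
                                                "upper"]))
})

test_that("trivial summary cases behave", {
  fake <- structure(list(
    replicates = data.frame(replicate = 1:3, stopping_n = c(10L, 20L, 30L),
                            sample_r = c(0.9, 0.9, 0.9),
                            terminal_bf = c(20, 30, 40),
                            boundary = "upper"),
    spec = design_spec(n_sims = 3),
    curves = NULL), class = "sequential_result")
  s <- summarize_design(fake)
  up <- s$by_boundary[s$by_boundary$boundary == "upper", ]
  expect_equal(up$median, 20)
  expect_equal(up$proportion, 1)
  # empty boundary classes are reported as unavailable, not as errors
  lo <- s$by_boundary[s$by_boundary$boundary == "lower", ]
  expect_true(is.na(lo$median))
  expect_equal(lo$n_replicates, 0L)
})
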