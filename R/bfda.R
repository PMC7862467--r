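#' Specification of a sequential Bayes Factor design
#'
#' Bundles everything a sequential Bayes Factor Design Analysis needs: the
#' assumed true correlation, the analysis prior, the evidence boundaries,
#' and the sampling schedule. Defaults follow common BFDA practice
#' (start at `n_min = 10`, add one participant at a time); the registered
#' protocol variant of the study this models (start at 100, test every 10,
#' ceiling 300) is available via [registered_design()].
#'
#' @param true_rho Data-generating correlation, in \eqn{(-1, 1)}.
#' @param prior A [prior_spec()] used for every interim Bayes factor.
#' @param bf_upper,bf_lower Stopping boundaries on \eqn{BF_{10}}; sampling
#'   stops when the interim BF reaches `bf_upper` (evidence for a nonzero
#'   correlation) or drops to `bf_lower` (evidence for the null).
#' @param n_min First interim analysis (at least 4).
#' @param n_step Participants added between interim analyses.
#' @param n_max Hard ceiling on the sample size; replicates still unresolved
#'   there stop with boundary `"ceiling"`.
#' @param n_sims Number of simulated replicates.
#' @param seed Integer seed; the full simulation is reproducible given it.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(true_rho = 0.3, prior = prior_spec(),
                        bf_upper = 10, bf_lower = 0.1,
                        n_min = 10, n_step = 1, n_max = 300,
                        n_sims = 1000, seed = 1) {
  stopifnot(inherits(prior, "prior_spec"))
  if (abs(true_rho) >= 1) {
    stop("configuration error: true_rho must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (!(bf_lower > 0 && bf_lower < 1 && bf_upper > 1)) {
    stop("configuration error: need 0 < bf_lower < 1 < bf_upper",
         call. = FALSE)
  }
  if (n_min < 4 || n_step < 1 || n_max < n_min || n_sims < 1) {
    stop("configuration error: require n_min >= 4, n_step >= 1, ",
         "n_max >= n_min, n_sims >= 1", call. = FALSE)
  }
  structure(list(true_rho = true_rho, prior = prior,
                 bf_upper = bf_upper, bf_lower = bf_lower,
                 n_min = as.integer(n_min), n_step = as.integer(n_step),
                 n_max = as.integer(n_max), n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' The registered sequential protocol
#'
#' Convenience constructor for the protocol variant actually registered for
#' the study this package models: a minimum sample of 100, interim tests
#' every 10 participants thereafter, and a hard ceiling of 300.
#'
#' @inheritParams design_spec
#' @param ... Passed on to [design_spec()].
#' @return A `design_spec`.
#' @export
registered_design <- function(true_rho = 0.3, ...) {
  design_spec(true_rho = true_rho, n_min = 100, n_step = 10, n_max = 300, ...)
}

#' Critical-correlation boundary curves for a sequential design
#'
#' For each interim sample size, finds the sample correlation at which
#' \eqn{BF_{10}} crosses the upper and lower stopping boundaries. For a
#' two-sided prior the Bayes factor is an even, monotone-increasing function
#' of \eqn{|r|}, so each boundary corresponds to a critical \eqn{|r|}; for a
#' one-sided (positive) prior the BF is monotone in signed \eqn{r}. The
#' lower-boundary curve is `NA` at sample sizes where even \eqn{r = 0}
#' cannot push \eqn{BF_{10}} down to `bf_lower`.
#'
#' Precomputing these curves turns each simulated replicate into a cheap
#' comparison of running correlations against two vectors, instead of
#' thousands of quadrature calls.
#'
#' @param n_seq Increasing vector of interim sample sizes (all >= 4).
#' @param prior A [prior_spec()].
#' @param bf_upper,bf_lower Stopping boundaries.
#' @return A data frame with columns `n`, `r_upper`, `r_lower`, `bf_at_zero`.
#' @export
bf_boundary_curves <- function(n_seq, prior = prior_spec(),
                               bf_upper = 10, bf_lower = 0.1) {
  stopifnot(all(n_seq >= 4), !is.unsorted(n_seq))
  m <- length(n_seq)
  r_up <- r_lo <- bf0 <- rep(NA_real_, m)
  r_min <- if (prior$sided == "positive") -0.99999 else 1e-7
  prev_up <- NA_real_
  prev_lo <- NA_real_
  for (i in seq_len(m)) {
    n <- n_seq[i]
    f_up <- function(r) .log_bf10(r, n, prior, 1e-6) - log(bf_upper)
    iv <- if (is.na(prev_up)) c(r_min, 0.99999) else
      c(max(r_min, prev_up - 0.1), min(0.99999, prev_up + 0.02))
    root <- tryCatch(
      stats::uniroot(f_up, iv, extendInt = "upX", tol = 1e-6),
      error = function(e) stats::uniroot(f_up, c(r_min, 0.99999), tol = 1e-6))
    r_up[i] <- root$root
    prev_up <- r_up[i]
    bf0[i] <- exp(.log_bf10(r_min, n, prior, 1e-6))
    if (bf0[i] <= bf_lower) {
      f_lo <- function(r) .log_bf10(r, n, prior, 1e-6) - log(bf_lower)
      iv <- if (is.na(prev_lo)) c(r_min, r_up[i]) else
        c(max(r_min, prev_lo - 0.02), min(r_up[i], prev_lo + 0.1))
      root <- tryCatch(
        stats::uniroot(f_lo, iv, extendInt = "upX", tol = 1e-6),
        error = function(e) stats::uniroot(f_lo, c(r_min, r_up[i]),
                                           tol = 1e-6))
      r_lo[i] <- root$root
      prev_lo <- r_lo[i]
    }
  }
  data.frame(n = n_seq, r_upper = r_up, r_lower = r_lo, bf_at_zero = bf0)
}

#' Simulate a sequential Bayes Factor design
#'
#' Monte-Carlo simulation of the stopping rule: each replicate grows a
#' bivariate-normal sample with correlation `true_rho` from `n_min` in steps
#' of `n_step`, evaluates the correlation Bayes factor at every interim, and
#' stops at the first boundary crossing or at `n_max`.
#'
#' @param spec A [design_spec()].
#' @param curves Optional precomputed [bf_boundary_curves()] for the spec's
#'   interim sizes, prior and boundaries; computed if missing. Supplying
#'   them lets several simulations (e.g. different `true_rho`) share one
#'   expensive precomputation.
#' @param terminal_bf If `TRUE` (default), the Bayes factor at each
#'   replicate's stopping point is evaluated and returned.
#' @return An object of class `sequential_result`: list with `replicates`
#'   (data frame: `replicate`, `stopping_n`, `sample_r`, `terminal_bf`,
#'   `boundary`), the `spec`, and the boundary `curves` used.
#' @examples
#' spec <- design_spec(true_rho = 0.8, n_min = 10, n_max = 40, n_sims = 20)
#' res <- simulate_sequential_design(spec)
#' summarize_design(res)
#' @export
simulate_sequential_design <- function(spec, curves = NULL,
                                       terminal_bf = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  n_seq <- seq(spec$n_min, spec$n_max, by = spec$n_step)
  if (n_seq[length(n_seq)] != spec$n_max) n_seq <- c(n_seq, spec$n_max)
  if (is.null(curves)) {
    curves <- bf_boundary_curves(n_seq, spec$prior, spec$bf_upper,
                                 spec$bf_lower)
  }
  if (!all(n_seq %in% curves$n)) {
    stop("`curves` do not cover the design's interim sample sizes",
         call. = FALSE)
  }
  curves <- curves[match(n_seq, curves$n), ]
  two_sided <- spec$prior$sided == "two"
  set.seed(spec$seed)
  nmax <- spec$n_max
  out <- data.frame(replicate = seq_len(spec$n_sims),
                    stopping_n = NA_integer_,
                    sample_r = NA_real_,
                    terminal_bf = NA_real_,
                    boundary = NA_character_)
  for (s in seq_len(spec$n_sims)) {
    x <- stats::rnorm(nmax)
    y <- spec$true_rho * x + sqrt(1 - spec$true_rho^2) * stats::rnorm(nmax)
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
    k <- n_seq
    r <- (k * cxy[k] - cx[k] * cy[k]) /
      sqrt((k * cxx[k] - cx[k]^2) * (k * cyy[k] - cy[k]^2))
    stat <- if (two_sided) abs(r) else r
    i_up <- which(stat >= curves$r_upper)
    i_lo <- which(!is.na(curves$r_lower) & stat <= curves$r_lower)
    first_up <- if (length(i_up)) i_up[1] else Inf
    first_lo <- if (length(i_lo)) i_lo[1] else Inf
    if (is.finite(first_up) || is.finite(first_lo)) {
      i <- min(first_up, first_lo)
      out$boundary[s] <- if (first_up <= first_lo) "upper" else "lower"
      out$stopping_n[s] <- k[i]
      out$sample_r[s] <- r[i]
    } else {
      out$boundary[s] <- "ceiling"
      out$stopping_n[s] <- nmax
      out$sample_r[s] <- r[length(k)]
    }
  }
  if (terminal_bf) {
    cache <- new.env(parent = emptyenv())
    out$terminal_bf <- vapply(seq_len(nrow(out)), function(s) {
      key <- paste(round(out$sample_r[s], 4), out$stopping_n[s])
      if (is.null(cache[[key]])) {
        cache[[key]] <- exp(.log_bf10(round(out$sample_r[s], 4),
                                      out$stopping_n[s], spec$prior, 1e-6))
      }
      cache[[key]]
    }, numeric(1))
  }
  structure(list(replicates = out, spec = spec, curves = curves),
            class = "sequential_result")
}

#' Summarise a sequential design simulation
#'
#' Per stopping boundary: the number and proportion of replicates and the
#' median and 5/25/75/95\% quantiles of the stopping sample size. Also
#' reports the proportion of misleading evidence: upper-boundary hits when
#' the simulated truth is \eqn{\rho = 0}, lower-boundary hits when it is
#' not.
#'
#' @param result A `sequential_result` from [simulate_sequential_design()].
#' @return A list with elements `by_boundary` (data frame) and
#'   `misleading_proportion` (scalar, `NA` when undefined).
#' @export
summarize_design <- function(result) {
  stopifnot(inherits(result, "sequential_result"))
  reps <- result$replicates
  if (!nrow(reps)) stop("empty result", call. = FALSE)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- lapply(c("upper", "lower", "ceiling"), function(b) {
    ns <- reps$stopping_n[reps$boundary == b]
    if (!length(ns)) {
      data.frame(boundary = b, n_replicates = 0L, proportion = 0,
                 q05 = NA_real_, q25 = NA_real_, median = NA_real_,
                 q75 = NA_real_, q95 = NA_real_)
    } else {
      q <- stats::quantile(ns, qs, names = FALSE, type = 7)
      data.frame(boundary = b, n_replicates = length(ns),
                 proportion = length(ns) / nrow(reps),
                 q05 = q[1], q25 = q[2], median = q[3], q75 = q[4],
                 q95 = q[5])
    }
  })
  by_boundary <- do.call(rbind, rows)
  mis <- if (result$spec$true_rho == 0) {
    mean(reps$boundary == "upper")
  } else {
    mean(reps$boundary == "lower")
  }
  list(by_boundary = by_boundary, misleading_proportion = mis)
}

#' @export
print.sequential_result <- function(x, ...) {
  s <- summarize_design(x)
  cat(sprintf("<sequential_result> true rho = %.3f, %d replicates, n in [%d, %d] by %d\n",
              x$spec$true_rho, x$spec$n_sims, x$spec$n_min, x$spec$n_max,
              x$spec$n_step))
  print(s$by_boundary, row.names = FALSE)
  invisible(x)
}
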