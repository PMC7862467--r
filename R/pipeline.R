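#' Configuration for the three-stage analysis pipeline
#'
#' @param cohort A [cohort_config()] describing the simulated sample.
#' @param prior A [prior_spec()] used at every stage.
#' @param stages Which analysis stages to run (subset of 1:3).
#' @param ncs_stage If `TRUE`, adds an exploratory stage correlating the
#'   Need for Cognition score with domain-mean subjective values; off by
#'   default, as it is orthogonal to the main hypotheses.
#' @param exclusion `"report-both"` (default): when non-compliant
#'   participants are flagged, report results with and without them;
#'   `"keep"`: ignore flags; `"drop"`: analyse only the excluded variant.
#' @param max_exclusion_fraction Error if exclusion would remove more than
#'   this fraction of the cohort (a sign the generator, not the sample, is
#'   wrong).
#' @param out_dir Optional directory; when given, all tables are written
#'   there as tab-separated text via [write_pipeline_tables()].
#' @param seed Integer seed for the discounting phase (cell order and any
#'   softmax choice noise); the cohort itself is governed by
#'   `cohort$seed`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_config(),
                            prior = prior_spec(),
                            stages = 1:3,
                            ncs_stage = FALSE,
                            exclusion = c("report-both", "keep", "drop"),
                            max_exclusion_fraction = 0.5,
                            out_dir = NULL,
                            seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(prior, "prior_spec"),
            all(stages %in% 1:3))
  exclusion <- match.arg(exclusion)
  structure(list(cohort = cohort, prior = prior, stages = sort(stages),
                 ncs_stage = isTRUE(ncs_stage), exclusion = exclusion,
                 max_exclusion_fraction = max_exclusion_fraction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Flag non-compliant choosers
#'
#' Flags participants who chose one and the same option on every decision
#' trial -- e.g. always taking the high-effort option -- the behavioural
#' pattern the sampling plan treats as possible non-compliance. A
#' participant did that exactly when, in all 18 cells, the first choice is
#' identical and the indifference point sits at the staircase floor
#' `base/32` (the titrated side was accepted on all five trials), so the
#' flag is computable from the SV table alone. Ordinary effort-averse
#' responders first-choose the easy option in every cell but then produce
#' mixed choices during titration, and are not flagged.
#'
#' @param svt An [sv_table()] covering both domains.
#' @return Data frame `participant_id`, `n_cells`, `always` (`"easy"`,
#'   `"hard"`, or `NA` when choices were mixed), `flagged`.
#' @export
flag_noncompliance <- function(svt) {
  ids <- unique(svt$participant_id)
  rows <- lapply(ids, function(p) {
    sub <- svt[svt$participant_id == p, ]
    uni <- unique(sub$first_choice)
    at_floor <- all(abs(sub$indifference_point -
                          sub$base_amount / 32) < 1e-12)
    one_sided <- length(uni) == 1L && at_floor
    data.frame(participant_id = p,
               n_cells = nrow(sub),
               always = if (one_sided) uni else NA_character_,
               flagged = one_sided)
  })
  do.call(rbind, rows)
}

.stage_label <- c("zero-order correlation of domain-mean SVs",
                  "correlation of performance-residualised SVs",
                  "partial correlation controlling for composites")

# run stages 1-3 (+ optional NCS stage) on one analysis sample
.run_stages <- function(svt, covariates, config) {
  wide <- domain_mean_sv(svt)
  sv_wm <- wide$mean_sv[wide$domain == "wm"]
  sv_sp <- wide$mean_sv[wide$domain == "speech"]
  ids <- unique(wide$participant_id)
  names(sv_wm) <- names(sv_sp) <- ids
  out <- list()
  res_wm <- res_sp <- NULL
  if (any(config$stages >= 2)) {
    res_wm <- residualize_sv(svt, covariates, "wm")
    res_sp <- residualize_sv(svt, covariates, "speech")
  }
  for (stage in config$stages) {
    if (stage == 1) {
      r <- stats::cor(sv_wm, sv_sp)
      bf <- correlation_bf(r, length(ids), config$prior)
    } else if (stage == 2) {
      r <- stats::cor(res_wm$residual_sv, res_sp$residual_sv)
      bf <- correlation_bf(r, length(ids), config$prior)
    } else {
      comp <- build_composites(
        covariates[covariates$participant_id %in% ids, ])
      x <- stats::setNames(res_wm$residual_sv, res_wm$participant_id)
      y <- stats::setNames(res_sp$residual_sv, res_sp$participant_id)
      bf <- partial_correlation_bf(
        x, y, comp[c("participant_id", "wm_capacity",
                     "reward_sensitivity")], config$prior)
      r <- bf$partial_r
    }
    out[[length(out) + 1L]] <- structure(
      list(stage = stage, label = .stage_label[stage],
           sample_r = r, n = length(ids), bf = bf),
      class = "stage_report")
  }
  if (config$ncs_stage) {
    ncs <- covariates$ncs[match(ids, covariates$participant_id)]
    for (d in c("wm", "speech")) {
      sv_d <- if (d == "wm") sv_wm else sv_sp
      r <- stats::cor(ncs, sv_d)
      out[[length(out) + 1L]] <- structure(
        list(stage = paste0("ncs-", d),
             label = paste("exploratory NCS correlation,", d),
             sample_r = r, n = length(ids),
             bf = correlation_bf(r, length(ids), config$prior)),
        class = "stage_report")
    }
  }
  list(stages = out,
       residuals = list(wm = res_wm, speech = res_sp))
}

#' Run the registered three-stage analysis end to end on a simulated cohort
#'
#' Simulates a cohort, runs the 45-trial discounting phase per participant
#' and domain, scores subjective values, then performs: stage 1, the
#' zero-order Bayesian correlation of domain-mean SVs; stage 2, the
#' correlation of SVs residualised on task level and performance; stage 3,
#' the partial correlation of those residuals controlling for the
#' working-memory-capacity and reward-sensitivity composites. Participants
#' who always chose one option are flagged, and (by default) analyses are
#' reported both with and without them.
#'
#' @param config An [analysis_config()].
#' @return An object of class `coged_pipeline`: list with `stages` (stage
#'   reports on the full sample), `stages_excluded` (same, flagged
#'   participants removed; `NULL` when nothing was flagged or
#'   `exclusion = "keep"`), `sv` (the SV table), `covariates`, `flags`,
#'   `residuals`, `composites` and the `config`.
#' @examples
#' \donttest{
#' cfg <- analysis_config(cohort = cohort_config(n_participants = 40,
#'                                               seed = 7))
#' fit <- run_pipeline(cfg)
#' fit$stages[[1]]$bf
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- generate_cohort(config$cohort)
  records <- list()
  for (i in seq_along(cohort$profiles)) {
    p <- cohort$profiles[[i]]
    for (d in names(coged_domains())) {
      seed_i <- (.participant_seed(config$seed, i) + match(d, c("wm", "speech"))) %%
        2147483647L
      set.seed(seed_i)
      recs <- run_discounting(profile_agent(p, d), d, seed = seed_i,
                              participant_id = p$participant_id)
      records <- c(records, recs)
    }
  }
  svt <- sv_table(records)
  flags <- flag_noncompliance(svt)
  frac <- mean(flags$flagged)
  if (config$exclusion != "keep" && frac > config$max_exclusion_fraction) {
    stop("exclusion rule would remove ", round(100 * frac), "% of the ",
         "cohort; raise max_exclusion_fraction to override", call. = FALSE)
  }
  full <- .run_stages(svt, cohort$covariates, config)
  stages_excluded <- NULL
  if (config$exclusion != "keep" && any(flags$flagged)) {
    keep <- flags$participant_id[!flags$flagged]
    svt_x <- svt[svt$participant_id %in% keep, ]
    cov_x <- cohort$covariates[cohort$covariates$participant_id %in% keep, ]
    stages_excluded <- .run_stages(svt_x, cov_x, config)$stages
  }
  out <- structure(
    list(stages = if (config$exclusion == "drop" &&
                      !is.null(stages_excluded)) stages_excluded
         else full$stages,
         stages_excluded = stages_excluded,
         sv = svt, covariates = cohort$covariates,
         flags = flags, residuals = full$residuals,
         composites = if (any(config$stages >= 3))
           build_composites(cohort$covariates) else NULL,
         profiles = cohort$profiles,
         config = config),
    class = "coged_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_tables(out, config$out_dir)
  out
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("stage %s: %s\n  r = %.4f (n = %d), BF10 = %.4g, ",
              x$stage, x$label, x$sample_r, x$n, x$bf$bf10))
  cat(sprintf("posterior median = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$bf$posterior_median_rho,
              x$bf$credible_interval_95[1], x$bf$credible_interval_95[2]))
  invisible(x)
}

#' @export
print.coged_pipeline <- function(x, ...) {
  cat(sprintf("<coged_pipeline> %d participants, %d flagged\n",
              length(unique(x$sv$participant_id)), sum(x$flags$flagged)))
  for (s in x$stages) print(s)
  if (!is.null(x$stages_excluded)) {
    cat("with flagged participants excluded:\n")
    for (s in x$stages_excluded) print(s)
  }
  invisible(x)
}
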