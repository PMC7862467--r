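#' Sum-of-z-scores composite
#'
#' Standardises each named measure over the analysed sample (mean 0, SD 1
#' in-sample) and sums the z-scores per participant, the construction used
#' for both the working-memory-capacity composite (L-span, O-span,
#' Sym-span totals) and the reward-sensitivity composite (BAS total,
#' GRAPES reward, SPSRQ reward).
#'
#' @param df Data frame with a `participant_id` column and the measures.
#' @param measures Character vector of measure column names.
#' @return Data frame `participant_id`, `composite`.
#' @export
zscore_composite <- function(df, measures) {
  stopifnot("participant_id" %in% names(df), all(measures %in% names(df)))
  if (nrow(df) < 2) {
    stop("need at least 2 participants to z-score", call. = FALSE)
  }
  z <- matrix(0, nrow(df), length(measures))
  for (j in seq_along(measures)) {
    x <- df[[measures[j]]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate input: measure '", measures[j],
           "' has zero variance in this sample", call. = FALSE)
    }
    z[, j] <- (x - mean(x)) / s
  }
  data.frame(participant_id = df$participant_id, composite = rowSums(z))
}

#' Working-memory-capacity and reward-sensitivity composites
#'
#' @param covariates Covariate table from [generate_cohort()] (or any data
#'   frame with the span and reward-scale columns).
#' @return Data frame `participant_id`, `wm_capacity`, `reward_sensitivity`.
#' @export
build_composites <- function(covariates) {
  wm <- zscore_composite(covariates, c("lspan", "ospan", "symspan"))
  rs <- zscore_composite(covariates,
                         c("bas_total", "grapes_reward", "spsrq_reward"))
  data.frame(participant_id = wm$participant_id,
             wm_capacity = wm$composite,
             reward_sensitivity = rs$composite)
}

# map a hard-level label to the covariate column suffix used in the table
.level_suffix <- function(level) {
  gsub("[^0-9]", "", level)
}

.domain_covariate_cols <- function(domain) {
  dom <- .resolve_domain(domain)
  if (dom$name == "wm") {
    lapply(dom$hard_levels, function(l) {
      s <- .level_suffix(l)
      c(dprime = paste0("dprime_", s, "back"), rt = paste0("rt_", s, "back"))
    })
  } else {
    lapply(dom$hard_levels, function(l) {
      c(intelligibility = paste0("intel_", .level_suffix(l)))
    })
  }
}

#' Residualise subjective values on task level and performance
#'
#' Fits an ordinary least-squares model predicting subjective value from
#' task level (categorical) and the domain's performance covariates
#' (N-back: d-prime and mean RT; speech: intelligibility), then averages
#' each participant's row residuals to a single covariate-adjusted score.
#' The default grain is participant x level (level enters the model, so the
#' outcome must vary by level); `grain = "participant"` instead averages
#' SVs and covariates per participant first and omits the level factor.
#'
#' @param svt An [sv_table()] containing the domain's records.
#' @param covariates Covariate table from [generate_cohort()].
#' @param domain Domain name or descriptor.
#' @param grain `"level"` (default) or `"participant"`.
#' @return Data frame `participant_id`, `residual_sv` (in-sample mean 0),
#'   with the fitted model attached as attribute `"model"`.
#' @export
residualize_sv <- function(svt, covariates, domain,
                           grain = c("level", "participant")) {
  grain <- match.arg(grain)
  dom <- .resolve_domain(domain)
  lvl <- level_mean_sv(svt, dom)
  cov_cols <- .domain_covariate_cols(dom)
  names(cov_cols) <- dom$hard_levels
  need <- unique(unlist(cov_cols))
  if (!all(need %in% names(covariates))) {
    stop("covariate table lacks columns: ",
         paste(setdiff(need, names(covariates)), collapse = ", "),
         call. = FALSE)
  }
  rows <- merge(lvl, covariates, by = "participant_id")
  preds <- names(cov_cols[[1]])
  for (p in preds) {
    rows[[p]] <- vapply(seq_len(nrow(rows)), function(i) {
      rows[[cov_cols[[rows$hard_level[i]]][[p]]]][i]
    }, numeric(1))
  }
  # constant performance covariates carry no information; drop them rather
  # than tripping the collinearity check against the intercept
  preds <- preds[vapply(preds, function(p) stats::sd(rows[[p]]) > 0,
                        logical(1))]
  if (grain == "participant") {
    agg <- stats::aggregate(rows[c("sv", preds)],
                            by = rows["participant_id"], FUN = mean)
    fml <- stats::reformulate(if (length(preds)) preds else "1",
                              response = "sv")
    fit <- stats::lm(fml, data = agg)
    .check_full_rank(fit)
    out <- data.frame(participant_id = agg$participant_id,
                      residual_sv = stats::residuals(fit))
  } else {
    fml <- stats::reformulate(c("factor(hard_level)", preds),
                              response = "sv")
    fit <- stats::lm(fml, data = rows)
    .check_full_rank(fit)
    rows$resid <- stats::residuals(fit)
    agg <- stats::aggregate(resid ~ participant_id, data = rows, FUN = mean)
    out <- data.frame(participant_id = agg$participant_id,
                      residual_sv = agg$resid)
  }
  rownames(out) <- NULL
  attr(out, "model") <- fit
  out
}

.check_full_rank <- function(fit) {
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
  }
}
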