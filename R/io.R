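# Delimited-text writers/readers for every pipeline artifact. All files are
# plain TSV with a single header row; reruns with the same config and seed
# produce byte-identical files.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated pipeline table, validating its schema
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return Data frame.
#' @export
read_pipeline_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("parse error in ", basename(path), ": missing columns ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write every artifact of a pipeline run as delimited text
#'
#' Emits, under `dir`: `costs.tsv` (ground-truth proportional costs),
#' `covariates.tsv`, `sv_table.tsv`,
#' `sv_means.tsv` (participant x domain means),
#' `residuals.tsv` and `composites.tsv` (when computed), `flags.tsv`,
#' `stage_reports.tsv`, and `run_info.tsv` recording the seeds and package
#' version.
#'
#' @param pipeline A `coged_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_pipeline_tables <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "coged_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- list(profiles = pipeline$profiles)
  .write_tsv(cohort_cost_table(cohort), file.path(dir, "costs.tsv"))
  .write_tsv(pipeline$covariates, file.path(dir, "covariates.tsv"))
  .write_tsv(pipeline$sv, file.path(dir, "sv_table.tsv"))
  .write_tsv(domain_mean_sv(pipeline$sv), file.path(dir, "sv_means.tsv"))
  .write_tsv(pipeline$flags, file.path(dir, "flags.tsv"))
  if (!is.null(pipeline$residuals$wm)) {
    res <- rbind(cbind(domain = "wm", pipeline$residuals$wm),
                 cbind(domain = "speech", pipeline$residuals$speech))
    .write_tsv(res, file.path(dir, "residuals.tsv"))
  }
  if (!is.null(pipeline$composites)) {
    .write_tsv(pipeline$composites, file.path(dir, "composites.tsv"))
  }
  stage_df <- do.call(rbind, lapply(pipeline$stages, function(s) {
    data.frame(stage = as.character(s$stage), label = s$label,
               sample_r = s$sample_r, n = s$n, bf10 = s$bf$bf10,
               posterior_median_rho = s$bf$posterior_median_rho,
               ci_lower = s$bf$credible_interval_95[1],
               ci_upper = s$bf$credible_interval_95[2],
               prior_family = s$bf$prior$family,
               prior_scale = s$bf$prior$scale,
               prior_sided = s$bf$prior$sided)
  }))
  .write_tsv(stage_df, file.path(dir, "stage_reports.tsv"))
  info <- data.frame(
    key = c("package", "version", "cohort_seed", "discounting_seed",
            "n_participants", "cross_domain_rho"),
    value = c("cogedkit",
              as.character(utils::packageVersion("cogedkit")),
              pipeline$config$cohort$seed, pipeline$config$seed,
              pipeline$config$cohort$n_participants,
              pipeline$config$cohort$cross_domain_rho))
  .write_tsv(info, file.path(dir, "run_info.tsv"))
  invisible(dir)
}

#' Write the full decision-trial log of an SV table's records
#'
#' @param records List of `indifference_record`s.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_trial_log <- function(records, path) {
  rows <- lapply(records, function(r) {
    log <- r$trial_log
    data.frame(participant_id = r$participant_id, domain = r$domain,
               hard_level = r$hard_level, base = r$base_amount,
               trial_index = log$trial_index,
               easy_amount = sprintf("%.4f", log$easy_amount),
               hard_amount = sprintf("%.4f", log$hard_amount),
               choice = log$choice)
  })
  .write_tsv(do.call(rbind, rows), path)
  invisible(path)
}
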