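#' Subjective value of an indifference record
#'
#' Maps an indifference point onto the 0-2 subjective-value scale. When the
#' participant's first (equal-offer) choice was the easy option, the hard
#' option was being discounted and SV is the indifference point divided by
#' the base amount, a value in (0, 1]. When the first choice was the hard
#' option, the easy option was titrated; SV is then
#' `(base - IP) / base + 1`, a value in [1, 2). Values above 1 mark
#' effort-seeking preferences, values below 1 effort avoidance.
#'
#' @param record An `indifference_record` from [run_cell()].
#' @return A single subjective value in (0, 2).
#' @examples
#' rec <- list(first_choice = "easy", indifference_point = 1,
#'             base_amount = 2)
#' class(rec) <- "indifference_record"
#' subjective_value(rec)  # 0.5
#' @export
subjective_value <- function(record) {
  stopifnot(inherits(record, "indifference_record"))
  ip <- record$indifference_point
  base <- record$base_amount
  if (!is.numeric(base) || base <= 0) {
    stop("data error: base amount must be positive", call. = FALSE)
  }
  if (!is.numeric(ip) || ip <= 0 || ip > base) {
    stop("data error: indifference point must lie in (0, base]",
         call. = FALSE)
  }
  if (record$first_choice == "easy") {
    ip / base
  } else {
    (base - ip) / base + 1
  }
}

#' Tabulate subjective values for a set of indifference records
#'
#' @param records List of `indifference_record`s (possibly several
#'   participants and domains).
#' @return Data frame with one row per record: `participant_id`, `domain`,
#'   `hard_level`, `base_amount`, `first_choice`, `indifference_point`,
#'   `sv`.
#' @export
sv_table <- function(records) {
  stopifnot(length(records) > 0)
  get_chr <- function(f) vapply(records, function(r) r[[f]], "")
  get_num <- function(f) vapply(records, function(r) r[[f]], 0)
  data.frame(participant_id = get_chr("participant_id"),
             domain = get_chr("domain"),
             hard_level = get_chr("hard_level"),
             base_amount = get_num("base_amount"),
             first_choice = get_chr("first_choice"),
             indifference_point = get_num("indifference_point"),
             sv = vapply(records, subjective_value, 0))
}

.complete_cells <- function(svt, participant, domain) {
  sub <- svt[svt$participant_id == participant & svt$domain == domain, ]
  dom <- .resolve_domain(domain)
  want <- expand.grid(hard_level = dom$hard_levels, base_amount = c(2, 3, 4),
                      stringsAsFactors = FALSE)
  have <- paste(sub$hard_level, sub$base_amount)
  missing <- setdiff(paste(want$hard_level, want$base_amount), have)
  if (length(missing)) {
    stop("incomplete data for ", participant, " in ", dom$name,
         "; missing cells: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub
}

#' Mean subjective value for one participant in one domain
#'
#' Arithmetic mean over the nine cells (3 levels x 3 base amounts); errors
#' if any cell is absent, naming the missing cells.
#'
#' @param svt An [sv_table()].
#' @param participant Participant id.
#' @param domain Domain name or descriptor.
#' @return A single mean subjective value.
#' @export
average_sv <- function(svt, participant, domain) {
  sub <- .complete_cells(svt, participant, domain)
  mean(sub$sv)
}

#' Per-participant, per-domain mean subjective values
#'
#' @param svt An [sv_table()].
#' @return Data frame `participant_id`, `domain`, `mean_sv`, sorted by
#'   participant then domain; every participant x domain must have its full
#'   nine cells.
#' @export
domain_mean_sv <- function(svt) {
  counts <- stats::aggregate(sv ~ participant_id + domain, data = svt,
                             FUN = length)
  bad <- counts[counts$sv != 9L, ]
  if (nrow(bad)) {
    stop("incomplete data: expected 9 cells per participant x domain; ",
         "offenders: ",
         paste(paste(bad$participant_id, bad$domain), collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(sv ~ participant_id + domain, data = svt,
                          FUN = mean)
  names(agg)[names(agg) == "sv"] <- "mean_sv"
  agg <- agg[order(agg$participant_id, agg$domain), ]
  rownames(agg) <- NULL
  agg
}

#' Per-level mean subjective values
#'
#' Mean SV over the three base amounts within each (participant, domain,
#' level); the grain at which the covariate-adjustment model operates,
#' since task level enters that model as a predictor.
#'
#' @param svt An [sv_table()].
#' @param domain Optional domain filter.
#' @return Data frame `participant_id`, `domain`, `hard_level`, `sv`.
#' @export
level_mean_sv <- function(svt, domain = NULL) {
  if (!is.null(domain)) {
    dom <- .resolve_domain(domain)
    svt <- svt[svt$domain == dom$name, ]
  }
  agg <- stats::aggregate(sv ~ participant_id + domain + hard_level,
                          data = svt, FUN = mean)
  agg[order(agg$participant_id, agg$domain, agg$hard_level), ]
}

#' Exhaustive enumeration of every staircase outcome
#'
#' Replays [run_cell()] for all \eqn{2^5} choice sequences at each base
#' amount and scores the result, enumerating every subjective value the
#' scoring rules can produce. Useful for verifying the (0, 2) bound and the
#' attainable extremes (min 1/32, max 63/32).
#'
#' @param bases Base amounts to enumerate.
#' @return Data frame with one row per (base, choice sequence):
#'   `base_amount`, `choices` (string of e/h), `first_choice`,
#'   `indifference_point`, `sv`.
#' @export
enumerate_staircase_outcomes <- function(bases = c(2, 3, 4)) {
  seqs <- expand.grid(rep(list(c("easy", "hard")), 5),
                      stringsAsFactors = FALSE)
  rows <- vector("list", length(bases) * nrow(seqs))
  k <- 0L
  for (b in bases) {
    for (i in seq_len(nrow(seqs))) {
      choices <- unlist(seqs[i, ], use.names = FALSE)
      idx <- 0L
      scripted <- function(easy_amount, hard_amount) {
        idx <<- idx + 1L
        choices[idx]
      }
      rec <- run_cell(scripted, "wm", "2-back", b)
      k <- k + 1L
      rows[[k]] <- data.frame(
        base_amount = b,
        choices = paste(substr(choices, 1, 1), collapse = ""),
        first_choice = rec$first_choice,
        indifference_point = rec$indifference_point,
        sv = subjective_value(rec))
    }
  }
  do.call(rbind, rows)
}
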