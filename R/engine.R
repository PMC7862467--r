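#' Run one titration cell of the discounting task
#'
#' Implements the five-trial adaptive staircase for a single (hard level,
#' base amount) pairing. Trial 1 offers equal amounts (`base` vs `base`);
#' the option chosen there becomes the titrated side for the rest of the
#' cell. After each of the five choices the titrated offer moves by a
#' halving step (`base / 2^k` after choice `k`): down when the titrated side
#' was chosen (it was still preferred, so it must get cheaper), up when the
#' fixed side was chosen (capped at `base`). The titrated offer after the
#' fifth adjustment is the indifference point, which therefore always lies
#' within `base/32` of a deterministic chooser's true threshold.
#'
#' All step sizes are dyadic fractions of whole-dollar bases, so every
#' amount is represented exactly in floating point; no rounding occurs.
#'
#' @param agent Choice function `(easy_amount, hard_amount)` returning
#'   `"easy"` or `"hard"`, e.g. from [make_threshold_agent()].
#' @param domain Domain name or descriptor (see [coged_domains()]).
#' @param hard_level Label of the hard option's load level.
#' @param base Base amount in dollars; one of 2, 3, 4.
#' @param participant_id Optional id carried into the record.
#' @return An object of class `indifference_record`: list with
#'   `participant_id`, `domain`, `hard_level`, `base_amount`,
#'   `first_choice`, `indifference_point` and the five-row `trial_log`.
#' @examples
#' always_easy <- function(easy_amount, hard_amount) "easy"
#' rec <- run_cell(always_easy, "wm", "2-back", base = 2)
#' rec$trial_log
#' rec$indifference_point  # 0.0625 = 2 - 1 - 0.5 - 0.25 - 0.125 - 0.0625
#' @export
run_cell <- function(agent, domain, hard_level, base,
                     participant_id = NA_character_) {
  dom <- .resolve_domain(domain)
  if (!base %in% c(2, 3, 4)) {
    stop("base amount must be one of $2, $3, $4", call. = FALSE)
  }
  if (!hard_level %in% dom$hard_levels) {
    stop("unknown hard level '", hard_level, "' for domain ", dom$name,
         call. = FALSE)
  }
  easy_amt <- base
  hard_amt <- base
  titrated <- NULL
  log_easy <- log_hard <- numeric(5)
  log_choice <- character(5)
  for (k in 1:5) {
    log_easy[k] <- easy_amt
    log_hard[k] <- hard_amt
    choice <- agent(easy_amt, hard_amt)
    if (!identical(choice, "easy") && !identical(choice, "hard")) {
      stop("protocol error: agent must return \"easy\" or \"hard\"",
           call. = FALSE)
    }
    log_choice[k] <- choice
    if (k == 1L) titrated <- choice
    step <- base / 2^k
    cur <- if (titrated == "easy") easy_amt else hard_amt
    cur <- if (choice == titrated) cur - step else min(cur + step, base)
    if (titrated == "easy") easy_amt <- cur else hard_amt <- cur
  }
  # bare-metal data.frame: run_cell is called thousands of times per cohort
  log <- structure(list(trial_index = 1:5, easy_amount = log_easy,
                        hard_amount = log_hard, choice = log_choice),
                   class = "data.frame", row.names = c(NA, -5L))
  ip <- if (titrated == "easy") easy_amt else hard_amt
  structure(
    list(participant_id = participant_id,
         domain = dom$name,
         hard_level = hard_level,
         base_amount = base,
         first_choice = titrated,
         indifference_point = ip,
         trial_log = log),
    class = "indifference_record")
}

#' @export
print.indifference_record <- function(x, ...) {
  cat(sprintf("<indifference_record> %s %s vs baseline, base $%.2f\n",
              x$domain, x$hard_level, x$base_amount))
  cat(sprintf("  first choice: %s   indifference point: $%.4f\n",
              x$first_choice, x$indifference_point))
  invisible(x)
}

#' Run the full discounting phase for one domain
#'
#' Nine cells (3 hard levels x base amounts $2, $3, $4), five calibration
#' trials each: 45 decision trials per domain. Cell presentation order is
#' shuffled under `seed` when given (the agents here are memoryless, so
#' order only affects the log ordering and any RNG consumption by noisy
#' agents).
#'
#' @param agent Function `(easy_amount, hard_amount, hard_level, base)`
#'   returning `"easy"` or `"hard"`; see [profile_agent()].
#' @param domain Domain name or descriptor with exactly 3 hard levels.
#' @param seed Optional integer seed for the cell order.
#' @param participant_id Optional id carried into the records.
#' @param bases Base amounts; fixed at $2/$3/$4 by default.
#' @return List of 9 `indifference_record`s.
#' @export
run_discounting <- function(agent, domain, seed = NULL,
                            participant_id = NA_character_,
                            bases = c(2, 3, 4)) {
  dom <- .resolve_domain(domain)
  if (length(dom$hard_levels) != 3L) {
    stop("configuration error: domain must declare exactly 3 hard levels",
         call. = FALSE)
  }
  cells <- expand.grid(hard_level = dom$hard_levels, base = bases,
                       stringsAsFactors = FALSE)
  if (!is.null(seed)) {
    set.seed(seed)
    cells <- cells[sample.int(nrow(cells)), ]
  }
  lapply(seq_len(nrow(cells)), function(i) {
    lvl <- cells$hard_level[i]
    b <- cells$base[i]
    cell_agent <- function(easy_amount, hard_amount) {
      agent(easy_amount, hard_amount, lvl, b)
    }
    run_cell(cell_agent, dom, lvl, b, participant_id = participant_id)
  })
}
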