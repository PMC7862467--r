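# Simple deterministic agents used across the engine and scoring tests.

always_easy <- function(easy_amount, hard_amount) "easy"
always_hard <- function(easy_amount, hard_amount) "hard"

# chooses the easy (titrated-when-first-chosen) option iff its offer meets a
# fixed dollar threshold; at equal offers above threshold it picks easy
easy_threshold_agent <- function(threshold) {
  force(threshold)
  function(easy_amount, hard_amount) {
    if (easy_amount >= threshold) "easy" else "hard"
  }
}

# utility agent with a proportional cost of the hard option: the analytic
# indifference offer is base * (1 - cost) when cost > 0 (easy side titrated)
# and base * (1 + cost) when cost < 0 (hard side titrated)
proportional_cost_agent <- function(cost, base) {
  force(cost); force(base)
  function(easy_amount, hard_amount) {
    if (easy_amount >= hard_amount - cost * base) "easy" else "hard"
  }
}

# replays a fixed choice sequence
scripted_agent <- function(choices) {
  idx <- 0L
  function(easy_amount, hard_amount) {
    idx <<- idx + 1L
    choices[idx]
  }
}

# a hand-built profile with known costs, for engine/pipeline tests
fixed_profile <- function(id = "PX", wm_costs = c(0.3, 0.45, 0.6),
                          speech_costs = c(0.3, 0.45, 0.6),
                          temperature = 0) {
  costs <- c(wm_costs, speech_costs)
  names(costs) <- c("wm:2-back", "wm:3-back", "wm:4-back",
                    "speech:-4dB", "speech:-8dB", "speech:-12dB")
  structure(list(participant_id = id, motivation_factor = 0,
                 domain_costs = costs, wm_capacity_latent = 0,
                 reward_sensitivity_latent = 0,
                 temperature = temperature),
            class = "participant_profile")
}
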