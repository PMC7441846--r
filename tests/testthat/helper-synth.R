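# Small configuration for fast structural tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_units = 8, n_participants = 400,
    inventories = data.frame(name = "INV1", items_per_trait = 4,
                             sampling_rate = 1.0),
    seed = 101
  )
  do.call(synth_config, utils::modifyList(defaults, args))
}

# One moderate study shared across test files (defaults = SAPA-like regime)
shared_cfg <- synth_config(n_participants = 6000, seed = 2024)
shared_sim <- simulate_study(shared_cfg, sample_id = "shared")
shared_scores <- score_scales(shared_sim$responses, shared_sim$bank, "INV1")
shared_table <- aggregate_states(shared_scores)

# Build a response_table directly from explicit item answers.
# answers: data.frame(participant_id, unit, item_id, response)
manual_responses <- function(answers, likert_min = 1, likert_max = 6) {
  parts <- unique(answers[c("participant_id", "unit")])
  response_table(parts, answers[c("participant_id", "item_id", "response")],
                 likert_min = likert_min, likert_max = likert_max,
                 sample_id = "manual")
}

# Minimal item bank from vectors
manual_bank <- function(item_id, trait, keying = 1L, inventory = "INV1",
                        sampling_rate = 1) {
  data.frame(item_id = item_id, inventory = inventory, trait = trait,
             keying = rep_len(keying, length(item_id)),
             sampling_rate = sampling_rate, stringsAsFactors = FALSE)
}
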