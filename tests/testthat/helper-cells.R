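# simulate participant-averaged cell means directly from the linear model
# used by the inference layer: random participant intercepts (sd
# `sd_participant`), fixed congruency/cue effects, optional interaction,
# residual sd per cell mean
sim_cells <- function(n, b_congruency = 40, b_cue = 5, b_interaction = 0,
                      sd_participant = 40, sd_resid = 30, seed = 1) {
  set.seed(seed)
  id <- sprintf("p%03d", seq_len(n))
  u <- rnorm(n, 0, sd_participant)
  g <- expand.grid(participant_id = id,
                   congruency = c("congruent", "incongruent"),
                   cue = c("informative", "non_informative"),
                   stringsAsFactors = FALSE)
  g$mean_rt_ms <- 450 +
    b_congruency * (g$congruency == "incongruent") +
    b_cue * (g$cue == "non_informative") +
    b_interaction * (g$congruency == "incongruent") *
      (g$cue == "non_informative") +
    u[match(g$participant_id, id)] +
    rnorm(nrow(g), 0, sd_resid)
  g
}

# minimal trial data.frame for behavioural-layer tests
make_trials <- function(participant_id, rt_ms, congruency = "congruent",
                        cue = "informative", correct = TRUE,
                        is_catch = FALSE) {
  n <- max(lengths(list(participant_id, rt_ms, congruency, cue, correct,
                        is_catch)))
  data.frame(participant_id = rep_len(participant_id, n),
             block = 1L, trial_in_block = seq_len(n),
             cue = rep_len(cue, n), congruency = rep_len(congruency, n),
             target_identity = "B", target_location = 0L, foil_location = 1L,
             is_catch = rep_len(is_catch, n), rt_ms = rep_len(rt_ms, n),
             correct = rep_len(correct, n), stringsAsFactors = FALSE)
}
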