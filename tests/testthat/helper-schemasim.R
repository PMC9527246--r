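# shared fixtures, built in code

# small cohort for fast tests
tiny_config <- function(n = 4, ...) {
  a <- n %/% 2
  cohort_config(n_participants = n, group_split = c(A = a, B = n - a), ...)
}

# hand-built trial metadata for similarity pairing tests
toy_meta <- function(runs, scenes, congruency = "congruent",
                     grain = "detailed", participant = "p1", delay = "short") {
  sc <- scene_table()
  data.frame(
    participant = participant, delay = delay, run_index = runs,
    trial_index = seq_along(runs), object_id = sprintf("o%02d", seq_along(runs)),
    scene_id = scenes, context = sc$context[match(scenes, sc$scene_id)],
    congruency = congruency, grain = grain, stringsAsFactors = FALSE
  )
}

# events table for a toy retrieval run with labeled outcomes
toy_run_events <- function(n_trials, spacing = 12, grain = "detailed",
                           congruency = "congruent") {
  data.frame(
    onset = (seq_len(n_trials) - 1) * spacing,
    dur_cue = 2, dur_context_resp = 2, dur_scene_resp = 2,
    grain = rep_len(grain, n_trials),
    congruency = rep_len(congruency, n_trials),
    stringsAsFactors = FALSE
  )
}

# independent Williams-test oracle: Hotelling-Williams statistic written in
# the textbook arrangement (kept separate from the package's implementation)
williams_oracle <- function(r12, r13, r23, n) {
  R <- (1 - r12^2 - r13^2 - r23^2) + 2 * r12 * r13 * r23
  rm2 <- ((r12 + r13) / 2)^2
  num <- (r12 - r13) * sqrt((n - 1) * (1 + r23))
  den <- sqrt(2 * R * (n - 1) / (n - 3) + rm2 * (1 - r23)^3)
  num / den
}

# sample skewness (moment estimator), used as an oracle for the sqrt rule
skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
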