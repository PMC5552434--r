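# Shared fixtures, generated once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small representational monkey cohort (2 subjects x 5 sessions).
small_monkey_cohort <- function() memo("small_monkey", {
  generate_cohort(species_profile("monkey", sessions_per_subject = 5),
                  default_agent_config("monkey"),
                  rt_cfg = rt_config(), n_subjects = 2, seed = 101)
})

# Small naive (human-like) cohort, 12 single-session subjects.
small_human_cohort <- function() memo("small_human", {
  generate_cohort(species_profile("human"),
                  default_agent_config("human"),
                  rt_cfg = rt_config(species = "human"),
                  n_subjects = 12, seed = 202)
})

# Cohort with constant correct-choice probability p across all trials.
constant_p_cohort <- function(p = 0.5, n_sessions = 8, seed = 303) {
  prof <- species_profile("human", sessions_per_subject = 1)
  cfg <- parametric_config(function(sched) rep(p, nrow(sched)))
  generate_cohort(prof, cfg, rt_cfg = rt_config(), n_subjects = n_sessions,
                  seed = seed)
}

# Truncate a schedule to phase 1 plus the first n2 phase-2 trials: enough
# to observe the massed-transition signature cheaply.
truncated_schedule <- function(profile, seed, n2 = 12L) {
  s <- build_schedule(profile, seed = seed)
  rbind(s[s$phase == 1, ], head(s[s$phase == 2, ], n2))
}

# First-xF outcome (correct indicator) of one simulated session.
first_xf_correct <- function(records) {
  p2 <- records[records$phase == 2 & records$item_hi == "F", , drop = FALSE]
  p2 <- p2[order(p2$trial_index), , drop = FALSE]
  if (nrow(p2) == 0L) return(NA_integer_)
  p2$correct[1L]
}
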