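# hand-built 6-row valid trial table used by the io tests
tiny_trials <- function() {
  data.frame(
    subject_id = rep("S01", 6),
    group = "trained",
    session_index = c(1L, 1L, 1L, 2L, 2L, 2L),
    session_role = "training",
    effector = "hand",
    difficulty = c(0, 0.31, 1, 0.31, 1, 3.16),
    stimulus = c("neutral", "CW", "CCW", "CW", "CCW", "CW"),
    choice = c("CW", "CW", "CW", "CCW", "CCW", "CW"),
    correct = c(NA, TRUE, FALSE, FALSE, TRUE, TRUE),
    rt = c(0.512345, 0.43, 0.61, 0.55, 0.72, 0.38),
    timeout_redraws = c(0L, 0L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

# small fast design for simulation-based tests
quick_design <- function(...) {
  experiment_design(n_training_sessions = 2, has_transfer = TRUE,
                    difficulties = c(0, 0.5, 2),
                    trials_per_signed_level = 8, ...)
}

quick_truth <- function(...) {
  ground_truth(beta = c(0.6, 1.0), z = c(0.47, 0.5), ...)
}

n_trials_per_session_for_test <- function(design) {
  design$trials_per_signed_level *
    (sum(design$difficulties == 0) + 2L * sum(design$difficulties > 0))
}
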