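# Shared default designs, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

agl_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_d1n <- function() agl_fixture("d1n", function() {
  agl_design(1, "nested", seed = 101)
})
fx_d1c <- function() agl_fixture("d1c", function() {
  agl_design(1, "cross-serial", seed = 102)
})
fx_d2n <- function() agl_fixture("d2n", function() {
  agl_design(2, "nested", seed = 103)
})
fx_d2c <- function() agl_fixture("d2c", function() {
  agl_design(2, "cross-serial", seed = 104)
})

# First five pairs only: small enough for exhaustive grammar enumeration.
reduced_lexicon <- function() agl_lexicon()[1:5, ]

# A minimal test-phase-only design wrapper for large-n estimator checks:
# n_correct members + n_incorrect non-members, sequences are placeholders
# (the SDT simulant only looks at labels).
synthetic_test_design <- function(n_correct, n_incorrect) {
  n <- n_correct + n_incorrect
  trials <- data.frame(
    index = seq_len(n),
    phase = "test",
    length_class = "medium",
    n_pairs = 3L,
    sequence = paste("seq", seq_len(n)),
    label = rep(c("correct", "incorrect"), c(n_correct, n_incorrect)),
    foil_subset = "none",
    repeat_probe = FALSE,
    grammar_of_sequence = "nested",
    test_position = seq_len(n),
    stringsAsFactors = FALSE
  )
  structure(list(experiment = 1L, group = "nested", seed = 0L,
                 config = agl_config(1), trials = trials),
            class = "agl_design")
}

# All permutations of a small integer vector.
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

# Yes/no accuracy of a response log against the design's labels.
log_accuracy <- function(log, design) {
  tr <- design$trials
  lab <- tr$label[match(log$trial_index, tr$index)]
  mean((log$answer == "yes") == (lab == "correct"))
}
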