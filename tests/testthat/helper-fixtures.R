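# Shared fixtures: all data are generated in code at test time.

# A full default schedule (8 blocks x 30 trials), cached per session.
fixture_schedule <- local({
  cache <- new.env()
  function(seed = 101) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- build_schedule(seed = seed)
    cache[[key]]
  }
})

# One simulated subject with known parameters.
fixture_subject <- function(seed = 202, params = rl_params(0.6, 0.2, 5),
                            sched_seed = 101) {
  sched <- fixture_schedule(sched_seed)
  set.seed(seed)
  simulate_subject(params, sched, subject_id = sprintf("fx%d", seed))
}

# A hand-built single-block dataset with fully controlled outcomes/choices.
manual_dataset <- function(value_1, value_2, choice, block_type = "BHNH",
                           subject_id = "manual") {
  n <- length(choice)
  stopifnot(length(value_1) == n, length(value_2) == n)
  trials <- tibble::tibble(
    block_index = 1L,
    block_type = block_type,
    is_equal_mean = block_type %in% c("BHNH", "BLNL"),
    trial_index = seq_len(n),
    value_1 = as.integer(value_1),
    value_2 = as.integer(value_2),
    outcome_1 = rescale_value(value_1),
    outcome_2 = rescale_value(value_2),
    choice = as.integer(choice),
    points = as.integer(ifelse(choice == 1L, value_1 - value_2,
                               value_2 - value_1))
  )
  structure(
    list(subject_id = subject_id, schedule = NULL, trials = trials,
         traits = NULL, params_true = NULL),
    class = "subject_dataset"
  )
}

# Replace a subject's choices with the output of `fn(trials)` (an integer
# vector), keeping outcomes fixed; used to plant exclusion-rule violations.
override_choices <- function(dataset, fn) {
  dataset$trials$choice <- as.integer(fn(dataset$trials))
  dataset$trials$points <- as.integer(ifelse(
    dataset$trials$choice == 1L,
    dataset$trials$value_1 - dataset$trials$value_2,
    dataset$trials$value_2 - dataset$trials$value_1
  ))
  dataset
}

# Index of the broader / higher-mean deck per block type (mirrors the
# package's role labelling; recomputed here from first principles).
fx_broader <- c(BHNL = 1L, NHBL = 2L, BHBL = NA, BHNH = 1L, BLNL = 1L)
fx_higher <- c(BHNL = 1L, NHBL = 1L, BHBL = 1L, BHNH = NA, BLNL = NA)
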