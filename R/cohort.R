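#' Simulate one subject performing the task
#'
#' A softmax Rescorla-Wagner agent plays the full schedule: expected values
#' start at 0.5 for each block's fresh decks, the choice is sampled from the
#' softmax of the current value difference, and both decks' values are updated
#' from their own revealed (rescaled) outcomes with the sign-dependent
#' learning rate. Card values are drawn from the deck pmfs; points per trial
#' equal the chosen minus the unchosen raw card value.
#'
#' Uses R's global random-number stream; call [set.seed()] first (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param params An `rl_params`.
#' @param schedule A `task_schedule`.
#' @param subject_id Subject label.
#' @param traits Optional named list/vector with `stai` and `sds` raw scores.
#' @return An object of class `subject_dataset`: list with `subject_id`,
#'   `schedule`, `trials` (tibble: block/trial indices, block type, card
#'   values, rescaled outcomes, choice, points), `traits`, and
#'   `params_true` (the generating parameters).
#' @export
simulate_subject <- function(params, schedule, subject_id = "sim01",
                             traits = NULL) {
  stopifnot(inherits(params, "rl_params"), inherits(schedule, "task_schedule"))
  trials <- purrr::map_dfr(seq_along(schedule$blocks), function(b) {
    bl <- schedule$blocks[[b]]
    out <- draw_block_outcomes(bl)
    nt <- bl$n_trials
    R1 <- rescale_value(out$value_1)
    R2 <- rescale_value(out$value_2)
    choice <- integer(nt)
    V1 <- 0.5; V2 <- 0.5
    for (i in seq_len(nt)) {
      p1 <- stats::plogis(params$beta * (V1 - V2))
      choice[i] <- if (runif(1) < p1) 1L else 2L
      d1 <- R1[i] - V1
      d2 <- R2[i] - V2
      V1 <- V1 + (if (d1 >= 0) params$alpha_pos else params$alpha_neg) * d1
      V2 <- V2 + (if (d2 >= 0) params$alpha_pos else params$alpha_neg) * d2
    }
    tibble(
      block_index = b,
      block_type = bl$block_type,
      is_equal_mean = bl$is_equal_mean,
      trial_index = seq_len(nt),
      value_1 = out$value_1,
      value_2 = out$value_2,
      outcome_1 = R1,
      outcome_2 = R2,
      choice = choice,
      points = ifelse(choice == 1L, out$value_1 - out$value_2,
                      out$value_2 - out$value_1)
    )
  })
  structure(
    list(subject_id = subject_id, schedule = schedule, trials = trials,
         traits = traits, params_true = params),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s: %d trials in %d blocks, %d points\n",
              x$subject_id, nrow(x$trials),
              length(unique(x$trials$block_index)), sum(x$trials$points)))
  invisible(x)
}

#' Generate a simulated cohort
#'
#' Samples per-subject learning parameters, alternates the equal-mean-first
#' starting condition across subjects, simulates task behavior, and couples
#' anxiety-depression trait scores to each subject's negative learning-rate
#' bias. The trait construction works on the standardized bias: the latent
#' trait factor is `rho * z(bias) + sqrt(1 - rho^2) * noise`, so its expected
#' Pearson correlation with the bias is `rho`; STAI and SDS raw scores are
#' noisy integer mappings of that factor onto the 20-80 questionnaire range.
#' With the default `trait_rho = 0.5`, more anxious-depressed subjects have a
#' larger negative learning-rate bias and hence a weaker provariance bias.
#'
#' @param n_subjects Number of subjects (default 49, the analyzed sample size
#'   this generator emulates).
#' @param seed Master integer seed; the full cohort is reproducible from it.
#' @param alpha_range,beta_range Uniform sampling ranges for the learning
#'   rates and inverse temperature.
#' @param trait_rho Correlation (in \[-1, 1\]) between the latent trait factor
#'   and the negative learning-rate bias.
#' @param scale_noise_sd SD of the per-questionnaire noise added to the latent
#'   factor before mapping to raw scores.
#' @param n_trials,dist_params,jitter_range Passed to [build_schedule()].
#' @return An object of class `cohort`: list of `subject_dataset`s with a
#'   `config` attribute.
#' @export
#' @examples
#' coh <- generate_cohort(n_subjects = 3, seed = 7)
#' length(coh)
generate_cohort <- function(n_subjects = 49, seed = 1,
                            alpha_range = c(0.05, 0.95),
                            beta_range = c(1, 10),
                            trait_rho = 0.5,
                            scale_noise_sd = 0.15,
                            n_trials = 30,
                            dist_params = deck_params(),
                            jitter_range = c(1, 3)) {
  if (abs(trait_rho) > 1) abort("`trait_rho` must lie in [-1, 1].")
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  set.seed(as.integer(seed))
  alpha_pos <- runif(n_subjects, alpha_range[1], alpha_range[2])
  alpha_neg <- runif(n_subjects, alpha_range[1], alpha_range[2])
  beta <- runif(n_subjects, beta_range[1], beta_range[2])
  bias <- alpha_neg / (alpha_pos + alpha_neg)

  zb <- as.numeric(scale(bias))
  latent <- trait_rho * zb + sqrt(1 - trait_rho^2) * rnorm(n_subjects)
  stai_z <- latent + rnorm(n_subjects, sd = scale_noise_sd)
  sds_z <- latent + rnorm(n_subjects, sd = scale_noise_sd)
  to_raw <- function(z) pmin(pmax(as.integer(round(45 + 10 * z)), 20L), 80L)
  stai <- to_raw(stai_z)
  sds <- to_raw(sds_z)

  sub_seeds <- sample.int(.Machine$integer.max, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sched <- build_schedule(seed = sub_seeds[i], n_trials = n_trials,
                            start_equal = i %% 2 == 1,
                            dist_params = dist_params,
                            jitter_range = jitter_range)
    # build_schedule reseeds the stream; sub_seeds[i] also governs behavior
    simulate_subject(
      rl_params(alpha_pos[i], alpha_neg[i], beta[i]), sched,
      subject_id = sprintf("sim%03d", i),
      traits = list(stai = stai[i], sds = sds[i])
    )
  })
  structure(subjects,
            class = "cohort",
            config = list(n_subjects = n_subjects, seed = as.integer(seed),
                          alpha_range = alpha_range, beta_range = beta_range,
                          trait_rho = trait_rho,
                          scale_noise_sd = scale_noise_sd,
                          n_trials = n_trials))
}

#' @export
print.cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cohort> %d simulated subjects (seed %d, trait rho %.2f)\n",
              length(x), cfg$seed, cfg$trait_rho))
  invisible(x)
}

#' Ground-truth parameter table of a simulated cohort
#'
#' @param cohort A `cohort`.
#' @return Tibble with one row per subject: generating parameters, negative
#'   learning-rate bias, and trait scores.
#' @export
cohort_params <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    p <- s$params_true
    tibble(
      subject_id = s$subject_id,
      alpha_pos = p$alpha_pos,
      alpha_neg = p$alpha_neg,
      beta = p$beta,
      lr_neg_bias = negative_bias(p),
      stai = s$traits$stai,
      sds = s$traits$sds
    )
  })
}

COHORT_TRIAL_COLS <- c(
  "subject_id", "block_index", "block_type", "is_equal_mean", "trial_index",
  "value_1", "value_2", "outcome_1", "outcome_2", "choice", "points",
  "choice_onset", "rt", "fb1_onset", "fb1_dur", "fb2_onset", "fb2_dur",
  "fb3_onset", "fb3_dur", "chosen_first", "deck1_side"
)

#' Save / load a cohort as delimited tables
#'
#' Writes two CSVs: `trials.csv` (trial-level choices, outcomes and event
#' timings, one row per subject x trial) and `subjects.csv` (trait scores and,
#' for simulated cohorts, ground-truth parameters). `load_cohort` rebuilds the
#' cohort and errors with the offending column name when a required column is
#' missing.
#'
#' @param cohort A `cohort`.
#' @param dir Directory to write to / read from (created if absent).
#' @return `save_cohort` invisibly returns `dir`; `load_cohort` returns a
#'   `cohort`.
#' @export
save_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- purrr::map_dfr(cohort, function(s) {
    dplyr::bind_cols(
      tibble(subject_id = s$subject_id),
      s$trials,
      s$schedule$trials %>%
        select("choice_onset", "rt", "fb1_onset", "fb1_dur",
               "fb2_onset", "fb2_dur", "fb3_onset", "fb3_dur",
               "chosen_first", "deck1_side")
    )
  })
  readr::write_csv(trials[, COHORT_TRIAL_COLS], file.path(dir, "trials.csv"))

  subjects <- purrr::map_dfr(cohort, function(s) {
    p <- s$params_true
    tibble(
      subject_id = s$subject_id,
      stai = as.integer(s$traits$stai %||% NA_integer_),
      sds = as.integer(s$traits$sds %||% NA_integer_),
      alpha_pos = if (is.null(p)) NA_real_ else p$alpha_pos,
      alpha_neg = if (is.null(p)) NA_real_ else p$alpha_neg,
      beta = if (is.null(p)) NA_real_ else p$beta,
      schedule_seed = s$schedule$seed,
      start_equal = s$schedule$start_equal
    )
  })
  readr::write_csv(subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}

require_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  file, paste(missing, collapse = ", ")))
  }
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  tr_path <- file.path(dir, "trials.csv")
  su_path <- file.path(dir, "subjects.csv")
  trials <- readr::read_csv(tr_path, show_col_types = FALSE,
                            col_types = readr::cols(subject_id = "c"))
  subjects <- readr::read_csv(su_path, show_col_types = FALSE,
                              col_types = readr::cols(subject_id = "c"))
  require_cols(trials, COHORT_TRIAL_COLS, tr_path)
  require_cols(subjects, c("subject_id", "stai", "sds"), su_path)

  subs <- lapply(split(trials, factor(trials$subject_id,
                                      levels = unique(trials$subject_id))),
                 identity)
  cohort <- lapply(names(subs), function(id) {
    str <- subs[[id]]
    srow <- subjects[subjects$subject_id == id, , drop = FALSE]
    if (nrow(srow) != 1) {
      abort(sprintf("Subject '%s' has %d rows in subjects.csv (expected 1).",
                    id, nrow(srow)))
    }
    sched <- NULL
    if (!is.null(srow$schedule_seed) && !is.na(srow$schedule_seed)) {
      sched <- build_schedule(seed = srow$schedule_seed,
                              n_trials = max(str$trial_index),
                              start_equal = isTRUE(srow$start_equal))
    }
    params <- NULL
    if (!is.null(srow$alpha_pos) && !is.na(srow$alpha_pos)) {
      params <- rl_params(srow$alpha_pos, srow$alpha_neg, srow$beta)
    }
    core <- as_tibble(str[, setdiff(COHORT_TRIAL_COLS,
                                    c("subject_id", "choice_onset", "rt",
                                      "fb1_onset", "fb1_dur", "fb2_onset",
                                      "fb2_dur", "fb3_onset", "fb3_dur",
                                      "chosen_first", "deck1_side"))])
    for (cl in c("block_index", "trial_index", "value_1", "value_2",
                 "choice", "points")) {
      core[[cl]] <- as.integer(core[[cl]])
    }
    # rescaled outcomes are a pure function of the card values; recompute
    # rather than trust text round-tripping of doubles to the last bit
    core$outcome_1 <- rescale_value(core$value_1)
    core$outcome_2 <- rescale_value(core$value_2)
    structure(
      list(
        subject_id = id,
        schedule = sched,
        trials = core,
        traits = list(stai = as.integer(srow$stai), sds = as.integer(srow$sds)),
        params_true = params
      ),
      class = "subject_dataset"
    )
  })
  structure(cohort, class = "cohort",
            config = list(n_subjects = length(cohort), seed = NA_integer_))
}
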