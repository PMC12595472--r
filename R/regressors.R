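#' Event regressors for the first fMRI design (sign-split prediction errors)
#'
#' Builds the 12 event regressors of the first-level design in which the
#' chosen and unchosen decks' prediction errors are split by sign: a response
#' event at the button press, a parametric reaction-time regressor and a mean
#' (all-ones) regressor at the choice phase; parametric + mean pairs for the
#' chosen deck's positive prediction errors, the chosen deck's negative
#' prediction errors, and likewise for the unchosen deck, each placed at the
#' onset of that deck's card reveal (first or second feedback according to
#' the trial's reveal order) with the card's display duration; and a mean
#' regressor at the joint (3rd) feedback. Negative-PE weights are flipped in
#' sign (so larger = more negative surprise) before demeaning. Parametric
#' weights are demeaned within regressor so each parametric column is
#' orthogonal to its paired mean column.
#'
#' @param dataset A `subject_dataset` whose schedule carries event timings.
#' @param trajectory Output of [run_model()] over all blocks of `dataset`.
#' @param demean Demean parametric weights within regressor (default `TRUE`).
#' @return An object of class `regressor_table`: tibble with columns
#'   `regressor`, `block_index`, `trial_index`, `onset`, `duration`,
#'   `weight`, plus a `manifest` attribute mapping regressor names to design
#'   beta indices.
#' @export
glm1_events <- function(dataset, trajectory, demean = TRUE) {
  ev <- event_frame(dataset, trajectory)

  choice_rows <- ev %>%
    dplyr::distinct(.data$block_index, .data$trial_index, .keep_all = TRUE)
  choice <- bind_rows(
    choice_rows %>%
      mutate(regressor = "response", onset = .data$choice_onset + .data$rt,
             duration = 0.1, weight = 1),
    choice_rows %>%
      mutate(regressor = "rt_parametric", onset = .data$choice_onset,
             duration = .data$rt, weight = .data$rt),
    choice_rows %>%
      mutate(regressor = "choice_mean", onset = .data$choice_onset,
             duration = .data$rt, weight = 1)
  )

  pe <- ev %>%
    mutate(
      role = ifelse(.data$chosen, "chosen", "unchosen"),
      sign = ifelse(.data$delta >= 0, "ppe", "npe"),
      regressor = paste(role, sign, "parametric", sep = "_"),
      onset = .data$reveal_onset,
      duration = .data$reveal_dur,
      weight = abs(.data$delta)  # NPEs sign-flipped; PPEs unchanged
    )
  pe_mean <- pe %>%
    mutate(regressor = sub("parametric$", "mean", .data$regressor),
           weight = 1)

  fb3 <- choice_rows %>%
    mutate(regressor = "feedback3_mean", onset = .data$fb3_onset,
           duration = .data$fb3_dur, weight = 1)

  manifest <- c(
    response = 1, rt_parametric = 2, choice_mean = 3,
    chosen_ppe_parametric = 4, chosen_ppe_mean = 5,
    chosen_npe_parametric = 6, chosen_npe_mean = 7,
    unchosen_ppe_parametric = 8, unchosen_ppe_mean = 9,
    unchosen_npe_parametric = 10, unchosen_npe_mean = 11,
    feedback3_mean = 12
  )
  finalize_regressors(bind_rows(choice, pe, pe_mean, fb3), manifest,
                      demean = demean)
}

#' Event regressors for the second fMRI design (signed PEs per deck role)
#'
#' Equal-mean blocks only. Builds the 12 regressors of the design that keeps
#' prediction errors signed but splits them by deck role (broader vs
#' narrower) and choice status: response, parametric expected-value
#' difference (chosen minus unchosen value at the choice phase, from the
#' trajectory's pre-update values) and choice mean; parametric + mean pairs
#' for each of broader-chosen, broader-unchosen, narrower-chosen and
#' narrower-unchosen reveals; and the joint-feedback mean. Each trial
#' contributes its broader deck's PE to exactly one of the broader cells and
#' its narrower deck's PE to the complementary narrower cell.
#'
#' @inheritParams glm1_events
#' @return A `regressor_table` (see [glm1_events()]).
#' @export
glm2_events <- function(dataset, trajectory, demean = TRUE) {
  ev <- event_frame(dataset, trajectory)
  if (any(!ev$is_equal_mean)) {
    ev <- ev %>% filter(.data$is_equal_mean)
  }
  if (nrow(ev) == 0) abort("No equal-mean-block trials in the dataset.")

  ev <- ev %>%
    mutate(broader = .data$deck ==
             vapply(.data$block_type, broader_deck, integer(1)))

  ev_wide <- ev %>%
    select("block_index", "trial_index", "chosen", "deck", "V_pre") %>%
    tidyr::pivot_wider(names_from = "deck", values_from = c("V_pre", "chosen"),
                       names_prefix = "d")
  ev_wide <- ev_wide %>%
    mutate(ev_diff = ifelse(.data$chosen_d1,
                            .data$V_pre_d1 - .data$V_pre_d2,
                            .data$V_pre_d2 - .data$V_pre_d1))

  choice_rows <- ev %>%
    dplyr::distinct(.data$block_index, .data$trial_index, .keep_all = TRUE) %>%
    left_join(ev_wide %>% select("block_index", "trial_index", "ev_diff"),
              by = c("block_index", "trial_index"))

  choice <- bind_rows(
    choice_rows %>%
      mutate(regressor = "response", onset = .data$choice_onset + .data$rt,
             duration = 0.1, weight = 1),
    choice_rows %>%
      mutate(regressor = "ev_diff_parametric", onset = .data$choice_onset,
             duration = .data$rt, weight = .data$ev_diff),
    choice_rows %>%
      mutate(regressor = "choice_mean", onset = .data$choice_onset,
             duration = .data$rt, weight = 1)
  )

  pe <- ev %>%
    mutate(
      role = paste0(ifelse(.data$broader, "broader", "narrower"), "_",
                    ifelse(.data$chosen, "chosen", "unchosen")),
      regressor = paste0(role, "_pe_parametric"),
      onset = .data$reveal_onset,
      duration = .data$reveal_dur,
      weight = .data$delta  # signed: PPE and NPE combined
    )
  pe_mean <- pe %>%
    mutate(regressor = sub("parametric$", "mean", .data$regressor),
           weight = 1)

  fb3 <- choice_rows %>%
    mutate(regressor = "feedback3_mean", onset = .data$fb3_onset,
           duration = .data$fb3_dur, weight = 1)

  manifest <- c(
    response = 1, ev_diff_parametric = 2, choice_mean = 3,
    broader_chosen_pe_parametric = 4, broader_chosen_pe_mean = 5,
    broader_unchosen_pe_parametric = 6, broader_unchosen_pe_mean = 7,
    narrower_chosen_pe_parametric = 8, narrower_chosen_pe_mean = 9,
    narrower_unchosen_pe_parametric = 10, narrower_unchosen_pe_mean = 11,
    feedback3_mean = 12
  )
  finalize_regressors(bind_rows(choice, pe, pe_mean, fb3), manifest,
                      demean = demean)
}

# Internal: join trajectory rows (one per trial x deck) to schedule timing
# and choice information, and compute each deck's reveal onset/duration from
# the trial's reveal order.
event_frame <- function(dataset, trajectory) {
  if (is.null(dataset$schedule)) {
    abort("Dataset has no schedule; event timings are unavailable.")
  }
  timing <- dataset$schedule$trials %>%
    select("block_index", "trial_index", "choice_onset", "rt",
           "fb1_onset", "fb1_dur", "fb2_onset", "fb2_dur",
           "fb3_onset", "fb3_dur", "chosen_first")
  ev <- trajectory %>%
    left_join(dataset$trials %>%
                select("block_index", "block_type", "is_equal_mean",
                       "trial_index", "choice"),
              by = c("block_index", "trial_index")) %>%
    left_join(timing, by = c("block_index", "trial_index"))
  if (any(is.na(ev$choice_onset))) {
    abort("Trajectory rows do not align with the dataset's schedule.")
  }
  ev %>%
    mutate(
      revealed_first = (.data$chosen & .data$chosen_first) |
        (!.data$chosen & !.data$chosen_first),
      reveal_onset = ifelse(.data$revealed_first, .data$fb1_onset,
                            .data$fb2_onset),
      reveal_dur = ifelse(.data$revealed_first, .data$fb1_dur, .data$fb2_dur)
    )
}

# Internal: demean parametric weights, order events, attach manifest.
finalize_regressors <- function(events, manifest, demean) {
  events <- events %>%
    select("regressor", "block_index", "trial_index", "onset", "duration",
           "weight")
  if (demean) {
    events <- events %>%
      group_by(.data$regressor) %>%
      mutate(weight = if (grepl("parametric$", .data$regressor[1])) {
        .data$weight - mean(.data$weight)
      } else .data$weight) %>%
      ungroup()
  }
  events <- events %>%
    mutate(regressor = factor(.data$regressor, levels = names(manifest))) %>%
    arrange(.data$regressor, .data$onset) %>%
    mutate(regressor = as.character(.data$regressor))
  structure(events, class = c("regressor_table", class(events)),
            manifest = manifest)
}

#' Write a regressor table as FSL 3-column event files
#'
#' Writes one whitespace-delimited text file per regressor with columns
#' onset, duration, weight, fixed-point formatted to 6 decimals, plus a JSON
#' manifest mapping each regressor name to its file and design beta index.
#'
#' @param table A `regressor_table`.
#' @param dir Output directory (created if absent).
#' @param prefix Optional filename prefix (e.g. subject/block id).
#' @return Invisibly, a named character vector of the written EV file paths.
#' @export
write_fsl_ev <- function(table, dir, prefix = "") {
  stopifnot(inherits(table, "regressor_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- attr(table, "manifest")
  paths <- character(0)
  for (name in names(manifest)) {
    rows <- table[table$regressor == name, , drop = FALSE]
    fname <- paste0(prefix, name, ".txt")
    path <- file.path(dir, fname)
    lines <- sprintf("%.6f %.6f %.6f", rows$onset, rows$duration, rows$weight)
    writeLines(lines, path)
    paths[name] <- path
  }
  jsonlite::write_json(
    list(regressors = lapply(names(manifest), function(name) {
      list(name = name, beta_index = unname(manifest[[name]]),
           file = paste0(prefix, name, ".txt"),
           n_events = sum(table$regressor == name))
    })),
    file.path(dir, paste0(prefix, "manifest.json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Read back an FSL 3-column event file
#'
#' @param path Path to a 3-column EV text file.
#' @return Tibble with columns `onset`, `duration`, `weight`.
#' @export
read_fsl_ev <- function(path) {
  if (length(readLines(path, n = 1)) == 0) {
    return(tibble(onset = numeric(0), duration = numeric(0),
                  weight = numeric(0)))
  }
  m <- utils::read.table(path, col.names = c("onset", "duration", "weight"))
  as_tibble(m)
}
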