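#' Default deck distribution parameters
#'
#' Card decks hide integer values 1 to 13 drawn from a discretized Gaussian.
#' High-mean decks are centered above the midpoint of the support (7), low-mean
#' decks symmetrically below it; broad decks have a larger scale than narrow
#' decks. The defaults place the high/low locations at 9/5 and use scales
#' 1.0 (narrow) and 2.0 (broad), which keeps the realized means of a broad and
#' a narrow deck of the same mean class within 0.1 of each other after
#' truncation to the 1--13 support, while the broad variance (about 3.7)
#' clearly exceeds the narrow variance (about 1.0).
#'
#' @param loc_high,loc_low Gaussian locations for high- and low-mean decks.
#' @param scale_narrow,scale_broad Gaussian scales for narrow and broad decks.
#' @return A named list of distribution parameters.
#' @export
#' @examples
#' deck_params()
deck_params <- function(loc_high = 9, loc_low = 5,
                        scale_narrow = 1.0, scale_broad = 2.0) {
  stopifnot(scale_narrow > 0, scale_broad > 0)
  if (scale_broad <= scale_narrow) {
    abort("`scale_broad` must exceed `scale_narrow`.")
  }
  list(loc_high = loc_high, loc_low = loc_low,
       scale_narrow = scale_narrow, scale_broad = scale_broad)
}

#' Construct a card deck specification
#'
#' A deck is an outcome distribution over the integer card values 1 to 13,
#' labelled by its mean class (high/low) and variance class (narrow/broad).
#' The pmf is a Gaussian evaluated at the integers and renormalized.
#'
#' @param mean_level `"high"` or `"low"`.
#' @param variance_level `"narrow"` or `"broad"`.
#' @param dist_params Output of [deck_params()].
#' @param deck_id Optional label; defaults to `"<variance>_<mean>"`.
#' @return An object of class `deck_spec` with fields `deck_id`, `mean_level`,
#'   `variance_level`, `pmf` (length-13 probability vector).
#' @export
#' @examples
#' d <- make_deck("high", "narrow")
#' deck_mean(d)
make_deck <- function(mean_level = c("high", "low"),
                      variance_level = c("narrow", "broad"),
                      dist_params = deck_params(),
                      deck_id = NULL) {
  mean_level <- match.arg(mean_level)
  variance_level <- match.arg(variance_level)
  loc <- if (mean_level == "high") dist_params$loc_high else dist_params$loc_low
  sc <- if (variance_level == "narrow") dist_params$scale_narrow else dist_params$scale_broad
  if (!is.finite(loc) || !is.finite(sc) || sc < 0) {
    abort("Deck location must be finite and scale non-negative.")
  }
  point_mass <- as.numeric(CARD_VALUES == max(min(round(loc), 13L), 1L))
  if (sc == 0) {
    pmf <- point_mass
  } else {
    w <- dnorm(CARD_VALUES, mean = loc, sd = sc)
    # tiny scales underflow dnorm at every integer: degenerate limit
    pmf <- if (sum(w) == 0 || !all(is.finite(w))) point_mass else w / sum(w)
  }
  structure(
    list(
      deck_id = deck_id %||% paste(variance_level, mean_level, sep = "_"),
      mean_level = mean_level,
      variance_level = variance_level,
      pmf = pmf
    ),
    class = "deck_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deck pmf moments
#'
#' @param deck A `deck_spec`.
#' @return Mean or variance of the deck's pmf over card values 1..13.
#' @export
deck_mean <- function(deck) sum(CARD_VALUES * deck$pmf)

#' @rdname deck_mean
#' @export
deck_var <- function(deck) sum(CARD_VALUES^2 * deck$pmf) - deck_mean(deck)^2

#' @export
print.deck_spec <- function(x, ...) {
  cat(sprintf("<deck_spec> %s (%s mean, %s variance): mean %.2f, var %.2f\n",
              x$deck_id, x$mean_level, x$variance_level,
              deck_mean(x), deck_var(x)))
  invisible(x)
}

#' Construct a block specification
#'
#' A block pairs two decks for `n_trials` choices. The five block types code
#' each deck's variance (B road / N arrow) and mean (H igh / L ow) class:
#' BHNL, NHBL and BHBL are different-mean blocks, BHNH and BLNL equal-mean.
#'
#' @param block_type One of `"BHNL"`, `"NHBL"`, `"BHBL"`, `"BHNH"`, `"BLNL"`.
#' @param n_trials Trials per block (default 30).
#' @param dist_params Output of [deck_params()].
#' @return An object of class `block_spec` with the two `deck_spec`s,
#'   `is_equal_mean` flag, and `n_trials`.
#' @export
make_block <- function(block_type, n_trials = 30, dist_params = deck_params()) {
  block_type <- match.arg(block_type, BLOCK_TYPES)
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  roles <- BLOCK_DECKS[[block_type]]
  decks <- lapply(roles, function(r) {
    parts <- strsplit(r, "_")[[1]]
    make_deck(mean_level = parts[2], variance_level = parts[1],
              dist_params = dist_params, deck_id = r)
  })
  structure(
    list(
      block_type = block_type,
      deck_1 = decks[[1]],
      deck_2 = decks[[2]],
      n_trials = as.integer(n_trials),
      is_equal_mean = block_type %in% EQUAL_MEAN_TYPES
    ),
    class = "block_spec"
  )
}

# Sample an 8-block order satisfying the session constraints:
#  - composition {1 NHBL, 1 BHNL, 2 BHBL, 2 BHNH, 2 BLNL}
#  - the first block's class follows `start_equal`
#  - exactly 2 equal-mean and 2 different-mean blocks in each half
#  - transitions out of each class are balanced (counts of same-class vs
#    cross-class successors differ by at most 1), by rejection sampling
sample_block_order <- function(start_equal, max_tries = 10000L) {
  types <- c("NHBL", "BHNL", "BHBL", "BHBL", "BHNH", "BHNH", "BLNL", "BLNL")
  for (i in seq_len(max_tries)) {
    perm <- sample(types)
    eq <- perm %in% EQUAL_MEAN_TYPES
    if (eq[1] != start_equal) next
    if (sum(eq[1:4]) != 2L) next
    from_eq <- eq[1:7][eq[1:7]]
    to_after_eq <- eq[2:8][eq[1:7]]
    to_after_df <- eq[2:8][!eq[1:7]]
    if (abs(sum(to_after_eq) - sum(!to_after_eq)) > 1L) next
    if (abs(sum(to_after_df) - sum(!to_after_df)) > 1L) next
    return(perm)
  }
  abort("Could not find a block order satisfying the constraints.")
}

#' Build a full task schedule
#'
#' Generates the 8-block session: block order under the counterbalancing
#' constraints, per-trial feedback timing with uniform jitter, reveal order
#' (chosen deck's card first on half the trials of each block), and left/right
#' deck placement. Onsets are in seconds from block start. Because choices are
#' self-paced, the schedule pre-draws a response time per trial (log-normal,
#' median about 0.8 s) so that absolute event onsets are fully determined.
#'
#' @param seed Integer seed; identical seed and settings give an identical
#'   schedule.
#' @param n_trials Trials per block (default 30).
#' @param start_equal Logical; does the session open with an equal-mean block?
#'   Alternate this flag across a cohort so that half start with each class.
#' @param dist_params Output of [deck_params()].
#' @param jitter_range Two numbers; bounds (seconds) of the uniform jitter used
#'   for the delay between choice and first reveal and for each card's display
#'   duration (default `c(1, 3)`, mean 2 s).
#' @param iti Inter-trial interval in seconds after the joint (3rd) feedback.
#' @return An object of class `task_schedule`: a list with `blocks` (list of
#'   `block_spec`), `block_table` (one row per block), and `trials` (tibble
#'   with one row per trial: timings, reveal order, side assignment).
#' @export
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$block_table$block_type)
build_schedule <- function(seed, n_trials = 30, start_equal = TRUE,
                           dist_params = deck_params(),
                           jitter_range = c(1, 3), iti = 1) {
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  if (length(jitter_range) != 2 || diff(jitter_range) < 0 || jitter_range[1] < 0) {
    abort("`jitter_range` must be an increasing pair of non-negative numbers.")
  }
  set.seed(as.integer(seed))
  order <- sample_block_order(isTRUE(start_equal))
  blocks <- lapply(order, make_block, n_trials = n_trials,
                   dist_params = dist_params)

  trials <- purrr::map_dfr(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    nt <- bl$n_trials
    rt <- rlnorm(nt, meanlog = log(0.8), sdlog = 0.35)
    delay <- runif(nt, jitter_range[1], jitter_range[2])
    fb1_dur <- runif(nt, jitter_range[1], jitter_range[2])
    fb2_dur <- runif(nt, jitter_range[1], jitter_range[2])
    # chosen-first on half the trials (+1 extra if nt is odd, at random)
    n_first <- floor(nt / 2) + (nt %% 2 == 1 && runif(1) < 0.5)
    chosen_first <- sample(rep(c(TRUE, FALSE), c(n_first, nt - n_first)))
    deck1_side <- sample(c("left", "right"), nt, replace = TRUE)

    # sequential event chain within the block
    choice_onset <- numeric(nt)
    fb1_onset <- fb2_onset <- fb3_onset <- numeric(nt)
    t0 <- 0
    for (i in seq_len(nt)) {
      choice_onset[i] <- t0
      fb1_onset[i] <- choice_onset[i] + rt[i] + delay[i]
      fb2_onset[i] <- fb1_onset[i] + fb1_dur[i] + 0.5
      fb3_onset[i] <- fb2_onset[i] + fb2_dur[i]
      t0 <- fb3_onset[i] + 1 + iti
    }
    tibble(
      block_index = b,
      block_type = bl$block_type,
      is_equal_mean = bl$is_equal_mean,
      trial_index = seq_len(nt),
      choice_onset = choice_onset,
      rt = rt,
      fb1_onset = fb1_onset, fb1_dur = fb1_dur,
      fb2_onset = fb2_onset, fb2_dur = fb2_dur,
      fb3_onset = fb3_onset, fb3_dur = 1,
      chosen_first = chosen_first,
      deck1_side = deck1_side
    )
  })

  block_table <- tibble(
    block_index = seq_along(blocks),
    block_type = order,
    is_equal_mean = order %in% EQUAL_MEAN_TYPES,
    deck_1 = vapply(blocks, function(b) b$deck_1$deck_id, character(1)),
    deck_2 = vapply(blocks, function(b) b$deck_2$deck_id, character(1)),
    n_trials = vapply(blocks, function(b) b$n_trials, integer(1))
  )

  structure(
    list(seed = as.integer(seed), start_equal = isTRUE(start_equal),
         jitter_range = jitter_range, blocks = blocks,
         block_table = block_table, trials = trials),
    class = "task_schedule"
  )
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule> %d blocks (%s), %d trials, seed %d\n",
              nrow(x$block_table),
              paste(x$block_table$block_type, collapse = " "),
              nrow(x$trials), x$seed))
  invisible(x)
}

#' Validate a task schedule
#'
#' Asserts the schedule invariants: block composition (1 NHBL, 1 BHNL, 2 BHBL,
#' 2 BHNH, 2 BLNL), exactly two equal-mean blocks in the first half, feedback
#' durations within the jitter bounds, and chosen-first reveal order on half
#' the trials of each block (within one for odd counts).
#'
#' @param schedule A `task_schedule`.
#' @return Invisibly `TRUE`; aborts with a message on the first violated
#'   invariant.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  bt <- schedule$block_table
  comp <- table(factor(bt$block_type, levels = BLOCK_TYPES))
  if (!all(comp == c(BHNL = 1, NHBL = 1, BHBL = 2, BHNH = 2, BLNL = 2)[BLOCK_TYPES])) {
    abort("Block composition must be {1 BHNL, 1 NHBL, 2 BHBL, 2 BHNH, 2 BLNL}.")
  }
  if (sum(bt$is_equal_mean[1:4]) != 2) {
    abort("First half must contain exactly two equal-mean blocks.")
  }
  tr <- schedule$trials
  jr <- schedule$jitter_range
  if (any(tr$fb1_dur < jr[1] | tr$fb1_dur > jr[2]) ||
      any(tr$fb2_dur < jr[1] | tr$fb2_dur > jr[2])) {
    abort("Feedback durations fall outside the jitter bounds.")
  }
  bad <- tr %>%
    group_by(.data$block_index) %>%
    summarise(dev = abs(sum(.data$chosen_first) - n() / 2), .groups = "drop") %>%
    filter(.data$dev > 0.5)
  if (nrow(bad) > 0) {
    abort("Chosen-first reveal order is not balanced within every block.")
  }
  if (any(diff(tr$choice_onset[tr$block_index == tr$block_index[1]]) <= 0)) {
    abort("Choice onsets must increase within a block.")
  }
  invisible(TRUE)
}

#' Draw hidden card values for one block
#'
#' Samples `n_trials` independent card values from each of the block's two
#' deck pmfs, using R's global random-number stream (seed with [set.seed()]
#' for reproducibility).
#'
#' @param block A `block_spec`.
#' @return Tibble with columns `trial_index`, `value_1`, `value_2` (integer
#'   card values 1..13 for deck 1 and deck 2).
#' @export
draw_block_outcomes <- function(block) {
  stopifnot(inherits(block, "block_spec"))
  nt <- block$n_trials
  tibble(
    trial_index = seq_len(nt),
    value_1 = sample(CARD_VALUES, nt, replace = TRUE, prob = block$deck_1$pmf),
    value_2 = sample(CARD_VALUES, nt, replace = TRUE, prob = block$deck_2$pmf)
  )
}

#' Rescale a card value to the unit interval
#'
#' Maps the integer card values 1..13 affinely onto \[0.01, 0.99\], so that
#' 1 maps to 0.01, 7 to 0.50 and 13 to 0.99. Learned expected values live on
#' this scale, with a prior of 0.5.
#'
#' @param v Integer card value(s) in 1..13.
#' @return Rescaled value(s) in \[0.01, 0.99\].
#' @export
#' @examples
#' rescale_value(c(1, 7, 13))
rescale_value <- function(v) {
  if (any(!v %in% CARD_VALUES)) {
    abort("Card values must be integers in 1..13.")
  }
  0.01 + (v - 1) * 0.98 / 12
}

#' Write / read a schedule as a tidy delimited table
#'
#' One row per trial, with block-level columns repeated. `read_schedule_table`
#' returns the tibble only (the full `task_schedule` object is reproducible
#' from its seed).
#'
#' @param schedule A `task_schedule`.
#' @param path File path for the delimited (CSV) table.
#' @return `write_schedule` invisibly returns `path`; `read_schedule_table`
#'   returns a tibble.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  tab <- schedule$trials %>%
    left_join(schedule$block_table %>%
                select("block_index", "deck_1", "deck_2"),
              by = "block_index")
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
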