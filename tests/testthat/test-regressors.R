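traj_for <- function(ds, p = rl_params(0.6, 0.2, 5)) run_model(p, ds)

test_that("sign-split design partitions every trial's PEs exactly", {
  ds <- fixture_subject(seed = 701)
  tab <- glm1_events(ds, traj_for(ds))
  counts <- table(tab$regressor)
  n_trials <- nrow(ds$trials)
  expect_equal(unname(counts["chosen_ppe_parametric"] +
                        counts["chosen_npe_parametric"]), n_trials)
  expect_equal(unname(counts["unchosen_ppe_parametric"] +
                        counts["unchosen_npe_parametric"]), n_trials)
  expect_equal(unname(counts["choice_mean"]), n_trials)
  expect_equal(unname(counts["feedback3_mean"]), n_trials)
  # mean regressors pair their parametric partners event-for-event
  for (r in c("chosen_ppe", "chosen_npe", "unchosen_ppe", "unchosen_npe")) {
    expect_equal(unname(counts[paste0(r, "_parametric")]),
                 unname(counts[paste0(r, "_mean")]))
  }
  # manifest covers the 12 design columns
  expect_length(attr(tab, "manifest"), 12)
  expect_equal(unname(attr(tab, "manifest")["feedback3_mean"]), 12)
})

test_that("negative-PE weights are sign-flipped magnitudes before demeaning", {
  ds <- fixture_subject(seed = 702)
  traj <- traj_for(ds)
  raw <- glm1_events(ds, traj, demean = FALSE)
  npe <- raw[raw$regressor %in% c("chosen_npe_parametric",
                                  "unchosen_npe_parametric"), ]
  expect_true(all(npe$weight >= 0))
  # reconstruction: flipping NPEs back and pooling with PPEs recovers delta
  pe_rows <- raw[grepl("_(p|n)pe_parametric$", raw$regressor), ]
  pe_rows$delta_back <- ifelse(grepl("npe", pe_rows$regressor),
                               -pe_rows$weight, pe_rows$weight)
  pe_rows$role <- sub("_(p|n)pe_parametric$", "", pe_rows$regressor)
  key <- merge(
    pe_rows[, c("block_index", "trial_index", "role", "delta_back")],
    within(as.data.frame(traj), role <- ifelse(chosen, "chosen", "unchosen")),
    by = c("block_index", "trial_index", "role")
  )
  expect_equal(nrow(key), 2 * nrow(ds$trials))
  expect_equal(sort(key$delta_back), sort(key$delta))
})

test_that("a constructed all-positive-surprise block has no NPE events", {
  # outcomes always at the top of the scale: deltas never negative
  ds <- fixture_subject(seed = 703)
  ds$trials$value_1 <- 13L
  ds$trials$value_2 <- 13L
  ds$trials$outcome_1 <- rescale_value(13)
  ds$trials$outcome_2 <- rescale_value(13)
  tab <- glm1_events(ds, traj_for(ds))
  expect_equal(sum(tab$regressor == "chosen_npe_parametric"), 0)
  expect_equal(sum(tab$regressor == "chosen_ppe_parametric"),
               nrow(ds$trials))
})

test_that("demeaned parametric columns sum to zero; means are all ones", {
  ds <- fixture_subject(seed = 704)
  for (tab in list(glm1_events(ds, traj_for(ds)),
                   glm2_events(ds, traj_for(ds)))) {
    par_sums <- tapply(tab$weight, tab$regressor, sum)
    for (r in names(par_sums)) {
      if (grepl("parametric$", r)) {
        expect_lt(abs(par_sums[[r]]), 1e-6)
      }
    }
    means <- tab[grepl("mean$", tab$regressor) | tab$regressor == "response", ]
    expect_true(all(means$weight == 1))
  }
})

test_that("PE events sit at the correct card reveal with its duration", {
  ds <- fixture_subject(seed = 705)
  tab <- glm1_events(ds, traj_for(ds))
  sched <- ds$schedule$trials
  chosen_pe <- tab[grepl("^chosen_(p|n)pe_parametric$", tab$regressor), ]
  m <- merge(chosen_pe, sched, by = c("block_index", "trial_index"))
  # chosen card shown first iff the trial's reveal order says so
  expect_true(all(ifelse(m$chosen_first,
                         m$onset == m$fb1_onset & m$duration == m$fb1_dur,
                         m$onset == m$fb2_onset & m$duration == m$fb2_dur)))
  expect_true(all(m$duration >= 1 & m$duration <= 3))
  # onsets within each regressor are non-decreasing block by block
  by_reg <- split(tab, list(tab$regressor, tab$block_index), drop = TRUE)
  expect_true(all(vapply(by_reg, function(g) !is.unsorted(g$onset),
                         logical(1))))
})

test_that("role-split design covers equal-mean trials with complementary cells", {
  ds <- fixture_subject(seed = 706)
  traj <- traj_for(ds)
  tab <- glm2_events(ds, traj, demean = FALSE)
  n_eq <- sum(ds$trials$is_equal_mean)
  cnt <- table(tab$regressor)
  # each trial contributes one broader event and one narrower event,
  # split by whether that deck was chosen
  expect_equal(unname(cnt["broader_chosen_pe_parametric"] +
                        cnt["broader_unchosen_pe_parametric"]), n_eq)
  expect_equal(unname(cnt["narrower_chosen_pe_parametric"] +
                        cnt["narrower_unchosen_pe_parametric"]), n_eq)
  # complementarity: broader chosen on a trial <=> narrower unchosen on it
  key <- function(r) {
    x <- tab[tab$regressor == r, c("block_index", "trial_index")]
    sort(paste(x$block_index, x$trial_index))
  }
  expect_equal(key("broader_chosen_pe_parametric"),
               key("narrower_unchosen_pe_parametric"))
  expect_equal(key("broader_unchosen_pe_parametric"),
               key("narrower_chosen_pe_parametric"))
  # EV-difference is zero on every block's first trial (0.5 priors)
  ev1 <- tab[tab$regressor == "ev_diff_parametric" & tab$trial_index == 1, ]
  expect_equal(nrow(ev1), 4)
  expect_true(all(ev1$weight == 0))
  # weights stay signed: both positive and negative PEs appear
  pe_w <- tab$weight[grepl("_pe_parametric$", tab$regressor)]
  expect_true(any(pe_w > 0) && any(pe_w < 0))
})

test_that("role-split design rejects datasets without equal-mean trials", {
  ds <- fixture_subject(seed = 707)
  traj <- traj_for(ds)
  keep <- !ds$trials$is_equal_mean
  ds$trials <- ds$trials[keep, ]
  traj_dm <- traj[!traj$block_index %in%
                    unique(ds$trials$block_index[ds$trials$is_equal_mean]), ]
  traj_dm <- traj_dm[traj_dm$block_index %in% ds$trials$block_index, ]
  expect_error(glm2_events(ds, traj_dm), "equal-mean")
})

test_that("written 3-column files round-trip and carry a manifest", {
  ds <- fixture_subject(seed = 708)
  tab <- glm1_events(ds, traj_for(ds))
  dir <- withr::local_tempdir()
  paths <- write_fsl_ev(tab, dir, prefix = "sub01_")
  expect_length(paths, 12)
  for (r in c("chosen_ppe_parametric", "choice_mean")) {
    back <- read_fsl_ev(paths[[r]])
    orig <- tab[tab$regressor == r, ]
    expect_lt(max(abs(back$onset - orig$onset)), 1e-6)
    expect_lt(max(abs(back$duration - orig$duration)), 1e-6)
    expect_lt(max(abs(back$weight - orig$weight)), 1e-6)
    expect_equal(nrow(back), nrow(orig))
  }
  man <- jsonlite::read_json(file.path(dir, "sub01_manifest.json"))
  expect_length(man$regressors, 12)
  expect_equal(man$regressors[[1]]$beta_index, 1)
})
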