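test_that("provariance bias is the unweighted mean of per-block fractions", {
  ds <- fixture_subject(seed = 901)
  per <- pvb_per_block(ds)
  expect_equal(nrow(per), 4)
  expect_equal(pvb(ds), mean(per$frac_broader))
  expect_true(all(per$frac_broader >= 0 & per$frac_broader <= 1))
  # all-broader chooser scores exactly 1
  all_broad <- override_choices(ds, function(tr) {
    ifelse(tr$is_equal_mean, fx_broader[tr$block_type], tr$choice)
  })
  expect_equal(pvb(all_broad), 1.0)
})

test_that("hand-set per-block fractions average as stated", {
  # one equal-mean block at each of 0.8, 0.6, 0.4, 0.6 broader-choice rates
  sch <- fixture_schedule()
  ds <- fixture_subject(seed = 902)
  fracs <- c(0.8, 0.6, 0.4, 0.6)
  eq_blocks <- unique(ds$trials$block_index[ds$trials$is_equal_mean])
  ds <- override_choices(ds, function(tr) {
    ch <- tr$choice
    for (j in seq_along(eq_blocks)) {
      rows <- which(tr$block_index == eq_blocks[j])
      bd <- fx_broader[tr$block_type[rows[1]]]
      n_broad <- round(fracs[j] * length(rows))
      pick <- c(rep(bd, n_broad), rep(3L - bd, length(rows) - n_broad))
      ch[rows] <- pick
    }
    ch
  })
  expect_equal(pvb(ds), 0.6)
})

test_that("block accuracies hit the trivial endpoints", {
  ds <- fixture_subject(seed = 903)
  always_higher <- override_choices(ds, function(tr) {
    ifelse(tr$is_equal_mean, tr$choice, fx_higher[tr$block_type])
  })
  acc <- block_accuracy(always_higher)
  dm <- acc[!acc$is_equal_mean, ]
  expect_true(all(dm$fraction == 1))
  expect_equal(sum(acc$n_blocks), 8)
})

test_that("learning is harder when both decks are broad", {
  set.seed(91)
  accs <- purrr::map_dfr(1:40, function(i) {
    sch <- build_schedule(seed = 90000 + i, start_equal = i %% 2 == 1)
    ds <- simulate_subject(rl_params(0.3, 0.3, 8), sch)
    a <- block_accuracy(ds)
    tibble::tibble(bhbl = a$fraction[a$block_type == "BHBL"],
                   nhbl = a$fraction[a$block_type == "NHBL"],
                   bhnl = a$fraction[a$block_type == "BHNL"])
  })
  expect_lt(mean(accs$bhbl), min(mean(accs$nhbl), mean(accs$bhnl)))
})

test_that("exclusion rules fire in order on planted violations", {
  # a cohort of competent learners plus three planted rule-breakers; the
  # control group must be large enough for a planted extreme to exceed 3 SD
  # even though it inflates the group SD itself
  coh <- generate_cohort(n_subjects = 30, seed = 92,
                         alpha_range = c(0.25, 0.45), beta_range = c(6, 10),
                         trait_rho = 0)
  # subject 1: below-chance different-mean accuracy (always lower deck)
  coh[[1]] <- override_choices(coh[[1]], function(tr) {
    ifelse(tr$is_equal_mean, tr$choice, 3L - fx_higher[tr$block_type])
  })
  # subject 2: same deck on every trial of its first equal-mean block
  eq1 <- min(coh[[2]]$trials$block_index[coh[[2]]$trials$is_equal_mean])
  coh[[2]] <- override_choices(coh[[2]], function(tr) {
    ifelse(tr$block_index == eq1, 1L, tr$choice)
  })
  # subject 3: extreme provariance bias, far outside 3 SD, but not a
  # same-option chooser (one narrower pick per block keeps rule 2 quiet)
  coh[[3]] <- override_choices(coh[[3]], function(tr) {
    ch <- ifelse(tr$is_equal_mean, fx_broader[tr$block_type],
                 fx_higher[tr$block_type])
    flip <- tr$is_equal_mean & tr$trial_index == 15
    ifelse(flip, 3L - ch, ch)
  })
  rep <- apply_exclusions(coh)
  expect_true(rep$rule_low_accuracy[1])
  expect_false(rep$kept[1])
  expect_true(rep$rule_same_option[2])
  expect_false(rep$kept[2])
  expect_true(rep$rule_pvb_outlier[3])
  expect_false(rep$kept[3])
  expect_true(all(rep$kept[4:30]))
  # a subject is kept iff no rule triggered
  expect_equal(rep$kept, !(rep$rule_low_accuracy | rep$rule_same_option |
                             rep$rule_pvb_outlier))
  # idempotence: re-running on the kept set triggers no rule-1/2 exclusions
  kept <- structure(coh[rep$kept], class = "cohort")
  rep2 <- apply_exclusions(kept)
  expect_false(any(rep2$rule_low_accuracy))
  expect_false(any(rep2$rule_same_option))
})

test_that("rule 1 threshold sits at 60 percent mean accuracy", {
  coh <- generate_cohort(n_subjects = 4, seed = 93,
                         alpha_range = c(0.3, 0.4), beta_range = c(8, 10))
  # plant exactly 55% accuracy in every different-mean block
  coh[[1]] <- override_choices(coh[[1]], function(tr) {
    ch <- tr$choice
    for (b in unique(tr$block_index[!tr$is_equal_mean])) {
      rows <- which(tr$block_index == b)
      hi <- fx_higher[tr$block_type[rows[1]]]
      n_hi <- round(0.55 * length(rows))
      ch[rows] <- c(rep(hi, n_hi), rep(3L - hi, length(rows) - n_hi))
    }
    ch
  })
  rep <- apply_exclusions(coh)
  expect_true(rep$rule_low_accuracy[1])
})

test_that("trait composite is the sum of sample z-scores", {
  stai <- c(30, 40, 50, 60, 70)
  sds <- c(35, 45, 40, 55, 65)
  comp <- composite_trait(stai, sds)
  expect_equal(mean(comp), 0)
  expect_equal(comp, as.numeric(scale(stai)) + as.numeric(scale(sds)))
  # a subject at both sample means scores 0
  expect_equal(composite_trait(c(40, 50, 60), c(10, 20, 30))[2], 0)
  expect_error(composite_trait(rep(50, 3), c(10, 20, 30)), "variance")
  expect_error(composite_trait(1:3, 1:4), "length")
})

test_that("statistics table matches textbook formulas on a hand case", {
  x <- c(0.6, 0.7, 0.8, 0.55, 0.65)
  summ <- tibble::tibble(
    subject_id = paste0("s", 1:5),
    acc_bhnl = x, acc_nhbl = x, acc_bhbl = x, acc_diff_mean = x,
    frac_broader_bhnh = x, frac_broader_blnl = rev(x),
    pvb = x,
    stai = c(30, 42, 55, 61, 48), sds = c(40, 39, 52, 66, 45)
  )
  tab <- correlate_and_test(summ)
  t_manual <- (mean(x) - 0.5) / (sd(x) / sqrt(5))
  row <- tab[tab$analysis == "pvb_vs_chance", ]
  expect_equal(row$statistic, t_manual)
  expect_equal(row$df, 4)
  # perfectly linear pair gives r = 1
  summ2 <- summ
  summ2$stai <- 1:5 * 10L
  summ2$sds <- 1:5 * 7L
  tab2 <- correlate_and_test(dplyr::mutate(summ2, pvb = 0.4 + 0.05 * (1:5)))
  expect_equal(tab2$statistic[tab2$analysis == "r_pvb_stai"], 1.0)
  expect_equal(tab2$df[tab2$analysis == "r_pvb_stai"], 3)
  # constant vector: undefined one-sample t reported as error
  expect_error(correlate_and_test(dplyr::mutate(summ, pvb = 0.7)), "variance")
  expect_error(correlate_and_test(summ[1:2, ]))
})

test_that("trait coupling sign propagates to the PVB correlation", {
  coh <- generate_cohort(n_subjects = 200, seed = 94, trait_rho = 0.5)
  summ <- cohort_summary(coh)
  r <- cor(summ$pvb, composite_trait(summ$stai, summ$sds))
  # higher trait -> higher negative bias -> lower PVB
  expect_lt(r, 0)
})
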