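#' Which deck is broader / higher in a block?
#'
#' Deck roles follow the block-type code: the broader deck is the one whose
#' variance class is broad (defined only when the two decks differ in
#' variance class, which holds in every block type except BHBL), and the
#' higher deck is the one whose mean class is high (defined only in
#' different-mean blocks).
#'
#' @param block_type Block type code.
#' @return Deck index (1 or 2), or `NA` when undefined.
#' @keywords internal
broader_deck <- function(block_type) {
  roles <- BLOCK_DECKS[[block_type]]
  broad <- grepl("^broad", roles)
  if (sum(broad) != 1) return(NA_integer_)
  which(broad)
}

higher_deck <- function(block_type) {
  roles <- BLOCK_DECKS[[block_type]]
  high <- grepl("high$", roles)
  if (sum(high) != 1) return(NA_integer_)
  which(high)
}

#' Provariance bias of one subject
#'
#' The fraction of broader-option choices is computed per equal-mean block
#' (two broad-high vs narrow-high and two broad-low vs narrow-low blocks) and
#' averaged, unweighted, over the four blocks. A value above 0.5 indicates a
#' preference for the higher-variance deck when means are equal.
#'
#' @param dataset A `subject_dataset`.
#' @return A single fraction in \[0, 1\].
#' @export
pvb <- function(dataset) {
  per_block <- pvb_per_block(dataset)
  mean(per_block$frac_broader)
}

#' @rdname pvb
#' @return `pvb_per_block` returns a tibble with one row per equal-mean
#'   block: `block_index`, `block_type`, `frac_broader`.
#' @export
pvb_per_block <- function(dataset) {
  tr <- dataset$trials %>% filter(.data$is_equal_mean)
  if (length(unique(tr$block_index)) != 4) {
    abort("Dataset must contain four equal-mean blocks.")
  }
  tr %>%
    group_by(.data$block_index, .data$block_type) %>%
    summarise(
      frac_broader = mean(.data$choice ==
                            broader_deck(.data$block_type[1])),
      .groups = "drop"
    )
}

#' Block-type accuracies of one subject
#'
#' For different-mean blocks, the fraction of trials on which the higher-mean
#' deck was chosen, per block and averaged per block type (BHBL is the mean of
#' its two blocks). For equal-mean block types the same summary is reported as
#' the fraction of broader-option choices.
#'
#' @param dataset A `subject_dataset`.
#' @return Tibble with one row per block type present: `block_type`,
#'   `is_equal_mean`, `fraction` (higher-mean choices, or broader choices for
#'   equal-mean types), `n_blocks`.
#' @export
block_accuracy <- function(dataset) {
  dataset$trials %>%
    group_by(.data$block_index, .data$block_type, .data$is_equal_mean) %>%
    summarise(
      fraction = if (.data$is_equal_mean[1]) {
        mean(.data$choice == broader_deck(.data$block_type[1]))
      } else {
        mean(.data$choice == higher_deck(.data$block_type[1]))
      },
      .groups = "drop"
    ) %>%
    group_by(.data$block_type, .data$is_equal_mean) %>%
    summarise(fraction = mean(.data$fraction), n_blocks = n(),
              .groups = "drop")
}

#' Per-subject behavioral summary of a cohort
#'
#' @param cohort A `cohort`.
#' @return Tibble with one row per subject: accuracy per different-mean block
#'   type, mean different-mean accuracy, fraction broader per equal-mean type,
#'   provariance bias, and raw trait scores.
#' @export
cohort_summary <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    acc <- block_accuracy(s)
    get_frac <- function(bt) {
      v <- acc$fraction[acc$block_type == bt]
      if (length(v) == 0) NA_real_ else v
    }
    dm <- s$trials %>%
      filter(!.data$is_equal_mean) %>%
      group_by(.data$block_index, .data$block_type) %>%
      summarise(acc = mean(.data$choice == higher_deck(.data$block_type[1])),
                .groups = "drop")
    tibble(
      subject_id = s$subject_id,
      acc_bhnl = get_frac("BHNL"),
      acc_nhbl = get_frac("NHBL"),
      acc_bhbl = get_frac("BHBL"),
      acc_diff_mean = mean(dm$acc),
      frac_broader_bhnh = get_frac("BHNH"),
      frac_broader_blnl = get_frac("BLNL"),
      pvb = pvb(s),
      stai = s$traits$stai %||% NA_integer_,
      sds = s$traits$sds %||% NA_integer_
    )
  })
}

#' Apply the subject exclusion rules
#'
#' Three rules, applied in order:
#' 1. mean accuracy across the four different-mean blocks below 60%;
#' 2. the same deck chosen on every trial of at least one equal-mean block;
#' 3. after removing rule-1/rule-2 subjects, a provariance bias more than
#'    3 SD from the remaining group's mean.
#'
#' @param cohort A `cohort`.
#' @param accuracy_cutoff Rule-1 threshold (default 0.60).
#' @param sd_cutoff Rule-3 threshold in SD units (default 3).
#' @param per_block_rule1 If `TRUE`, rule 1 triggers when any single
#'   different-mean block falls below the cutoff instead of the mean.
#' @return Tibble with one row per subject: `subject_id`, `kept`, and logical
#'   columns `rule_low_accuracy`, `rule_same_option`, `rule_pvb_outlier`.
#' @export
apply_exclusions <- function(cohort, accuracy_cutoff = 0.60, sd_cutoff = 3,
                             per_block_rule1 = FALSE) {
  summ <- cohort_summary(cohort)
  rule1 <- if (per_block_rule1) {
    purrr::map_lgl(cohort, function(s) {
      dm <- s$trials %>%
        filter(!.data$is_equal_mean) %>%
        group_by(.data$block_index) %>%
        summarise(acc = mean(.data$choice ==
                               higher_deck(.data$block_type[1])),
                  .groups = "drop")
      any(dm$acc < accuracy_cutoff)
    })
  } else {
    summ$acc_diff_mean < accuracy_cutoff
  }
  rule2 <- purrr::map_lgl(cohort, function(s) {
    eq <- s$trials %>%
      filter(.data$is_equal_mean) %>%
      group_by(.data$block_index) %>%
      summarise(one_option = length(unique(.data$choice)) == 1,
                .groups = "drop")
    any(eq$one_option)
  })
  keep12 <- !(rule1 | rule2)
  if (sum(keep12) < 2) {
    abort("Fewer than two subjects survive rules 1-2; cannot apply rule 3.")
  }
  pvb_kept <- summ$pvb[keep12]
  mu <- mean(pvb_kept)
  sdv <- sd(pvb_kept)
  rule3 <- keep12 & abs(summ$pvb - mu) > sd_cutoff * sdv
  tibble(
    subject_id = summ$subject_id,
    kept = keep12 & !rule3,
    rule_low_accuracy = rule1,
    rule_same_option = rule2,
    rule_pvb_outlier = rule3
  )
}

#' Anxiety-depression trait composite
#'
#' Z-standardizes the STAI and SDS raw scores over the analyzed sample and
#' sums them elementwise. The composite has sample mean 0 by construction.
#'
#' @param stai,sds Numeric vectors of raw questionnaire scores, same length.
#' @return Numeric vector of composite z-sums.
#' @export
composite_trait <- function(stai, sds) {
  if (length(stai) != length(sds)) {
    abort("`stai` and `sds` must have the same length.")
  }
  if (sd(stai) == 0 || sd(sds) == 0) {
    abort("Cannot z-score a scale with zero variance.")
  }
  as.numeric(scale(stai)) + as.numeric(scale(sds))
}

#' Behavioral statistics table
#'
#' Runs the cohort-level tests on a post-exclusion summary table: two-tailed
#' one-sample t tests of each block-type fraction against chance (0.5),
#' paired t tests between block-type accuracies, and Pearson correlations
#' among provariance bias, negative learning-rate bias, the trait composite
#' and the raw scales.
#'
#' @param summary A [cohort_summary()] tibble (post-exclusion rows only).
#' @param fits Optional tidy 2lr fit table (adds `lr_neg_bias` correlations).
#' @return Tibble with columns `analysis`, `type`, `statistic`, `df`,
#'   `p_value`, `estimate` (mean fraction, mean difference, or r).
#' @export
correlate_and_test <- function(summary, fits = NULL) {
  if (nrow(summary) < 3) abort("Need at least 3 subjects.")
  if (!is.null(fits)) {
    fits2 <- fits %>% filter(.data$model == "2lr")
    summary <- summary %>%
      left_join(fits2 %>% select("subject_id", "lr_neg_bias"),
                by = "subject_id")
  }
  summary$trait_composite <- composite_trait(summary$stai, summary$sds)

  one_sample <- function(x, name) {
    if (sd(x) == 0) {
      abort(sprintf("Zero variance in '%s'; one-sample t test undefined.",
                    name))
    }
    tt <- t.test(x, mu = 0.5)
    tibble(analysis = paste0(name, "_vs_chance"), type = "one_sample_t",
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, estimate = mean(x))
  }
  paired <- function(x, y, name) {
    tt <- t.test(x, y, paired = TRUE)
    tibble(analysis = name, type = "paired_t",
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, estimate = mean(x - y))
  }
  pearson <- function(x, y, name) {
    ct <- cor.test(x, y)
    tibble(analysis = name, type = "pearson_r",
           statistic = unname(ct$estimate), df = unname(ct$parameter),
           p_value = ct$p.value, estimate = unname(ct$estimate))
  }

  rows <- bind_rows(
    one_sample(summary$acc_bhnl, "acc_bhnl"),
    one_sample(summary$acc_nhbl, "acc_nhbl"),
    one_sample(summary$acc_bhbl, "acc_bhbl"),
    one_sample(summary$frac_broader_bhnh, "frac_broader_bhnh"),
    one_sample(summary$frac_broader_blnl, "frac_broader_blnl"),
    one_sample(summary$pvb, "pvb"),
    paired(summary$acc_bhbl, summary$acc_nhbl, "acc_bhbl_vs_nhbl"),
    paired(summary$acc_bhbl, summary$acc_bhnl, "acc_bhbl_vs_bhnl"),
    paired(summary$frac_broader_bhnh, summary$frac_broader_blnl,
           "frac_broader_bhnh_vs_blnl"),
    pearson(summary$pvb, summary$trait_composite, "r_pvb_trait"),
    pearson(summary$pvb, summary$stai, "r_pvb_stai"),
    pearson(summary$pvb, summary$sds, "r_pvb_sds")
  )
  if (!is.null(fits)) {
    rows <- bind_rows(
      rows,
      pearson(summary$pvb, summary$lr_neg_bias, "r_pvb_lr_neg_bias"),
      pearson(summary$lr_neg_bias, summary$trait_composite,
              "r_lr_neg_bias_trait")
    )
  }
  rows
}
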