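#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * loglik`, where `n` is the number of choices entering
#' the likelihood and `k` the number of free parameters. Lower is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return The BIC value.
#' @export
#' @examples
#' bic(-80, 3, 120)
bic <- function(loglik, k, n) {
  if (n < 1) abort("`n` must be at least 1.")
  if (k < 0) abort("`k` must be non-negative.")
  k * log(n) - 2 * loglik
}

#' BIC of the random-choice baseline
#'
#' The random model assigns probability 0.5 to every choice and has no free
#' parameters, so its BIC is `-2 * n * log(0.5)`.
#'
#' @param n Number of choices.
#' @return The BIC value.
#' @export
#' @examples
#' random_model_bic(120)
random_model_bic <- function(n) {
  if (n < 1) abort("`n` must be at least 1.")
  -2 * n * log(0.5)
}

# default optimizer box constraints; alpha bounded away from 0 and beta away
# from both 0 and +Inf to avoid flat/degenerate regions of the likelihood
FIT_BOUNDS <- list(alpha = c(0.001, 1), beta = c(0.01, 30))

#' Fit a learning model to one subject by maximum likelihood
#'
#' Bounded multi-start maximum-likelihood estimation over the four equal-mean
#' blocks' choices. Initial points are a seeded Latin-hypercube over the
#' parameter box (alpha in \[0.001, 1\], beta in \[0.01, 30\]); each start is
#' refined with L-BFGS-B and the best converged solution is retained. The
#' random model has a closed-form likelihood and no parameters.
#'
#' @param dataset A `subject_dataset` containing the equal-mean blocks.
#' @param model `"2lr"`, `"1lr"` or `"random"`.
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Integer seed controlling the start points.
#' @param prob_floor Floor on choice probabilities inside the log.
#' @return An object of class `model_fit`: list with `subject_id`, `model`,
#'   `k`, `n`, `params` (an `rl_params`, or `NULL` for random), `loglik`,
#'   `bic`, `lr_neg_bias` (2lr only), `n_converged` (starts that converged),
#'   and `converged` (did any start converge).
#' @export
fit_subject <- function(dataset, model = c("2lr", "1lr", "random"),
                        n_starts = 10, seed = 1, prob_floor = 1e-12) {
  model <- match.arg(model)
  spec <- model_spec(model)
  arrays <- dataset_arrays(dataset, equal_mean_only = TRUE)
  n <- sum(vapply(arrays, function(a) length(a$choice), integer(1)))

  if (model == "random") {
    ll <- n * log(0.5)
    return(structure(
      list(subject_id = dataset$subject_id, model = model, k = 0L, n = n,
           params = NULL, loglik = ll, bic = bic(ll, 0, n),
           lr_neg_bias = NA_real_, n_converged = NA_integer_,
           converged = TRUE),
      class = "model_fit"
    ))
  }

  k <- spec$k
  lower <- c(FIT_BOUNDS$alpha[1], FIT_BOUNDS$beta[1])
  upper <- c(FIT_BOUNDS$alpha[2], FIT_BOUNDS$beta[2])
  if (model == "2lr") {
    lower <- c(FIT_BOUNDS$alpha[1], lower)
    upper <- c(FIT_BOUNDS$alpha[2], upper)
  }
  obj <- if (model == "2lr") {
    function(par) negll_arrays(par, arrays, prob_floor)
  } else {
    function(par) negll_arrays(c(par[1], par[1], par[2]), arrays, prob_floor)
  }

  set.seed(as.integer(seed))
  starts <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("All optimizer starts failed for subject '%s' (%s).",
                  dataset$subject_id, model))
  }

  params <- if (model == "2lr") {
    rl_params(best$par[1], best$par[2], best$par[3])
  } else {
    rl_params(best$par[1], best$par[1], best$par[2])
  }
  ll <- -best$value
  structure(
    list(subject_id = dataset$subject_id, model = model, k = k, n = n,
         params = params, loglik = ll, bic = bic(ll, k, n),
         lr_neg_bias = if (model == "2lr") negative_bias(params) else NA_real_,
         n_converged = n_conv, converged = n_conv > 0L),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s / %s: loglik %.2f, BIC %.2f (n = %d, k = %d)\n",
              x$subject_id, x$model, x$loglik, x$bic, x$n, x$k))
  invisible(x)
}

#' Collect model fits into a tidy table
#'
#' @param fits A list of `model_fit` objects.
#' @return Tibble with one row per fit.
#' @export
fits_table <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    tibble(
      subject_id = f$subject_id,
      model = f$model,
      k = f$k,
      n = f$n,
      alpha_pos = if (is.null(f$params)) NA_real_ else f$params$alpha_pos,
      alpha_neg = if (is.null(f$params)) NA_real_ else f$params$alpha_neg,
      beta = if (is.null(f$params)) NA_real_ else f$params$beta,
      loglik = f$loglik,
      bic = f$bic,
      lr_neg_bias = f$lr_neg_bias,
      converged = f$converged
    )
  })
}

#' Fit a model to every subject of a cohort
#'
#' @param cohort A `cohort`.
#' @param model `"2lr"`, `"1lr"` or `"random"`.
#' @param n_starts,seed,prob_floor Passed to [fit_subject()]; per-subject
#'   start seeds are derived deterministically from `seed`.
#' @return Tidy tibble of fits (see [fits_table()]).
#' @export
fit_cohort <- function(cohort, model = "2lr", n_starts = 10, seed = 1,
                       prob_floor = 1e-12) {
  fits <- lapply(seq_along(cohort), function(i) {
    fit_subject(cohort[[i]], model = model, n_starts = n_starts,
                seed = seed + i, prob_floor = prob_floor)
  })
  fits_table(fits)
}

#' Compare fitted models across subjects
#'
#' Sums BIC across subjects per model, computes delta BIC relative to the
#' best (lowest summed BIC) model, and counts per-subject wins. Ties in
#' per-subject selection are broken toward the model with fewer parameters.
#'
#' @param fits Tidy fit table covering every subject x model cell (rows as
#'   produced by [fit_cohort()] / [fits_table()]).
#' @return Tibble with one row per model: `model`, `k`, `sum_bic`,
#'   `delta_bic`, `n_best_subjects`.
#' @export
compare_models <- function(fits) {
  cells <- table(fits$subject_id, fits$model)
  if (any(cells != 1)) {
    abort("`fits` must contain exactly one fit per subject x model cell.")
  }
  per_subject_best <- fits %>%
    group_by(.data$subject_id) %>%
    arrange(.data$bic, .data$k, .by_group = TRUE) %>%
    summarise(best_model = .data$model[1], .groups = "drop")

  fits %>%
    group_by(.data$model) %>%
    summarise(k = .data$k[1], sum_bic = sum(.data$bic), .groups = "drop") %>%
    mutate(
      delta_bic = .data$sum_bic - min(.data$sum_bic),
      n_best_subjects = vapply(
        .data$model,
        function(m) sum(per_subject_best$best_model == m), numeric(1)
      )
    ) %>%
    arrange(.data$sum_bic)
}

#' Parameter-recovery diagnostic
#'
#' Simulates subjects with known parameters drawn uniformly from the given
#' ranges, refits the two-learning-rate model, and reports the correlation
#' and mean bias of recovered vs true values for each parameter and for the
#' negative learning-rate bias.
#'
#' @param n_subjects Number of simulated subjects (default 100).
#' @param seed Master seed.
#' @param alpha_range,beta_range Uniform sampling ranges for the generating
#'   parameters.
#' @param n_trials Trials per block.
#' @param n_starts Optimizer starts per fit.
#' @return List with `subjects` (tibble of true and recovered values) and
#'   `summary` (tibble: parameter, pearson_r, mean_bias).
#' @export
parameter_recovery <- function(n_subjects = 100, seed = 1,
                               alpha_range = c(0.05, 0.95),
                               beta_range = c(1, 10),
                               n_trials = 30, n_starts = 10) {
  cohort <- generate_cohort(n_subjects = n_subjects, seed = seed,
                            alpha_range = alpha_range,
                            beta_range = beta_range,
                            n_trials = n_trials)
  true <- cohort_params(cohort)
  fitted <- fit_cohort(cohort, model = "2lr", n_starts = n_starts,
                       seed = seed + 10000L)
  subjects <- true %>%
    select("subject_id", true_alpha_pos = "alpha_pos",
           true_alpha_neg = "alpha_neg", true_beta = "beta",
           true_lr_neg_bias = "lr_neg_bias") %>%
    left_join(fitted %>%
                select("subject_id", fit_alpha_pos = "alpha_pos",
                       fit_alpha_neg = "alpha_neg", fit_beta = "beta",
                       fit_lr_neg_bias = "lr_neg_bias"),
              by = "subject_id")
  pars <- c("alpha_pos", "alpha_neg", "beta", "lr_neg_bias")
  summary <- purrr::map_dfr(pars, function(p) {
    tv <- subjects[[paste0("true_", p)]]
    fv <- subjects[[paste0("fit_", p)]]
    tibble(parameter = p,
           pearson_r = cor(tv, fv),
           mean_bias = mean(fv - tv))
  })
  list(subjects = subjects, summary = summary)
}

#' Model-recovery diagnostic
#'
#' Simulates datasets from each generator (asymmetric two-rate, single-rate,
#' and random choosers), fits all three candidate models to each dataset, and
#' reports the fraction of datasets whose BIC-selected model matches the
#' generator. Asymmetric generators are resampled until
#' `|alpha_pos - alpha_neg| >= min_asymmetry`.
#'
#' @param n_per_generator Replicates per generating model (default 25).
#' @param seed Master seed.
#' @param alpha_range,beta_range Generating parameter ranges.
#' @param min_asymmetry Minimum learning-rate gap for the `2lr` generator.
#' @param n_trials Trials per block.
#' @param n_starts Optimizer starts per fit.
#' @return List with `confusion` (tibble: generator, selected, fraction) and
#'   `accuracy` (tibble: generator, fraction of correct selections).
#' @export
model_recovery <- function(n_per_generator = 25, seed = 1,
                           alpha_range = c(0.05, 0.95),
                           beta_range = c(1, 10),
                           min_asymmetry = 0.2,
                           n_trials = 30, n_starts = 10) {
  set.seed(as.integer(seed))
  generators <- c("2lr", "1lr", "random")
  draws <- purrr::map_dfr(generators, function(g) {
    purrr::map_dfr(seq_len(n_per_generator), function(r) {
      if (g == "2lr") {
        repeat {
          ap <- runif(1, alpha_range[1], alpha_range[2])
          an <- runif(1, alpha_range[1], alpha_range[2])
          if (abs(ap - an) >= min_asymmetry) break
        }
      } else if (g == "1lr") {
        ap <- an <- runif(1, alpha_range[1], alpha_range[2])
      } else {
        ap <- an <- 0.5  # irrelevant at beta = 0
      }
      b <- if (g == "random") 0 else runif(1, beta_range[1], beta_range[2])
      tibble(generator = g, rep = r, alpha_pos = ap, alpha_neg = an, beta = b,
             sched_seed = sample.int(.Machine$integer.max, 1),
             fit_seed = sample.int(.Machine$integer.max, 1) %% 100000L)
    })
  })

  selected <- purrr::pmap_chr(draws, function(generator, rep, alpha_pos,
                                              alpha_neg, beta, sched_seed,
                                              fit_seed) {
    sched <- build_schedule(seed = sched_seed, n_trials = n_trials,
                            start_equal = rep %% 2 == 1)
    ds <- simulate_subject(rl_params(alpha_pos, alpha_neg, beta), sched)
    f <- purrr::map_dfr(c("2lr", "1lr", "random"), function(m) {
      fits_table(fit_subject(ds, model = m, n_starts = n_starts,
                             seed = fit_seed))
    })
    f <- f[order(f$bic, f$k), ]
    f$model[1]
  })
  draws$selected <- selected

  confusion <- draws %>%
    group_by(.data$generator, .data$selected) %>%
    summarise(count = n(), .groups = "drop") %>%
    mutate(fraction = .data$count / n_per_generator)
  accuracy <- draws %>%
    group_by(.data$generator) %>%
    summarise(fraction_correct = mean(.data$selected == .data$generator),
              .groups = "drop")
  list(confusion = confusion, accuracy = accuracy, draws = draws)
}
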