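#' Parameter set for the Rescorla-Wagner observers
#'
#' The two-learning-rate model (`2lr`) updates expected values with rate
#' `alpha_pos` when the prediction error is non-negative and `alpha_neg` when
#' it is negative; the softmax inverse temperature `beta` controls choice
#' determinism. The one-learning-rate model (`1lr`) is the special case
#' `alpha_pos == alpha_neg`.
#'
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\].
#' @param beta Inverse temperature, non-negative.
#' @return An object of class `rl_params`.
#' @export
#' @examples
#' rl_params(0.6, 0.2, 5)
rl_params <- function(alpha_pos, alpha_neg = alpha_pos, beta) {
  if (!all(is.finite(c(alpha_pos, alpha_neg, beta)))) {
    abort("All parameters must be finite.")
  }
  if (alpha_pos < 0 || alpha_pos > 1 || alpha_neg < 0 || alpha_neg > 1) {
    abort("Learning rates must lie in [0, 1].")
  }
  if (beta < 0) abort("`beta` must be non-negative.")
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta),
            class = "rl_params")
}

#' @export
print.rl_params <- function(x, ...) {
  cat(sprintf("<rl_params> alpha+ = %.3f, alpha- = %.3f, beta = %.3f\n",
              x$alpha_pos, x$alpha_neg, x$beta))
  invisible(x)
}

#' One Rescorla-Wagner value update
#'
#' Computes the prediction error `delta = R - V`, selects the learning rate by
#' the sign of `delta` (the positive rate applies at `delta == 0`), and
#' returns the updated value `V + rate * delta`.
#'
#' @param V Current expected value in \[0, 1\].
#' @param R Rescaled outcome in \[0.01, 0.99\].
#' @param params An `rl_params`.
#' @return List with `delta`, `rate` (the applied learning rate), and
#'   `V_new`.
#' @export
#' @examples
#' value_update_step(0.5, 0.99, rl_params(0.4, 0.2, 5))
value_update_step <- function(V, R, params) {
  if (V < 0 || V > 1) abort("`V` must lie in [0, 1].")
  if (R < 0.01 - 1e-12 || R > 0.99 + 1e-12) {
    abort("`R` must lie in [0.01, 0.99].")
  }
  delta <- R - V
  rate <- if (delta >= 0) params$alpha_pos else params$alpha_neg
  list(delta = delta, rate = rate, V_new = V + rate * delta)
}

#' Negative learning-rate bias
#'
#' The ratio `alpha_neg / (alpha_pos + alpha_neg)`. Values above 0.5 indicate
#' stronger updating from worse-than-expected outcomes; a symmetric learner
#' has bias 0.5.
#'
#' @param params An `rl_params`, or the positive learning rate.
#' @param alpha_neg Negative learning rate (ignored when `params` is an
#'   `rl_params`).
#' @return The bias, in \[0, 1\].
#' @export
#' @examples
#' negative_bias(rl_params(0.6, 0.2, 5))  # 0.25
negative_bias <- function(params, alpha_neg = NULL) {
  if (inherits(params, "rl_params")) {
    ap <- params$alpha_pos
    an <- params$alpha_neg
  } else {
    ap <- params
    an <- alpha_neg
  }
  if (ap + an <= 0) abort("At least one learning rate must be positive.")
  an / (ap + an)
}

#' Softmax choice probability
#'
#' Probability of choosing option a given the two expected values, under the
#' logistic softmax `1 / (1 + exp(-beta * (V_a - V_b)))`. Overflow-safe for
#' large `beta`.
#'
#' @param v_a,v_b Expected values of the two options.
#' @param beta Inverse temperature (0 gives 0.5 regardless of values).
#' @return Probability of choosing option a.
#' @export
#' @examples
#' choice_prob(0.7, 0.5, 3)
choice_prob <- function(v_a, v_b, beta) {
  stats::plogis(beta * (v_a - v_b))
}

#' Model specifications for comparison
#'
#' @param model `"2lr"`, `"1lr"` or `"random"`.
#' @return List with `model` and `k`, the free-parameter count (3, 2, 0).
#' @export
model_spec <- function(model = c("2lr", "1lr", "random")) {
  model <- match.arg(model)
  list(model = model, k = c(`2lr` = 3L, `1lr` = 2L, random = 0L)[[model]])
}

# Internal: extract per-block arrays used by the forward pass and likelihood.
# Returns a list (one element per block kept) of
#   list(choice = integer vector in {1,2}, R = n x 2 matrix of rescaled
#        outcomes, block_index, trial_index)
dataset_arrays <- function(dataset, equal_mean_only = FALSE) {
  tr <- dataset$trials
  if (equal_mean_only) tr <- tr[tr$is_equal_mean, , drop = FALSE]
  if (nrow(tr) == 0) abort("Dataset has no trials for the requested blocks.")
  lapply(split(tr, tr$block_index), function(b) {
    list(block_index = b$block_index[1],
         trial_index = b$trial_index,
         choice = b$choice,
         R = cbind(rescale_value(b$value_1), rescale_value(b$value_2)))
  })
}

# Internal forward pass over one block: both decks updated from their own
# revealed outcomes; values start at 0.5 (new decks each block).
forward_block <- function(choice, R, alpha_pos, alpha_neg, beta) {
  nt <- length(choice)
  V <- c(0.5, 0.5)
  V_pre <- matrix(0, nt, 2)
  delta <- matrix(0, nt, 2)
  rate <- matrix(0, nt, 2)
  p_chosen <- numeric(nt)
  for (i in seq_len(nt)) {
    V_pre[i, ] <- V
    p1 <- stats::plogis(beta * (V[1] - V[2]))
    p_chosen[i] <- if (choice[i] == 1L) p1 else 1 - p1
    d <- R[i, ] - V
    a <- ifelse(d >= 0, alpha_pos, alpha_neg)
    V <- V + a * d
    delta[i, ] <- d
    rate[i, ] <- a
  }
  list(V_pre = V_pre, delta = delta, rate = rate, p_chosen = p_chosen)
}

#' Run a fitted model forward over a dataset
#'
#' Deterministic forward pass of the Rescorla-Wagner observer over all blocks
#' of a subject's data: values reset to 0.5 at each block start (each block
#' brings two new decks), and both decks are updated each trial from their own
#' revealed outcome using the sign-dependent learning rate. Emits the
#' trial-by-trial trajectory used for prediction-error regressors.
#'
#' @param params An `rl_params`.
#' @param dataset A `subject_dataset` (see [simulate_subject()]).
#' @param blocks `"all"` or `"equal_mean"`.
#' @return Tibble with one row per trial and deck: `block_index`,
#'   `trial_index`, `deck` (1 or 2), `chosen` (was this deck chosen),
#'   `V_pre` (value before update), `delta` (prediction error),
#'   `rate_applied`, `p_choice` (softmax probability of the chosen deck,
#'   repeated on both deck rows).
#' @export
run_model <- function(params, dataset, blocks = c("all", "equal_mean")) {
  blocks <- match.arg(blocks)
  arrays <- dataset_arrays(dataset, equal_mean_only = blocks == "equal_mean")
  purrr::map_dfr(arrays, function(a) {
    fw <- forward_block(a$choice, a$R, params$alpha_pos, params$alpha_neg,
                        params$beta)
    nt <- length(a$choice)
    tibble(
      block_index = rep(a$block_index, 2 * nt),
      trial_index = rep(a$trial_index, 2),
      deck = rep(1:2, each = nt),
      chosen = rep(1:2, each = nt) == rep(a$choice, 2),
      V_pre = c(fw$V_pre[, 1], fw$V_pre[, 2]),
      delta = c(fw$delta[, 1], fw$delta[, 2]),
      rate_applied = c(fw$rate[, 1], fw$rate[, 2]),
      p_choice = rep(fw$p_chosen, 2)
    )
  }) %>%
    arrange(.data$block_index, .data$trial_index, .data$deck)
}

#' Log-likelihood of a subject's equal-mean-block choices
#'
#' Sums log softmax probabilities of the observed choices over all trials of
#' the four equal-mean blocks (the blocks used for model fitting; learning in
#' the different-mean blocks is near ceiling and uninformative about the
#' learning asymmetry). The random baseline assigns probability 0.5 to every
#' choice. Choice probabilities are floored at `prob_floor` inside the log to
#' keep the objective finite for degenerate parameters.
#'
#' @param params An `rl_params` (ignored for the random model).
#' @param dataset A `subject_dataset`.
#' @param model `"2lr"`, `"1lr"` or `"random"`. For `"1lr"`, `alpha_pos` is
#'   used as the single rate.
#' @param prob_floor Numerical floor on choice probabilities (default 1e-12).
#' @return The log-likelihood (a non-positive number).
#' @export
log_likelihood <- function(params, dataset, model = c("2lr", "1lr", "random"),
                           prob_floor = 1e-12) {
  model <- match.arg(model)
  arrays <- dataset_arrays(dataset, equal_mean_only = TRUE)
  n <- sum(vapply(arrays, function(a) length(a$choice), integer(1)))
  if (model == "random") return(n * log(0.5))
  an <- if (model == "1lr") params$alpha_pos else params$alpha_neg
  negll_arrays(c(params$alpha_pos, an, params$beta), arrays,
               prob_floor = prob_floor) * -1
}

# Internal objective for the optimizer: negative log-likelihood given raw
# parameter vector c(alpha_pos, alpha_neg, beta) and precomputed arrays.
negll_arrays <- function(par, arrays, prob_floor = 1e-12) {
  ap <- par[1]; an <- par[2]; beta <- par[3]
  nll <- 0
  for (a in arrays) {
    choice <- a$choice
    R <- a$R
    nt <- length(choice)
    V1 <- 0.5; V2 <- 0.5
    for (i in seq_len(nt)) {
      p1 <- stats::plogis(beta * (V1 - V2))
      p <- if (choice[i] == 1L) p1 else 1 - p1
      if (p < prob_floor) p <- prob_floor
      nll <- nll - log(p)
      d1 <- R[i, 1] - V1
      d2 <- R[i, 2] - V2
      V1 <- V1 + (if (d1 >= 0) ap else an) * d1
      V2 <- V2 + (if (d2 >= 0) ap else an) * d2
    }
  }
  nll
}
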