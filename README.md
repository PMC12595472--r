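# pvblearn

Asymmetric reinforcement learning and provariance bias in a two-deck
magnitude learning task.

## The problem

When two options pay out the same on average but one is riskier (higher
outcome variance), many people systematically prefer the riskier one — a
*provariance bias* (PVB). One computational account is asymmetric learning:
if good surprises update expectations more strongly than bad ones, the
learned value of a high-variance option drifts above its true mean, and the
option looks better than an equally-paying safe one. The strength of that
asymmetry varies across people and tracks anxiety and depression traits,
which makes it a quantity of interest in computational psychiatry.

`pvblearn` is an R package for researchers studying this mechanism. It
provides:

- a simulator for the card-deck magnitude learning task: 8 blocks x 30
  trials; each block pairs two decks hiding integer card values 1–13 whose
  distributions differ in mean (high/low) and/or variance (narrow/broad);
  five block types (`BHNL`, `NHBL`, `BHBL` different-mean; `BHNH`, `BLNL`
  equal-mean), counterbalanced ordering, and jittered event timing;
- a synthetic-cohort generator with known learning parameters and
  questionnaire scores (STAI, SDS) coupled to the learning asymmetry;
- the two-learning-rate Rescorla–Wagner observer and baselines, with
  per-subject maximum-likelihood fitting, BIC model comparison, and
  parameter/model recovery diagnostics;
- the behavioral statistics pipeline: block-type accuracies, PVB, subject
  exclusion rules, anxiety–depression trait composites, t tests and Pearson
  correlations;
- export of model-derived prediction-error regressors as FSL 3-column EV
  files for model-based fMRI first-level designs.

## The model

Card values `v` in 1..13 are rescaled to `R = 0.01 + (v-1) * 0.98/12`
(so 1 → 0.01, 7 → 0.5, 13 → 0.99). Each deck's expected value starts at
`V = 0.5` and is updated after its card is revealed:

    delta  = R - V                       (prediction error)
    alpha  = alpha_plus  if delta >= 0
             alpha_minus if delta <  0
    V'     = V + alpha * delta

Choices follow a softmax on the value difference,
`P(a) = 1 / (1 + exp(-beta * (V_a - V_b)))`. The *negative learning-rate
bias* is `alpha_minus / (alpha_plus + alpha_minus)`; values below 0.5 mean
good surprises dominate learning, which produces a provariance bias in
equal-mean blocks. Models are fitted on the four equal-mean blocks (120
choices) and compared by `BIC = k ln(n) - 2 ln L`, against a one-rate
variant (k = 2) and a random baseline (every choice probability 0.5, k = 0).

## Worked example

```r
library(pvblearn)

sched <- build_schedule(seed = 1)        # 8 blocks, counterbalanced
validate_schedule(sched)

set.seed(2)
subj <- simulate_subject(rl_params(alpha_pos = 0.6, alpha_neg = 0.2, beta = 5),
                         sched)
subj
#> <subject_dataset> sim01: 240 trials in 8 blocks, 269 points

pvb(subj)                                # fraction of broader-deck choices
#> 0.508

fit <- fit_subject(subj, model = "2lr", seed = 3)
fit
#> <model_fit> sim01 / 2lr: loglik -77.80, BIC 169.97 (n = 120, k = 3)
fit$params
#> <rl_params> alpha+ = 0.522, alpha- = 0.176, beta = 7.692
fit$lr_neg_bias
#> 0.252
```

The agent was generated with a negative learning-rate bias of
0.2 / (0.6 + 0.2) = 0.25; the fit recovers 0.252 from its 120 equal-mean
choices, and its PVB of 0.508 sits above indifference, as the positive
learning asymmetry predicts. The random baseline's BIC for the same data is
`random_model_bic(120)` = 166.36 — a reminder that 120 noisy choices carry
limited evidence per subject; cohort-level analyses (`fit_cohort()`,
`compare_models()`, `parameter_recovery()`, `model_recovery()`) quantify
this explicitly.

For fMRI designs:

```r
traj <- run_model(fit$params, subj)          # trial-by-trial values and PEs
ev1 <- glm1_events(subj, traj)               # sign-split PE regressors
write_fsl_ev(ev1, "evs/sub01", prefix = "sub01_")
```

## Documentation

The methods vignette (`vignettes/pvblearn-methods.Rmd`) describes the task
design, the model and its assumptions, the fitting choices (bounds,
multi-start initialization, probability floor), what the synthetic cohort
does and does not emulate, and known identifiability limits of the
equal-mean-block design.
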