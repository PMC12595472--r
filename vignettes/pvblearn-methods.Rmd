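---
title: "Methods: task design, learning model, fitting and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task design, learning model, fitting and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvblearn)
```

This vignette documents the scientific and numerical choices behind
`pvblearn`: the task the simulator emulates, the learning model and its
assumptions, how parameters are estimated and compared, what the synthetic
cohort can and cannot stand in for, and the known limits of the design.

## The task

A session is 8 blocks of 30 self-paced choices between two card decks. Each
deck hides integer card values 1–13 drawn from a fixed distribution; decks
are classified by mean (high/low) and variance (narrow/broad). Five block
types pair the classes: three *different-mean* types (`BHNL`, `NHBL`, and
two `BHBL` blocks) where one deck is objectively better, and two
*equal-mean* types (`BHNH` twice, `BLNL` twice) where only the variance
differs. Equal-mean blocks carry all the information about variance
preference: the fraction of broader-deck choices, averaged over the four
equal-mean blocks, is the subject's provariance bias (PVB).

Block order is pseudorandom under three constraints: a configurable flag
sets whether the session opens with an equal-mean block (alternate it across
a cohort so half start each way); each half of the session contains exactly
two equal-mean and two different-mean blocks; and transitions out of each
block class are balanced (an equal-mean block is about as likely to be
followed by either class). The last constraint is implemented by rejection
sampling of permutations, accepting an order when, separately for each
class, its same-class and cross-class successor counts differ by at most
one — the strictest balance eight blocks permit.

After each choice, one deck's card is revealed after a uniform 1–3 s delay,
shown for a uniform 1–3 s, then (0.5 s later) the other deck's card for
another 1–3 s, and finally both cards together for 1 s; the trial's points
are the chosen minus the unchosen card value. The chosen deck's card comes
first on half of each block's trials. Uniform jitter was chosen as the
simplest distribution with the stated 1–3 s range and 2 s mean. Because
choices are self-paced, the schedule pre-draws a response time per trial
(log-normal, median 0.8 s, sdlog 0.35 — typical for a two-alternative value
choice) so that all event onsets are determined at schedule-build time; an
inter-trial interval of 1 s follows the joint feedback.

### Deck distributions

The deck pmfs are Gaussians evaluated at the integers 1–13 and renormalized.
Defaults: locations 9 (high) and 5 (low), symmetric about the support
midpoint 7; scales 1.0 (narrow) and 2.0 (broad). The broad scale is the
largest round value for which truncation at the support edge still leaves a
broad deck's realized mean within 0.1 of its narrow partner (at scale 2.0
the broad-high mean is 8.94 vs 9.00 narrow-high, variances 3.71 vs 1.00).
Larger scales buy almost no extra spread — truncation eats it — while
breaking the mean match that defines the equal-mean conditions. All four
values are configurable through `deck_params()`.

## The learning model

Card values are rescaled to `[0.01, 0.99]` by the affine map
`R = 0.01 + (v - 1) * 0.98 / 12`; expected values start each block at the
scale midpoint 0.5 (each block brings two new decks, so no value carries
over). The two-learning-rate Rescorla–Wagner observer updates a deck's value
after its card is revealed:

- prediction error: `delta = R - V`;
- learning rate: `alpha_plus` when `delta >= 0` (ties go to the positive
  branch by definition), `alpha_minus` when `delta < 0`;
- update: `V' = V + alpha(delta) * delta`.

With rates in `[0, 1]` and outcomes in `[0.01, 0.99]`, values provably stay
in `[0, 1]`. Choices are softmax in the value difference with inverse
temperature `beta >= 0`. The *negative learning-rate bias*
`alpha_minus / (alpha_plus + alpha_minus)` summarizes the asymmetry: below
0.5, better-than-expected outcomes dominate learning, the broad deck's value
drifts upward in equal-mean blocks, and a provariance bias emerges; above
0.5 the drift reverses. This monotone link is exercised directly in the test
suite (grid of bias values at fixed `beta = 5` and total rate 0.8, 100
agents per point).

**Both decks update every trial.** The task reveals both cards, and the
fMRI designs require value estimates and prediction errors for the unchosen
deck, so the simulator and the likelihood update each deck from its own
revealed outcome. The alternative reading — only the chosen deck learns —
was implemented and compared during development; it changes parameter
identifiability only marginally and fits the full-feedback task less
naturally, so the both-update convention is used throughout.

## Fitting and model comparison

Fitting uses the four equal-mean blocks only (120 choices under defaults):
different-mean blocks are dominated by near-ceiling choice of the better
deck and carry little information about the learning asymmetry. Three
models are compared: the two-rate observer (k = 3), the one-rate observer
(k = 2; an exact special case, `alpha_plus = alpha_minus`, which the test
suite verifies to 1e-10), and a random baseline (every choice probability
0.5, k = 0, likelihood known in closed form).

Estimation is bounded multi-start maximum likelihood: 10 Latin-hypercube
start points (seed-controlled) refined with L-BFGS-B inside
`alpha in [0.001, 1]`, `beta in [0.01, 30]`; the best converged solution is
kept and flagged if no start converges. The bounds keep the optimizer away
from the flat `beta -> 0` ridge and the degenerate `alpha -> 0` corner.
Choice probabilities are floored at 1e-12 inside the log (configurable) so
degenerate parameter values yield a finite, steeply penalized objective
rather than `-Inf`. A MAP variant with weakly-informative priors was
evaluated during development; it stabilizes `beta` estimates but not the
bias ratio, so plain ML point estimates are used — they are the only
quantity consumed downstream.

Model comparison follows `BIC = k ln(n) - 2 lnL` with `n` the number of
choices entering the likelihood, summed across subjects; delta BIC is taken
from the best (lowest) model, and per-subject ties break toward the model
with fewer parameters.

## The synthetic cohort

`generate_cohort()` emulates a 49-subject study sample: learning rates
drawn i.i.d. from U(0.05, 0.95), inverse temperatures from U(1, 10), the
equal-mean-first starting condition alternating across subjects, and each
subject playing a fresh schedule. Anxiety–depression traits are coupled to
the negative learning-rate bias: a latent trait factor is
`rho * z(bias) + sqrt(1 - rho^2) * noise` (so its Pearson correlation with
the bias is `rho` by construction, default +0.5: more anxious-depressed
subjects update more from bad outcomes and show less provariance bias), and
STAI/SDS raw scores are independently noised, rounded, clipped integer
mappings of that factor onto the 20–80 questionnaire range. The coupling
sign and strength are configurable; the default follows the direction in
which learning asymmetry attenuates provariance bias with higher trait
load.

What the generator does *not* emulate: response-time dynamics tied to value
difference (RTs are schedule noise, not sequential-sampling output),
within-session drift in learning rates or attention, questionnaire
substructure beyond a single latent factor, and any fMRI signal. Tests that
pass on this cohort therefore validate the analysis machinery — they do not
show that human data satisfy the model's assumptions.

## Exclusions and statistics

Exclusion rules run in a fixed order: (1) mean accuracy across the four
different-mean blocks below 60%; (2) the same deck chosen on every trial of
at least one equal-mean block; (3) among survivors of rules 1–2, a PVB more
than 3 SD from that group's mean. "Mean accuracy" is read as the mean over
the four different-mean blocks (a per-block variant is available via
`per_block_rule1`). Rule 3 statistics deliberately include the candidate
subject itself, which means a single extreme subject in a small group can
fail to exceed 3 SD of a dispersion it itself inflates; this matches the
sequential narrative of the exclusion procedure rather than a leave-one-out
variant.

All tests are two-tailed: one-sample t against chance 0.5 per block type,
paired t between block types, and Pearson correlations (df = n - 2) among
PVB, fitted learning-rate bias, the trait composite (sum of the sample
z-scores of STAI and SDS) and the raw scales. No multiple-testing
correction is applied to these behavioral statistics.

## fMRI regressors

`run_model()` replays a fitted parameter set over a subject's outcomes and
emits per-trial, per-deck values, prediction errors and applied rates.
Two first-level designs are exported, each as 12 FSL 3-column EV files
(onset, duration, weight; fixed-point, 6 decimals) plus a JSON manifest:

- the **sign-split design**: choice-phase response, RT and mean regressors;
  parametric + mean pairs for the chosen deck's positive PEs, chosen
  negative PEs, unchosen positive PEs and unchosen negative PEs, each at the
  matching card-reveal onset with the card's display duration; and a
  joint-feedback mean. Negative-PE weights are sign-flipped magnitudes
  (larger = worse than expected) before demeaning.
- the **role-split design** (equal-mean blocks only): signed PEs split by
  deck role (broader/narrower) and choice status, plus a parametric
  expected-value-difference regressor (chosen minus unchosen pre-choice
  value) at the choice phase.

Parametric weights are demeaned within regressor by default so each
parametric column is orthogonal to its paired all-ones mean regressor
(`demean = FALSE` disables this). PE events use the revealed card's display
duration because the modeled duration is otherwise unspecified; a stick
(zero-duration) convention can be approximated by editing the exported
files. Design-matrix convolution and GLM estimation are out of scope.

## Numerical choices and degenerate inputs

- `delta = 0` takes the positive learning rate, by definition.
- Softmax probabilities are computed with `plogis`, which is overflow-safe
  at any `beta`.
- A deck scale of 0 (or small enough to underflow the Gaussian at every
  integer) yields a point mass at the rounded location.
- Rescaled outcomes are recomputed from the integer card values when a
  cohort is loaded from CSV, so text round-trips are exact.
- Schedules, cohorts, fits and recovery diagnostics are all deterministic
  given their seed arguments.

## Known limitations

The equal-mean-block design has an intrinsic identifiability ceiling. With
mean-matched decks on the bounded 1–13 support, the broad deck's rescaled
outcome SD cannot exceed roughly 0.2, so equal-mean value differences
hover near 0.1 and, at inverse temperatures up to 10, 120 choices carry
only a few nats of likelihood structure — comparable to the BIC penalty of
the two-rate model. Consequences, measured by this package's own
diagnostics at its documented scales (100 subjects for parameter recovery,
25 replicates per generator for model recovery): the correlation between
true and recovered learning-rate bias plateaus near 0.6 when `beta` is
drawn from U(1, 10), and BIC prefers the random baseline over the true
two-rate generator in most replicates. Recovery is excellent in the
high-information regime (the test suite verifies bias recovery within 0.1
on a 40-block horizon, and near-perfect selection of the random model).
Users applying the pipeline to designs of this size should treat
per-subject bias estimates as noisy, lean on cohort-level correlations,
and report recovery diagnostics alongside fits.
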