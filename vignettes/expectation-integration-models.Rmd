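---
title: "Expectation-integration models of controllable and predictable pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expectation-integration models of controllable and predictable pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paincontrol)
```

## The task and the question

Participants rate calibrated heat-pain stimuli on a 0--100 visual analogue
scale (VAS; 0 anchors the pain threshold, 100 the tolerance). Stimuli come
at three target intensities (VAS 30, 50, 70) under three conditions:
**controllable** (C; the participant chooses the next intensity),
**predictable** (P; the computer chooses but announces it), and
**unpredictable** (U; no information). Each run has 15 trials with every
level occurring exactly five times; each condition is run twice, giving 90
trials per subject.

Both C and P make the upcoming intensity perfectly predictable, so any
behavioural difference between them isolates what *control itself* adds.
The package implements the competing computational accounts of that
difference, the machinery to fit and compare them, and a synthetic-data
generator so that the whole analysis chain can be exercised and validated
without access to the original recordings.

## The observer model

Pain perception is modelled as Bayesian cue combination of an expectation
(prior) with nociceptive input (likelihood). For Gaussians, the posterior
mean is the precision-weighted average

$$\mu_1 = \frac{\tau_0^{-2}\mu_0 + \sigma^{-2} y}{\tau_0^{-2} + \sigma^{-2}}
       = \mu_0 + \alpha\,(y - \mu_0), \qquad
  \alpha = \frac{\tau_0^2}{\sigma^2 + \tau_0^2} \in [0,1],$$

and the posterior precision is the sum of the two precisions. Because the
separate magnitudes of $\tau_0$ and $\sigma$ are not identifiable from
ratings alone, the ratio enters as the single weight $\alpha$
(`alpha_from_variances()`, `shrink_mean()`). A linear drift $h\,t$ is
subtracted from the trial's target ($y_t = y_i - h t$,
`habituated_mean()`), capturing habituation ($h > 0$) or sensitisation
($h < 0$); $t$ is the 1-based trial index *within a run* (1..15), not a
cumulative counter — sites rotate between runs, which resets peripheral
adaptation, and the within-run index keeps $h$ identified.

Ratings live on a hard-bounded scale, so each rating is a draw from a
**truncated** normal on $[0,100]$ (truncation, not censoring: the scale
ends are real anchors, not clipped overflow). Truncation is what lets a
pure precision change move cell *means*: a wide distribution centred at 30
loses more mass below 0 than above 100, so its truncated mean rises, and
symmetrically falls at 70 (`trunc_normal_mean()`). Sampling uses the
inverse CDF (`rtrunc_normal()`), which needs no rejection loop even when
the location parameter sits far outside the scale.

### Condition structure and the eight variants

In C and P the cue removes the prediction error, so ratings are modelled
as draws from the condition's prior directly. In U the observer holds an
uncertain expectation and integrates it with the input via $\alpha$. Two
U-priors are implemented: a **fixed** subject-level constant (a priori
near the scale midpoint), and a **dynamic** prior equal to the
remaining-count-weighted average of the per-level prior means
(`dynamic_prior_mean()`): weights are remaining occurrences over remaining
trials, $5/15 = 1/3$ each at trial 1, drifting as stimuli are consumed
(e.g. downwards after three consecutive high stimuli).

The variants (`model_variants()`):

* `precision_change_{fixed,dynamic}` — C and P share prior means per
  level; their prior SDs $\tau_{0,C}, \tau_{0,P}$ differ. Control changes
  the *precision* of expectation.
* `mean_shift_{fixed,dynamic}` — C and P have separate prior means; one
  shared $\tau_0$. Control changes the *content* of expectation.
* `null_hab` — ratings are noisy readouts of $y_t$ everywhere; no
  expectation structure.
* `null_means` — free C/P prior means but no expectation bias in U.
* `two_alpha` / `three_alpha` — shrinkage in every condition with
  condition-specific weights ($\alpha_{CP}, \alpha_U$, respectively
  $\alpha_C, \alpha_P, \alpha_U$). These historical precursors are kept
  because their identifiability failure (see recovery below) is itself
  informative. They use the dynamic U prior, the better-supported choice
  of the two.

One deliberate resolution of an open modelling point: the habituation term
is applied in **all** conditions (subtracted from the C/P prior means and
from the U likelihood mean). Restricting $h$ to U trials would leave it
nearly unidentified from 30 trials, and the drift is a property of the
skin, not of the cue.

In `mean_shift_dynamic` the dynamic U prior averages the C- and P-specific
prior means per level, since the observer's generic intensity expectation
has no reason to prefer either labelled condition.

### Hierarchical structure and priors

Subject-level prior means are partially pooled around group-level means
(one per intensity level, prior $N(30/50/70,\,100)$) with pooling SD
$\sigma_{\mu_0}$; all SD-type parameters ($\sigma_{\mu_0}$, $\tau_0$,
$\tau_1$, null-model noise) are sampled on the log scale with
$\log(\cdot) \sim N(1.5, 0.5)$ (median $e^{1.5}\approx 4.5$ VAS); weights
$\alpha \sim N(0.5, 0.3)$ truncated to $[0,1]$ (truncation rather than a
logit link keeps the density bookkeeping trivial and the prior
interpretable on the natural scale); $h \sim N(0,1)$ VAS/trial; the fixed
U prior mean $\sim N(50, 100)$. $\alpha$, $h$ and the $\tau$'s are
subject-level without pooling: the subject-level spread of the weight is a
quantity of scientific interest in its own right, and pooling it would
entangle the recovery checks.

`fit_hierarchical()` samples the posterior with JAGS (4 chains; the
`paper` profile runs 4000 iterations with 1000 warm-up, the `recovery`
profile 1000/500 for simulate-and-refit studies, and a `smoke` profile
exists for fast pipeline checks). Every monitored parameter gets
split-$\widehat R$ and effective sample size; a fit is flagged (not
discarded) when any split-$\widehat R \ge 1.01$. The per-trial mean/SD
structure of the sampler's model code is asserted against the package's
own predictive core in the test suite, draw by draw, so the generative
sampler, the likelihood and the MCMC model cannot drift apart.

## Model comparison

Out-of-sample fit is measured by the expected log pointwise predictive
density (ELPD) under leave-one-out cross-validation:

* `psis_loo()` — importance-samples the LOO posterior from the full
  posterior, smoothing each observation's weight tail with a fitted
  generalized Pareto distribution (Zhang–Stephens profile likelihood
  estimator). The fitted shape $\hat k$ is the reliability diagnostic;
  observations with $\hat k > 0.7$ are flagged.
* `robust_loo()` — a mixture estimator: one auxiliary MCMC run targets
  the posterior multiplied by $\sum_i 1/p(y_i\mid\theta)$ (an equal-weight
  mixture of all leave-one-out posteriors), under which every
  per-observation weight is bounded, so all pointwise values are finite
  with no tail diagnostic needed.
* `exact_refit_loo()` — the oracle: refit once per held-out observation
  (capped at 200 observations).

`compare_elpd()` reports the ELPD difference with the standard error of
the pointwise differences; $|\Delta\text{ELPD}| < 4$ is treated as small.

## What the generator emulates — and what it does not

`simulate_dataset()` reproduces the task's schedule structure exactly
(5-per-level runs, two runs per condition, condition order balanced across
experiment halves) and draws every rating from the chosen variant's
trial-level truncated normal via the same predictive core the likelihood
uses.

Choice behaviour in C follows a constrained softmax over linear
trial-dependent utilities (high intensity favoured early, low late,
medium mid-run). The data themselves motivate this shape — dread reduces
when high pain is dispatched early — but the utility form is the package's
own minimal mechanism, chosen (once) so that the group-level
choice-frequency slopes have the observed signs and approximate sizes
(about $-3.6$ %/trial for high, $+3$ for low, and an inverted-U medium
profile); `choice_bias = 0.8` is that calibration point. P/U schedules are
yoked to C sequences by default, or probability-matched from the choice
model's per-trial frequencies.

Generator defaults are the package's study conditions, fixed once:
$\tau_{0,C} = 3$, $\tau_{0,P} = 8$ (a clearly separated precision-change
effect), $\tau_1 = 12$ (the scale of observed unpredictable-condition
rating variability), $\alpha = 0.74$ with between-subject SD $0.18$,
$h = 0$ (SD $0.3$), $\sigma_{\mu_0} = e^{1.5}$, null-model noise SD 12.
Reaction times are a condition-shift toy model anchored at observed
per-condition means (choices ~1.7 s, colour matching ~1.0–1.1 s) and
carry no further structure.

Passing tests on these data therefore show that the *machinery* is
correct — that parameters entered into the generative model are recovered,
that estimators agree with their oracles, that regressions detect built-in
effects at calibrated false-positive rates. They do not show that real
raters obey a truncated-normal observer model: real data bring rating
heaping, scale-use idiosyncrasies, drifting attention and
non-Gaussian noise that the generator deliberately omits.
`simulate_lmm_dataset()` is a separate, regression-native generator
(linear predictor plus subject intercepts, truncated to the scale) used
for mixed-model calibration and power; because of the bounds, a latent
interaction of 0.29 VAS/VAS appears attenuated in the realised cell
means, exactly as it would on a real bounded scale.

## Descriptive models

`fit_rating_lmm()` regresses ratings on linear intensity (anchored at
VAS 0, so the intercept is the extrapolated threshold response), condition
dummies, condition-by-intensity interactions, and trial and session
numbers, with a subject random intercept; priors are weakly informative
($N(0,50)$ intercept, Cauchy$(0, 2.5)$ weights, uniform positive error
SD). All three pairwise interaction contrasts are assembled by refitting
under a second baseline. `fit_sd_lmm()` does the same for within-subject
rating SDs with intensity as a three-level factor (the dispersion profile
is inverted-U over levels, which a linear term would misstate); the
per-trial predictors drop out because each SD cell pools a
subject-condition-level's trials — pooled over both sessions, ten ratings
per cell. Choice-frequency regressions use flat priors; JAGS cannot hold
an improper uniform over the real line, so $N(0, 10^4)$ stands in, which
is flat to machine precision at the scale of percentages.
`within_subject_sem()` centres each subject before computing error bars
(with the $\sqrt{M/(M-1)}$ small-cell correction), so condition plots
show within-subject uncertainty rather than between-subject offsets.

Interval summaries everywhere are highest-posterior-density intervals:
`hpdi()` returns the narrowest contiguous window over the sorted draws
containing $\lceil \text{mass}\cdot n\rceil$ of them, earliest window on
ties, and is tested against a brute-force window scan.

## Numerical choices, sizes, limitations

* Truncated-normal tails are computed on the better-conditioned side
  (reflection), so densities and quantiles remain finite for locations
  far outside the scale; ratings missing due to timeouts are dropped from
  every likelihood and SD cell.
* The Pareto-$\hat k$ reliability threshold is 0.7; the mixture chain of
  `robust_loo()` is initialised at the original fit's posterior means and
  its summed weight factor is computed under a data-derived log-scale
  shift with clamping, keeping the auxiliary target finite.
* Test and example sizes are chosen so the full chain demonstrates its
  properties at laptop scale: recovery checks use 12--20 subjects (the
  empirical-scale 60-subject recovery is a single function call,
  `parameter_recovery(variant, n_subjects = 60)`, left to the reader);
  model-selection checks use 8 subjects, where the precision-change
  versus mean-shift ELPD gap is already two orders above the
  small-difference convention; mixed-model calibration uses 50 replicates
  of 20 subjects at short chains.
* Known limitations: no reaction-time inference (summaries only); no
  cross-subject covariance between parameters; the choice model is a
  device for schedule realism, not a fitted cognitive model; JAGS's
  slice sampler needs more iterations than a gradient-based sampler
  would for the same effective sample size, which the profiles
  accommodate.
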