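---
title: "Conflict diffusion models and the cued-suppression analysis stack"
author: "condiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conflict diffusion models and the cued-suppression analysis stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condiff)
```

## The scientific problem

In hybrid flanker/visual-search cueing experiments, participants identify a
target letter (B or F) in a four-item array that also contains a *foil* — a
lower-case letter sharing the target's response feature (b or f), congruent
or incongruent with it. A spatial cue presented before the array either
points at the upcoming foil location (informative) or at all locations
(non-informative). If observers can use the cue to *proactively suppress*
the foil location, the response-time congruency effect should shrink under
informative cues — an interaction between congruency and cue. `condiff`
implements the complete analysis stack for this question: trial-schedule
construction, conflict diffusion-model simulation and fitting, RT
trimming/exclusion/congruency analyses, Bayesian mixed-model inference with
Bayes factors and HDI+ROPE decisions, a sequential-design controller, gaze
and rating auxiliaries, and a synthetic-data generator that makes the whole
chain testable against known ground truth.

## The two conflict models

Both models embed selective attention in a diffusion decision process:
noisy evidence accumulates towards symmetric response boundaries at
$\pm A$, and observed RT is the boundary-crossing time plus a non-decision
time $T_{er}$.

**Shrinking spotlight (SSP).** Attention is a zero-mean Gaussian window
over space whose sd starts at $sd_a$ and narrows linearly at rate $r_d$:
$\sigma(t) = \max(sd_a - r_d\,t,\ 0.001)$. With the target occupying the
unit interval $[-0.5, 0.5]$ and the foil mass aggregated outside it, the
momentary drift is

$$v(t) = p\,w_{target}(t) \pm p\,(1 - w_{target}(t)),$$

with $w_{target}(t)$ the window mass over the target region and the sign
set by congruency. On congruent trials the weights cancel and $v \equiv p$;
on incongruent trials drift starts low (or negative) and rises to $p$ as
the spotlight closes. The *interference time* $sd_a / r_d$ measures how
long foils influence the decision.

**Dual-stage two-phase (DSTP).** Response selection starts with drift
$\mu_{rs1} = \mu_t \pm \mu_{fl}$ while a parallel stimulus-selection
diffusion (drift $\mu_{ss}$, boundaries $\pm C$) races to pick one item.
If stimulus selection finishes first, response selection continues from its
current state with the late selective drift: $+\mu_{rs2}$ after target
selection (and after foil selection on congruent trials, where the foil
shares the correct response), $-\mu_{rs2}$ after foil selection on
incongruent trials. Its interference time is $\mu_{fl} / \mu_{ss}$. Both
models predict the classic *fast errors* on incongruent trials: accuracy in
the fastest RT bins is lowest because early drift is foil-contaminated.

The simulators (`simulate_conflict_trials()`) use Euler–Maruyama steps of
`dt_s = 0.001` s on the conventional diffusion scaling with within-trial
noise sd 0.1. These two constants are fixed conventions, not estimated
quantities. A trial whose decision process survives 10 s is resampled (and
counted); with `noise_sd = 0` the simulators become deterministic and match
the closed-form crossing times to one Euler step per boundary crossing,
which the test suite exploits as an oracle.

### Default parameter values

Default SSP values (`boundary` 0.07, `p` 0.4, `sd_a` 1.5, `r_d` 26/s,
`t_er` 0.3 s) and DSTP values (`boundary` 0.09, `boundary_C` 0.12, `mu_t`
0.12, `mu_fl` 0.18, `mu_ss` 0.40, `mu_rs2` 1.4, `t_er` 0.30 s) were
calibrated once, before any downstream testing, to produce
flanker-typical behaviour on this scaling: congruent accuracy near
ceiling, incongruent accuracy roughly 0.85–0.99, mean RTs of 450–650 ms —
comfortably inside the 200–1,200 ms trimming window — and a median-RT
congruency effect of a few tens of ms. They serve both as the population
means of the synthetic-data generator and as the fit routine's starting
means. A boundary an order of magnitude larger on this noise scaling would
push mean RTs towards ~3 s, where every simulated trial would be removed by
the trimming rule; such a configuration cannot represent the task.

## Model fitting

`fit_conflict_model()` fits by minimising the likelihood-ratio statistic

$$G^2 = 2 \sum_{bins} N\, p_{obs} \ln\frac{p_{obs}}{p_{pred}}$$

over quantile-binned RT/accuracy distributions of both congruency
conditions jointly. Observed correct RTs are summarised by the
.1/.3/.5/.7/.9 quantiles (linear interpolation), giving six bins whose
masses are scaled by accuracy; errors get the same treatment when at least
11 error trials exist, otherwise one pooled error bin. Predicted
proportions are the fractions of model-simulated trials landing in the
observed bins, floored at $1/(10\,n_{sim})$ to keep the logarithm finite.

The optimiser is Nelder–Mead in two steps: a broad search from `n_starts`
random starting points (each parameter $\sim N(\text{default},
\text{default}/5)$, truncated to its domain) at 1,000 simulated trials per
condition per evaluation, then a refinement from the step-1 best at 50,000.
Because the objective is stochastic, each Nelder–Mead run fixes its
simulation seed (common random numbers, re-drawn per start); the whole fit
is reproducible from its `seed`. Model comparison uses the binned BIC
$G^2 + k \ln N$ with $k = 5$ (SSP) or $k = 7$ (DSTP).

Identifiability note: `sd_a` and `r_d` trade off strongly; their ratio
(the interference time) is well constrained while the individual values
are not. Recovery checks therefore target `p`, `boundary`, `t_er` and
`sd_a / r_d`.

## Behavioural analyses

* `trim_rts()` removes responses outside 200–1,200 ms (strict
  inequalities: exactly 200 or 1,200 ms is kept); catch trials pass
  through.
* `apply_exclusions()` drops participants failing ≥50% of catch trials
  (any keypress on a catch trial is a failure), then those with overall
  accuracy <85%, then those losing >40% of trials to trimming — evaluated
  in that order, first match recorded. The ≥ reading of "failing 50%" is a
  documented choice; the other two bounds are strict by their wording.
* `congruency_effect()` computes CE = median incongruent − median
  congruent RT on correct trials; the positive control demands CE > 0 in
  more than 75% of participants before any suppression conclusion is
  meaningful.
* `conditional_accuracy()` builds five-bin CAFs within each cue ×
  congruency cell (quintile edges, linear interpolation).

## Bayesian inference

`cell_means()` averages correct trimmed RTs per participant × congruency ×
cue (arithmetic means; the CE positive control separately uses medians by
its own definition). `fit_mixed_model()` samples the random-intercept model
`mean_rt ~ congruency * cue + (1 | participant)` with JAGS (treatment
coding, 4 chains × 5,000 draws with 2,000 warmup by default, convergence
monitored by split-chain R-hat with a warning flag above 1.05). Priors are
weakly informative and data-scaled: slopes $N(0, (2.5\,sd_y)^2)$, intercept
$N(\bar y, (5\,sd_y)^2)$, uniform sds capped at $5\,sd_y$.

**Bayes factor.** In the balanced 2×2 within-participant design the
interaction-vs-main-effects comparison is carried entirely by the
per-participant double difference; the random intercept and the main
effects are orthogonal to it and common to both models. The package
therefore computes the interaction Bayes factor as the JZS default-prior
one-sample Bayes factor on those contrasts (Cauchy scale $\sqrt{2}/2$ on
the standardized effect), by numerical integration over the g-mixture
representation. This makes the estimate deterministic and cheap enough to
re-evaluate at every interim analysis. The method is recorded in the
output; the test suite cross-checks the integral against an independent
Monte-Carlo estimate.

**HDI + ROPE.** The region of practical equivalence is ±0.1 standardized
units, realized as ±0.1 × sd of the cell-mean outcome (a few ms on typical
cohorts). The reported percentage counts posterior draws inside the 89%
HDI that fall within the ROPE — draw counting, not interval-overlap
arithmetic, which can disagree with it on skewed posteriors. Equivalence is
accepted (rejected) when more than 89% of the HDI mass lies inside
(outside); anything else is inconclusive.

**Sequential design.** `sequential_controller()` evaluates the Bayes
factor at 80 participants and every 20 thereafter, stopping at the first
interim with BF > 10 or BF < 1/10, else at 200. Interim analyses refit from
scratch on the accumulated sample; no interim beyond the first stopping
point is computed.

## Auxiliary analyses

Gaze streams (60 Hz, screen-normalised) are scored by `aoi_occupancy()`: a
trial counts as centrally fixated when at least half of its samples in the
first 500 ms lie inside the closed box x, y ∈ [0.35, 0.65] (the bracketed
bounds are treated as closed; sample-free trials leave the denominator).
`rating_summary()` summarises the four cue-association questions and forms
a learning index (informative-valid minus informative-invalid means).
`code_percentages()` turns content-analysis tallies into percentages of the
tally total, and `cohens_kappa()` is the unweighted nominal-code kappa
(defined as 1 when both coders are constant and identical).

## The synthetic-data generator

`generate_cohort()` draws per-participant model parameters from a truncated
normal population (default sds 10% of the means), simulates every scheduled
trial from the generator model, and adds the nuisance processes the real
pipeline must survive: fast guesses (uniform 80–199 ms, 50% accuracy) and
slow outliers (uniform 1,201–2,500 ms) at 2% each — constructed to be
removed by the trimming rule — catch responses withheld with probability
0.95, Gaussian gaze noise around screen centre with occasional excursions,
no-learning ratings (all four questions share one Beta-scaled
distribution), and two coders with 80% agreement over a six-code book. An
optional suppression effect shrinks `sd_a` (SSP) or `mu_fl` (DSTP)
proportionally on informative-cue trials. All drawn parameters are returned
as ground truth, and `ground_truth_report()` scores recovery against them.

What the generator does *not* emulate: sequential effects (post-error
slowing, congruency sequence effects), RT drift over blocks, parameter
non-stationarity, letter-identity confusions, or WebGazer's structured
estimation error (gaze noise is Gaussian with excursions). Passing tests on
synthetic cohorts therefore validate the machinery and its calibration
under the stated generative assumptions, not the models' adequacy for any
particular empirical dataset.

## Numerical choices and problem sizes

* Euler step 1 ms; diffusion noise 0.1; spotlight sd floor 0.001;
  non-termination guard 10 s.
* Quantile and quintile ties: linear interpolation (R quantile type 7).
* Predicted-proportion floor $1/(10\,n_{sim})$.
* The parameter-recovery check simulates 10,000 trials per condition and
  refits with 10 starts and a 50,000-trial refinement; the
  model-selection and refinement properties run at reduced scale (hundreds
  to a few thousand trials, 2–3 starts) — sizes chosen so the full suite
  exercises every code path at meaningful precision.
* Inference calibration uses 20 replicates of 100-participant cohorts
  simulated at the cell-mean level (congruency effect 40 ms, cue effect
  5 ms, participant sd 40 ms, residual sd 30 ms, interaction 0 or 30 ms).

## Known limitations

* Across-trial variability parameters (drift, starting point) are out of
  scope, as are analytic first-passage likelihoods; everything is
  simulation-based.
* `sd_a` and `r_d` are reported individually but only their ratio should
  be interpreted.
* The four-item search display is reduced to the classic two-region
  spotlight geometry in both models, for the separated-locations design
  too; this conventional reduction is an assumption, not a fitted choice.
* The JZS contrast Bayes factor is exact for the balanced 2×2 design; with
  heavily unbalanced or incomplete cells it drops participants and should
  be interpreted with care.
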