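---
title: "State-space models of visuomotor adaptation under sensory uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-space models of visuomotor adaptation under sensory uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmadapt)
```

## The problem

When people reach under a visuomotor rotation, two control processes act at
once. A *feedforward* process plans the movement direction before the hand
moves and adapts from trial to trial in response to experienced errors. A
*feedback* process corrects the ongoing movement when cursor feedback appears
mid-reach. `vmadapt` models both processes jointly in an experiment where
cursor feedback is delivered briefly at the movement midpoint and/or endpoint
at one of four uncertainty levels: a single veridical dot (`L`), a 50-point
cloud with per-axis SD 0.5 cm (`M`) or 1 cm (`H`), or no feedback at all
(`INF`). The scientific question is *where* sensory uncertainty acts on the
learning system, and the package provides the machinery to ask it on
synthetic data: experiment generators, the candidate models, global fitting,
BIC comparison, and the regression layer used to describe behaviour without
committing to a model.

## Experiment designs

Each session has 20 baseline trials (veridical continuous feedback, no
rotation), 180 adaptation trials, and 100 washout trials (no feedback, no
rotation). Adaptation-trial rotations are drawn once per schedule from a
Gaussian with mean 12° and SD 4° (counter-clockwise positive) and shared by
all participants, as are the uncertainty labels: a seeded permutation of a
balanced vector with 45 trials per condition. Experiment 1 shows feedback at
midpoint only; Experiment 2 at midpoint and endpoint with matched levels;
Experiment 3 crosses low/high midpoint with low/high endpoint uncertainty
(trial types `LL`, `LH`, `HL`, `HH`).

```{r design}
sch <- build_schedule(1, seed = 1)
table(sch$phase)
table(sch$mp_uncertainty[sch$phase == "adaptation"])
round(angular_subtense(0.5, 5), 2)   # arc-angle of the 0.5 cm cloud SD at midpoint
```

## The model family

Within a trial, motor output is defined at three time points. The
feedforward command `y_ff` (one state, or the sum of a fast and a slow
state) is issued at reach initiation and held fixed; the cursor error seen at
midpoint is `delta_MP = y(t0) + r`; the feedback command responds to it as

    y_fb(t_MP) = -x_fb * delta_MP * eta[level],

where `x_fb` is a feedback gain and `eta` holds one scaling entry per
uncertainty level; the endpoint error is `delta_EP = y(t_MP) + r`. Between
trials the feedback gain updates from the endpoint error alone
(`x_fb <- beta_fb * x_fb + alpha_fb * delta_EP`, deliberately insensitive to
uncertainty), the slow state updates from both errors with the midpoint
feedback command treated as an error signal, and the fast state updates
according to one of five hypotheses about where uncertainty acts:

* **error-scaling** — uncertainty multiplies the error-driven term,
  with a temporal-discount weight `gamma` splitting midpoint from endpoint
  influence;
* **retention-scaling** — uncertainty multiplies the retention term;
* **bias-scaling** — uncertainty multiplies a constant bias `lambda`;
* **state-aim-scaling** — the fast state is *memoryless*: it equals the
  uncertainty-weighted bias outright, with no retention and no error term;
* **output-aim-scaling** — the states follow the unscaled dynamics and an
  additive aim term, set by the *previous* trial's uncertainty, enters the
  motor output directly.

Each hypothesis exists in one-state, two-state, and non-negative two-state
variants (the last constrains parameter bounds, not trajectories, so that
the internal states stay positive).

### Numerical and sign conventions

Three conventions deserve explicit statement because the equations above are
easy to implement with divergent signs.

1. **Learning acts on the target-compensation error.** The sensory
   prediction errors are cursor errors (`delta = y + r`, positive when the
   cursor misses counter-clockwise). Adding `alpha * delta` to the state
   verbatim would push the state *toward* the error and diverge under a
   constant rotation. The simulator therefore feeds the learning rules the
   sign-flipped error — the classic target-minus-output error with the
   target at zero — so that adaptation drives `y_ff` toward `-r`. The
   exported update operations (`update_fast_state()` etc.) are written
   exactly as the equations read and apply to whatever error signal they are
   handed; `simulate_trial()` documents the flip. Reporting utilities
   (`adaptation_extent()`) flip the sign once more so that adaptation extent
   is a positive number.
2. **The two error signals are algebraically redundant.** Because
   `y(t_MP) = y(t0) + y_fb`, the feedback-corrected endpoint error
   `delta_EP - y_fb` equals `delta_MP` identically. One consequence is an
   exact collapse identity used as an oracle in the tests: with all scaling
   entries at 1, the error-scaling family (whose `gamma`-blend of the two
   signals is convex) reduces to the classic single-error dynamics at
   learning rate `alpha`, while retention- and bias-scaling (whose two error
   terms add) reduce to it at rate `2 * alpha`.
3. **No-feedback events are simulated literally.** The `INF` level and the
   washout phase carry fitted scaling entries (`nu[INF]`, `eta[INF]`), so
   the equations are evaluated with latent errors everywhere and those
   entries absorb the no-feedback condition; baseline and washout trials
   (uncertainty "none") index the `INF` slot. A control switch
   (`sim_control(zero_error_on_nofb = TRUE)`) instead zeroes error-driven
   terms on events where nothing was displayed, for sensitivity analysis.
   Trials without a midpoint feedback *event* (baseline, washout) issue no
   feedback command in either mode.

Two bound-table ambiguities were resolved as package decisions: the aim
families keep `lambda_f` as their aim amplitude with bounds (-10, 10)
(non-negative variant (0, 10)) although the printed table marks it absent,
because the aim equations require it; and the output-aim family carries
fast-state `alpha_f`/`beta_f` in (0, 1) so that its prescribed unscaled
state dynamics exist, with the bias term omitted from the state update since
its `lambda` has moved into the output. Everything else in the bound table
is transcribed literally, including its quirks (e.g. the bias-scaling
non-negative column narrowing only the fourth feedback-scaling entry).

```{r simulate}
spec <- model_spec("state_aim_scaling", n_states = 2)
params <- default_generator_params(spec)
sim <- simulate_session(sch, params, spec)
round(tail(sim[, c("y_t0", "y_tMP", "delta_MP", "x_fast", "x_slow")], 3), 2)
```

## Synthetic participants

`generate_participant()` injects i.i.d. Gaussian motor noise into the
initiation output *before* the midpoint error is computed, so noise
propagates through the feedback correction and the learning updates the way
a real participant's execution variability would; observation noise is added
to the recorded series last. Cohorts share one schedule (trial-matched, 20
participants per experiment by default) with independent noise streams, and
every dataset records the provenance needed to regenerate it bit-identically.

The reference generator is the two-state state-aim-scaling model with
mid-range parameters: feedforward scaling `nu_ff = (0.9, 0.6, 0.3, 0.05)`
decreasing with uncertainty, feedback scaling `nu_fb = (1, 0.6, 0.3, 0)`,
aim amplitude `lambda_f = -9`° (compensatory in the model frame), a slow
state with `alpha_s = 0.04`, `beta_s = 0.99` carrying the adaptation
envelope, and feedback-gain dynamics `alpha_fb = 0.05`, `beta_fb = 0.9`,
`x_fb_init = 0.5`. The study gives no behavioural noise magnitude, so the
suite's default motor noise of 1° is a property of the tests, not a claim
about data. These synthetic data reproduce the qualitative signatures of
interest — late-adaptation stratification by the previous trial's
uncertainty under aim-type generators, level-ordered error-response slopes
under error-scaling generators — but not other features of real behaviour
(reaction times, outliers, slow drifts, participant heterogeneity), so
passing tests validate the machinery, not any claim about human data.

```{r extent}
ds <- generate_participant(spec, params, sch, noise_model(motor_sd = 1),
                           seed = 8)
round(adaptation_extent(ds), 2)  # degrees, compensation-positive
```

## Fitting and model comparison

Parameters are estimated per participant by minimising the sum of squared
midpoint plus endpoint hand-angle residuals over the adaptation and washout
phases (washout decay is what identifies retention; baseline is excluded by
default, and both choices are exposed as `fit_phases`). Endpoint angles are
fitted even in Experiment 1, where they are measured kinematically though no
endpoint feedback is shown. The search is a classic rand/1/bin differential
evolution over the per-family bound boxes with reflection at the bounds, a
dithered differential weight in `[0.5, 1]`, seeded restarts, and a bounded
quasi-Newton polish of the best member; the whole population is evaluated
at once through a vectorised simulator, which is what makes desk-scale
recovery studies practical. Divergent parameter regions (the printed bounds
allow them, e.g. `|beta_fb| > 1`) are assigned a large finite cost.

`R²` pools midpoint and endpoint residuals against the pooled mean, and
`BIC = n ln(1 - R²) + k ln(n)` with `n` the number of residuals entering the
objective (2 × fitted trials) and `k` the number of free bound-table rows.
Models are compared per participant by BIC rank (ties broken by parsimony,
then name, and flagged) and across participants by Bonferroni-corrected
paired t-tests with Hedges g (bias-corrected standardised mean paired
difference). An all-pairs Bonferroni scheme is used where a designated
reference model would otherwise be required, since none is singled out.

Problem sizes used by the shipped recovery and identifiability studies (the
package's own defaults): one 300-trial session per participant, five
synthetic participants per generating family, all five families fitted to
every cohort at a reduced optimizer budget (population 4 per dimension, 300
generations, one restart), and tolerances pinned from pilot recovery runs —
noiseless recovery reaches an objective below 1 squared degree and per-level
aim values within 0.5°; under 1° motor noise the per-level values can trade
a common offset (bounded at 2.5°) while their spread stays within 0.75°.
Because several families are near-nested (bias-scaling with zero learning
and retention *is* state-aim-scaling, one parameter dearer), identification
is asserted as a majority across generating families, not perfection.

## The regression layer

The descriptive analyses regress group-averaged adaptation-phase behaviour
on backward-difference-coded uncertainty (each coefficient estimates an
adjacent-level difference), the experienced errors, their interactions, and
`log(trial)` for the initial-movement-vector model. Feedforward analyses
(`imv`, `delta_imv`) take all error and uncertainty predictors from the
previous trial and drop the first adaptation trial; the feedback-integration
analysis (endpoint hand angle minus initial movement vector, per the
figure-caption convention) uses current-trial predictors. Experiment 1 omits
endpoint-error terms; Experiment 3 treats the four trial types as an ordered
factor, except for feedback integration, where the two midpoint levels enter
as a single centred contrast. Relative importance is the decomposition that
averages sequential R² contributions over all predictor orderings — the
standard choice that is non-negative and sums to the model R² — computed by
subset enumeration and reported per column and per term family.

The washout analysis scores, per participant and uncertainty type, the mean
compensation-positive accuracy over the last 10 adaptation trials *of that
type* (trials grouped by the previous trial's uncertainty, the grouping
under which behaviour stratifies) minus the mean over the first 3 washout
trials (a short window limits contamination from forgetting), then compares
types by repeated-measures ANOVA with generalized eta-squared and
Bonferroni-corrected paired t-tests.

```{r regress}
coh <- generate_cohort(spec, params, n_participants = 8, experiment_id = 1,
                       noise = noise_model(1), seed = 5)
des <- build_design(group_average(coh), regression_spec("imv", 1))
fit <- fit_regression(des)
fit$coefficients[, c("name", "coef", "se", "pval", "relimp")]
```

## Kinematics

For raw 200 Hz trajectories, movement onset is the first sample above 5% of
peak speed after the hand leaves the 0.5 cm start region, and offset the
first sample below 5% of peak speed after 9.5 cm of radial distance; speed
comes from central finite differences with no smoothing, as the procedure
specifies. The initial movement vector is read from the instantaneous
velocity direction at onset (a chord over the first k samples is available
as an option, documenting the ambiguity between the two readings), and the
endpoint hand angle from the start-to-endpoint chord at offset, both CCW
positive relative to the start-to-target line. The fixture generator
produces minimum-jerk two-segment reaches with a midcourse correction; its
optional noise is smooth 1–3 Hz speed-gated wobble, because white positional
noise is incompatible with unfiltered velocity thresholding (the detectors
would see no quiet terminal dwell). Recovery bounds under wobble were
measured on this family and pinned in the tests.

## Known limitations

* The temporal-discount weight `gamma` is interpretable only in Experiment
  3; in Experiments 1 and 2 it is confounded with the scaling amplitudes
  (Experiment 1 fixes every endpoint-indexed factor at the `INF` entry).
* In the state-aim family, `nu_ff` and `lambda_f` enter only as products;
  individual values are reported but only the products are identifiable.
* Differential evolution is stochastic; results are exactly reproducible
  under a seed, but different seeds can land in different near-ties between
  near-nested families. The comparison layer treats small BIC margins
  accordingly.
* Group-averaged OLS is the only regression variant, matching the analysis
  it mirrors; no mixed-effects alternative is provided.
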