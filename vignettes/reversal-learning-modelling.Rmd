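---
title: "Modelling serial probabilistic reversal learning with revlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling serial probabilistic reversal learning with revlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
```

## The task

Serial probabilistic reversal learning (PRL) probes behavioural
flexibility. Two abstract stimuli are shown side by side; one is currently
*correct* and yields positive feedback, except on a minority of misleading
trials where a correct choice receives spurious negative feedback that
should be ignored. Once the participant has made a criterion number of
correct choices within the current sequence, the contingency silently
reverses and the other stimulus becomes correct.

`task_config()` encodes the task constants: two runs of ten sequences
(hence 18 reversals for an agent that always reaches criterion), a
cumulative-correct criterion drawn uniformly from 10--15 per sequence,
misleading negative feedback on 15% of correct choices, and a hard cap of
200 trials per run for agents that fail to progress.

Decisions embedded in the generator, where the verbal task description
leaves room:

* Misleading feedback is i.i.d. Bernoulli(0.15) per correct trial. The
  original task modulated the misleading rate around reversals by an
  unspecified rule; the stationary approximation is used and the realised
  rate is observable in every log.
* Incorrect choices never receive spurious *positive* feedback.
* The cumulative-correct count includes correct choices that happened to
  draw misleading feedback (the criterion is about responses, not
  feedback), counts non-consecutively, and resets at each reversal.
* The 200-trial cap is per run: a capped run ends and the next run starts
  fresh.
* Missed ("too late") trials, the practice run, stimulus timing and
  inter-trial intervals are not modelled; the data contain completed
  choices only.
* Stimulus-to-side assignment is uniform-random and independent across
  trials, and the initially correct stimulus is randomised per run.

`generate_session()` runs any choice policy through the task and returns
the full annotated trial log; `validate_session()` re-checks every
structural invariant and is applied to all generated cohorts in the test
suite.

## The model family

All seven models maintain a value $V_i$ per stimulus (initialised at 0.5,
the midpoint of the binary outcome range, so the first choice is
unbiased), and choose through a softmax over option quantities $Q$:

$$P(a) = \frac{e^{\beta Q_a}}{\sum_k e^{\beta Q_k}},$$

with $\beta = 1$ everywhere except the experience-weighted attraction
model, so the $\tau$ weights below act directly as softmax-exponent
weights.

* **M1**: $V_c \leftarrow V_c + \alpha^{reinf}(R - V)$ for the chosen
  stimulus, $Q = \tau^{reinf} V$.
* **M2**: M1 plus stimulus stickiness $Q^{stim} = \tau^{stim} s_{t-1}$,
  where $s_{t-1}$ indicates the previously chosen stimulus.
* **M3**: separate learning rates, $\alpha^{rew}$ after reward and
  $\alpha^{pun}$ after nonreward.
* **M4a**: M3 plus side stickiness $Q^{loc} = \tau^{loc} L_{t-1}$ for the
  previously chosen screen side.
* **M4b**: M3 plus stimulus stickiness.
* **M4c**: M3 plus both stickiness terms (five free parameters; the
  winning model of the family).
* **M5** (EWA): experience weights $n$ per stimulus with
  $n' = n\rho + 1$ and $V' = (\phi\, n V + R)/n'$, free inverse
  temperature $\beta$, $Q = V$.

Conventions where the published description is not self-contained:

* The EWA update follows the parameterisation standard in the
  reversal-learning literature, with $n_0 = 1$ and payoff
  $R \in \{0, 1\}$; only the chosen stimulus's $n$ and $V$ update
  (unchosen-option experience does not decay).
* Stickiness indicators are all-zero on the first trial of a session and
  persist across the between-run break (state resets per session, not per
  run).

The compiled likelihood is checked against an independently written naive
trial-loop oracle at 100 random parameterisations (tolerance $10^{-10}$),
and the nesting ladder (M4c with $\tau^{loc}=0$ equals M4b, and so on
down to M1) is asserted exactly.

## The hierarchy

The design crosses three groups (healthy controls, stimulant use disorder,
OCD) with three within-subject drug sessions (placebo, amisulpride,
pramipexole). Estimation uses the cell-means parameterisation: each free
parameter gets nine cell means $\mu_{g,d}$ with identical priors across
cells, one inter-subject SD $\sigma$, and one deviation $\delta_s$ per
subject shared across that subject's sessions (capturing the
within-subject correlation structure). The value entering a session's
likelihood is $\mu_{g,d} + \delta_s$, truncated to the parameter's
support. Missing sessions simply contribute no likelihood term.

Priors (`prior_spec()`): Beta(1.2, 1.2) for learning rates and EWA decay
factors; Gamma(shape 4.82, rate 0.88) for $\tau^{reinf}$ and the EWA
$\beta$; Normal(0, 1) for the stickiness weights. Inter-subject SDs are
half-Normal: scale 0.05 for unit-interval parameters and $\tau^{loc}$,
scale 1 for $\tau^{reinf}$ and $\beta$. The SD prior for $\tau^{stim}$ is
not pinned down by the published prior table; half-Normal(0, 1), as for
the other unbounded weight, is assumed.

Additive Normal deviations around constrained cell means can stray outside
a parameter's support; clamping to the support is used rather than a
transformed scale. The tiny SD priors make clamping rare, and the
synthetic-cohort generator applies the identical clamping, so parameter
recovery tests the estimator rather than a generator/fitter mismatch.

### Sampling

`sample_posterior()` runs an adaptive random-walk Metropolis-within-Gibbs
sampler written in C++: one Gaussian proposal per scalar (cell means,
deviations, SDs), with per-coordinate step sizes adapted during warmup
toward a 0.44 acceptance rate and frozen afterwards. A joint *scale move*
per parameter multiplies $\sigma$ and all of that parameter's deviations
by a common factor; this traverses the half-Normal funnel that
coordinate-wise updates cross slowly and is what keeps the SD quantities
well mixed. Chains are initialised overdispersed (cell means drawn from
their priors) and seeded deterministically, so every fit is exactly
reproducible.

Defaults are 4 chains, 1000 warmup and 1000 retained draws. The
experiments in the test suite use 4 chains with 1500 warmup and 2500
draws thinned by 2 for fitted cohorts. Convergence is monitored by
split-chain $\hat R$ on every stored quantity; the recovery experiment
requires at least 99% of quantities below 1.1, mirroring the convergence
standard of the original analysis.

### Contrasts

`cell_contrasts()` computes draw-wise differences: between-group
differences on placebo, within-group drug effects, and
difference-in-difference contrasts
$(\text{patient}_{drug} - \text{patient}_{placebo}) -
(\text{HC}_{drug} - \text{HC}_{placebo})$, each summarised by 95% and 90%
highest-density intervals (`hdi()`: the shortest contiguous interval
containing the requested mass). No multiplicity adjustment is applied;
hierarchical shrinkage plays that role. Note that sample HDIs at two
masses are nested only up to order-statistic noise, and HDI endpoints
converge more slowly than interval widths; the tests account for both.

## Model comparison

`bridge_log_ml()` implements the iterative optimal-bridge estimator of
the marginal likelihood: draws are mapped to an unconstrained scale
(logit for unit-interval parameters, log for positive ones, with Jacobian
corrections), half of them fit a moment-matched multivariate normal
proposal, and the bridge identity is iterated in log space to a fixed
point (tolerance $10^{-10}$, at most 1000 iterations; a small ridge
stabilises near-degenerate covariances). The reported standard error uses
the independence approximation to the estimator's relative mean squared
error. On Beta--Bernoulli and Normal--Normal conjugate toys the estimate
lands within 0.05 nats of the closed-form evidence.

`compare_family()` fits each model, estimates its evidence over the full
hierarchical joint, and ranks the family under equal prior model
probabilities; `posterior_model_probabilities()` performs the
log-sum-exp arithmetic and is checked against the published
seven-model evidence table.

## Behavioural measures

Definitions follow the conventional PRL analysis, with two conventions
made explicit where the verbal definitions are ambiguous:

* A perseverative streak is the run of consecutive choices of the
  previously correct stimulus starting at the reversal; the error on the
  *first* post-reversal trial is excluded from the count but can start a
  streak, which ends at the first choice of the newly correct stimulus.
  The rate divides the total count by the number of sequences containing
  at least one counted error, and is 0 (flagged, so cohort averages stay
  defined) when there are none.
* Probabilistic switches and spontaneous errors require the switch on the
  immediately following trial, within the same run, and the switch must
  land on the currently incorrect stimulus -- so a switch that happens to
  cross a reversal onto the newly correct stimulus is not an error.

Trials per sequence averages over all sequences of a session, including a
final cap-terminated incomplete sequence if present. Win-stay and
lose-shift are raw stay/shift probabilities conditional on the previous
trial's reinforcement.

`stats_harness()` reproduces the classical analysis applied to simulated
behaviour: per measure, a one-way between-group ANOVA on placebo, pairwise
Welch t-tests (the unequal-variance form, matching the fractional degrees
of freedom reported in this literature), and a group-by-drug two-way ANOVA
when several drug conditions are present.

## Synthetic cohorts and the simulation experiments

The clinical raw data are not deposited and the fitted posterior means are
not printed, so all estimation experiments run on synthetic cohorts.

`preset_cells()` provides three generating-parameter presets for the
winning model:

* `placebo_pattern` encodes the qualitative placebo-group pattern at
  chosen magnitudes: a healthy-control baseline of
  $\alpha^{rew} = \alpha^{pun} = 0.40$, $\tau^{reinf} = 5.5$ (the
  Gamma-prior mean, rounded), $\tau^{stim} = 1.0$, $\tau^{loc} = 0.3$;
  the SUD cells lower $\alpha^{rew}$ to 0.12, raise $\alpha^{pun}$ to
  0.60 and raise $\tau^{stim}$ to 1.8; the OCD cells raise
  $\alpha^{pun}$ to 0.55 and lower $\tau^{stim}$ to 0.35. The magnitudes
  were chosen once so that the preset reproduces the qualitative
  behavioural signature it is meant to emulate -- the slow-learning,
  sticky, punishment-sensitive stimulant-use group requires more trials
  per sequence and makes more spontaneous errors than controls -- and are
  documented here as presets, not as fitted values.
* `stickiness_only` makes $\tau^{stim}$ the sole between-group difference
  (2.2 / 1.0 / 0.2 for SUD / HC / OCD), isolating stimulus stickiness for
  the ablation experiments.
* `spread` assigns each parameter nine well-separated values permuted
  differently across cells, for parameter recovery, where rank
  correlations between truth and estimate are only meaningful if the
  truths differ.

`generate_cohort()` mirrors the study design (defaults 19/18/19 subjects
per group, three sessions each) with per-subject deviations drawn from
Normal(0, SD) and the same support clamping as the fitter. The
experiments in the test suite use a reduced preset -- 6 subjects per
group, and 40 virtual subjects per cell for the identical-agent
simulations over 20 seeds -- sizes chosen to keep the full suite
comfortably reproducible on a laptop while leaving the statistical
conclusions unambiguous.

`posterior_mean_simulation()` reproduces the identical-virtual-subjects
design: no inter-subject variability, all behavioural variability coming
from choice sampling and side assignment. `fixed_parameter_ablation()`
replaces one parameter in every cell by the mean of the nine cell values
and re-runs the pipeline; fixing $\tau^{stim}$ abolishes a
stickiness-driven group effect on the perseverative error rate while
fixing $\tau^{loc}$ leaves it intact, the package's directional
replication of the published ablation finding.
`parameter_recovery_experiment()` closes the loop: generate from known
cell means, fit, and report rank correlation, HDI coverage and
convergence.

## What the synthetic data do and do not show

The generator reproduces the task's reinforcement structure and the
hierarchical data-generating process assumed by the model, which makes it
the right instrument for validating the estimators (recovery, coverage,
evidence arithmetic) and for sufficiency-style simulation arguments. It
does not emulate reaction times, session-order or practice effects,
missed trials, pharmacokinetic variation, or any behaviour outside the
model family; passing tests therefore certify the machinery, not the
clinical conclusions, which would require the original data.

## Numerical choices, in one place

* $V$ initialised at 0.5; stickiness indicators zero on trial 1.
* Softmax computed with max-subtraction; likelihoods accumulated in log
  space.
* Subject-level values clamped to parameter supports (ties between the
  generator and the fitter).
* Bridge iteration tolerance $10^{-10}$, max 1000 iterations, proposal
  covariance ridge $10^{-8}$ of the mean diagonal.
* MWG adaptation in batches of 50 toward 0.44 acceptance (0.3 for the
  scale move), gain capped at 0.25 and decaying as the inverse square
  root of the batch number.
* All randomness flows through R's RNG: one seed per command or
  experiment reproduces every downstream artifact, including the compiled
  simulator, which consumes the RNG stream in the same documented order
  as the R task engine (the two are draw-for-draw identical under a
  shared seed, and a test asserts it).
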