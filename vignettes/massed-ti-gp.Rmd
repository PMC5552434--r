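---
title: "Massed-training transitive inference: design, simulation and GP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Massed-training transitive inference: design, simulation and GP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigp)
```

## The task and its design

In a transitive-inference (TI) task a subject learns an ordered list of
stimuli — here seven items labelled A through G, rank 1 (A) earliest —
purely from pairwise trials: two items are shown, choosing the earlier one
is rewarded. Once the premise pairs are learned, subjects can typically
infer the order of pairs they have never seen together (choose B over D
after learning AB, BC, CD), with two robust behavioural regularities:

* **symbolic distance effect** — accuracy rises and reaction time falls
  with the rank separation of the two items;
* **terminal item effect** — pairs containing the first (always rewarded)
  or last (never rewarded) item are easier.

The massed-training variant probes *what* is learned during heavy training
of a single pair. A session has three phases: phase 1 presents only the
final pair FG (massed block); phase 2 presents the adjacent pairs plus all
pairs containing F or G (15 of the 21 pairs); phase 3 presents all 21
pairs. In the primate protocol each session is 760 trials (40 massed FG,
then 20 presentations of each pair in phases 2 and 3: 40 + 300 + 420), and
every session uses novel stimuli. The human protocol is a single session
of half that length (20 + 150 + 210 = 380). `build_schedule()` constructs
such sessions: each phase is a uniformly random permutation of its pair
multiset, with the correct item placed on each side of the screen on
exactly half of a pair's presentations.

Each pair carries two orthogonal coordinates used throughout the
analyses: symbolic distance (rank difference) and *joint rank* (rank sum;
e.g. BD has distance 2 and joint rank 6). Over the 21 pairs the map
pair → (distance, joint rank) is one-to-one and the two coordinates are
uncorrelated by construction, so both can serve as predictors of a joint
response surface without collinearity.

Two design points are not fixed by the protocol description and are
resolved here as package defaults: ordering within a phase is a single
uniform shuffle of the full phase multiset (no blocking), and trial
indices run continuously across phases (phase 2 of the primate design
starts at trial 41), which is the axis convention all analyses use.

## The two agent families

No subject-level data ship with the package; instead two simulator
families generate trial records with the statistical structure the
analyses are meant to detect. They formalise the two competing accounts
of massed-training TI, and they are deliberately minimal: their job is to
produce the qualitative signatures, not to fit any particular animal.

**Associative agent** (`associative_config()`). Each item carries a
scalar value $v_i$, initialised at $v_0 = 0.5$. Choice between the
displayed items $i, j$ is a softmax on the value difference,
$P(\text{choose } i) = \operatorname{logit}^{-1}\{\beta (v_i - v_j)\}$.
After feedback the chosen item's value moves toward the reward outcome by
the delta rule $v \leftarrow v + \alpha(r - v)$, $r \in \{0, 1\}$, and
with transfer coefficient $\theta > 0$ a fraction of the rewarded item's
value leaks to its partner
($v_j \leftarrow v_j + \theta\,\alpha\,(v_i - v_j)$), the classic
value-transfer mechanism. Because massed FG training drives $v_F$ toward
1 while novel items sit at $v_0$, this family *must* prefer F on the
first pairing of F with a novel item.

**Representational agent** (`representational_config()`). The agent
maintains a position estimate $\psi_i$ for each item (all initialised
near the list midpoint) and chooses the item whose noisy reading
$\psi_i + \varepsilon$, $\varepsilon \sim N(0, \sigma_\text{pos}^2)$,
appears earlier. Feedback reveals the pair's true order; any ordering
violation $\max(0, \psi_\text{lo} - \psi_\text{hi} + 1)$ is shrunk at
rate `learn_rate` after correct choices and `relearn_rate` after errors.
The cross-session "task representation" is a single parameter,
`massed_prior` $m$: at the phase 1 → 2 boundary the items seen during the
massed block are re-anchored toward the late end of the list,
$\psi \leftarrow (1 - m)\psi + m(n - 0.5)$. This one mechanism produces
all three signatures of the experienced-animal profile at once — the
massed items are ordered *after* novel items (above-chance first-xF
accuracy), the pair's learned separation is compressed (the abrupt
step-down in FG accuracy at the boundary), and pairings with the
never-rewarded item remain easy. Applying the prior at the boundary
rather than at initialisation reflects what the prior is: knowledge about
how *massed-phase* stimuli relate to stimuli *introduced later*, which
has no behavioural consequence until later stimuli appear. With $m = 0$
and fast relearning the same machinery yields the task-naive profile: a
transient preference for F on early xF pairings, reversed within a few
error-driven updates.

Species defaults (`default_agent_config()`) differ only in update rates
and the prior: monkey-like agents use `learn_rate = 0.04`,
`relearn_rate = 0.08`, `massed_prior = 0.8`; human-like agents
`learn_rate = 0.3`, `relearn_rate = 0.8`, `massed_prior = 0` — roughly
the ten-fold learning-speed gap the analyses should resolve. Both use
`position_noise = 0.5` rank units, which puts asymptotic adjacent-pair
accuracy near $\Phi(1/(0.5\sqrt 2)) \approx 0.92$ and end-of-massed-block
FG accuracy near 0.9.

**Reaction times** are log-normal (`rt_config()`):
$\log \text{RT} \sim N(\mu_0 + \beta_d\,\text{distance} +
\beta_t\,\text{trial}, \sigma^2)$. Species defaults reproduce the two
observed regimes: fast oculomotor responses with median
$e^{-1.35} \approx 0.26$ s, flat in trial and distance (a floor), versus
slower mouse responses with median $e^{0.5} \approx 1.65$ s, a mild
distance speed-up ($\beta_d = -0.03$) and a steady practice trend
($\beta_t = -5\times10^{-4}$ per trial, linear on the log scale — no
asymptote parameter). Residual $\sigma = 0.25$ is a typical log-RT
spread.

**What the generators do not emulate.** Motivation lapses, session-level
drift, RT–accuracy coupling (no speed–accuracy trade-off), stimulus
identity and salience, and any between-session learning beyond the massed
prior. Passing recovery tests on these cohorts therefore demonstrates
that the estimators detect the structures they target at realistic sample
sizes — not that real monkeys or humans obey the agents' update rules.

```{r cohort}
prof <- species_profile("monkey", sessions_per_subject = 5)
records <- generate_cohort(prof, default_agent_config("monkey"),
                           rt_config(), n_subjects = 2, seed = 1)
nrow(records)
```

## Gaussian-process analysis

All estimands are smooth functions of trial index (and, for the joint
surface, of distance and joint rank). They are estimated with GP
regression under a squared-exponential kernel with one automatic-relevance
lengthscale per input,
$k(x, x') = \sigma_f^2 \exp\{-\tfrac12 \sum_d (x_d - x_d')^2/\ell_d^2\}$.
The kernel choice is a package design decision: it encodes only
smoothness, is differentiable (needed for learning rates), and matches
the curve shapes these experiments produce.

* **Accuracy.** Correct/incorrect outcomes are aggregated across sessions
  into binomial counts per unique input, and the latent function $f$ (the
  log-odds of a correct choice; prior mean 0 = chance in a two-choice
  task) gets a binomial likelihood through the logistic link. The
  non-Gaussian posterior is handled by the Laplace approximation: Newton
  iteration to the posterior mode (tolerance $10^{-8}$ on the maximum
  latent change, at most 100 iterations, failure raised as an error with
  diagnostics), Gaussian curvature at the mode, and the standard
  approximate marginal likelihood. Aggregation is also the package's
  answer to GP cubic cost: a phase has at most 760 unique trial indices
  regardless of session count, so exact $O(n^3)$ inference is always
  feasible and no sparse approximation is needed.
* **Reaction times.** Log RTs are averaged per trial index and fitted
  exactly with a Gaussian likelihood whose per-index noise variance is
  `noise_variance / n_averaged`; the prior mean is the weighted sample
  mean.
* **Intervals.** 80% and 99% credible intervals are latent Gaussian
  quantiles mapped through the link. This guarantees probabilities in
  [0, 1] and strict nesting of the 80% inside the 99% interval. The
  binomial response-scale *mean* is the averaged predictive probability
  $E[\operatorname{logit}^{-1}(f_*)]$, computed by 20-point
  Gauss–Hermite quadrature, which is what an exact-integration oracle
  also computes.
* **Learning rates.** The derivative of a GP is jointly Gaussian with the
  process, so the posterior of $f'(x_*)$ follows from the
  cross-covariances $\partial k/\partial x_*$; `gp_derivative()` reports
  it in log-odds per trial. `learning_rates()` evaluates it at a phase's
  first trial index for every pair, sorted by distance then joint rank.
* **Hyperparameters.** `gp_optimize()` maximises the (approximate) log
  marginal likelihood over log-transformed parameters with L-BFGS-B from
  multiple deterministic starts; the initial value is always a candidate,
  so the result is never worse than the start. Lengthscales are bounded
  below by the input spacing — below it they are unidentifiable and the
  optimiser can otherwise wander into a white-noise-equivalent ridge —
  and above by ten times the input span. A small diagonal jitter
  ($10^{-6}$ by default) keeps Cholesky factorisations stable; genuinely
  singular systems surface as errors rather than being absorbed.

Two estimators intentionally do not use a GP. The phase-transition
profile (`transition_profile()`) indexes trials by *order of appearance*
within phase 2 (1st–6th instance of FG, of any xF pair, of any xG pair,
after the last four massed-block FG trials). Presentation index is a
short ordinal axis, so pooled counts are summarised by a Beta-binomial
posterior under a uniform Beta(1, 1) prior with equal-tailed quantile
intervals. And `effect_stats()` reduces a fitted surface to two scalars —
the Spearman correlation of the per-pair estimates with distance, and the
terminal contrast (mean over pairs containing A or G minus the rest) —
with Monte-Carlo intervals from draws of the joint latent posterior at
the 21 pair coordinates; a constant profile is reported as trend 0.

The joint surface (`joint_surface()`) fits one GP over (trial, distance,
joint rank), binning the trial axis (20-trial bins by default) before
aggregation so the input set stays small, and evaluates it at the first
phase-3 trial on a (distance, joint rank) grid. Grid resolution (0.1
default) is purely a reporting choice. Cells at coordinates no real pair
occupies — including all parity-violating combinations, since distance
and joint rank are sums/differences of the same two ranks — are flagged
`interpolated` and never reported as pairs. Accuracy and log-RT surfaces
are independent fits; nothing in the data ties their hyperparameters
together.

```{r fit}
curve <- accuracy_timeseries(records, "FG", phase = 1, optimize = FALSE)
summary(attr(curve, "fit"))
round(head(curve[, c("trial_index", "mean", "lo99", "hi99")], 3), 3)
```

## Numerical and validation choices

Edge behaviour matters for learning rates: at a phase's first trial the
derivative posterior is partially shrunk toward the prior because data
exist on one side only. The shrinkage is roughly multiplicative at a
common smoothing scale, so *comparisons* of learning rates across pairs
or cohorts are made with one shared lengthscale (the phase span) rather
than per-series optimised ones; the package's validation suite does this
when checking that a built-in ten-fold speed difference is recovered
within two-fold and that built-in distance effects in accuracy and rate
are recovered with Spearman correlations above 0.8.

The validation suite (and the bundled `scripts/acceptance.R`) runs at
problem sizes chosen to make its Monte-Carlo checks decisive while
staying desk-sized: slope-recovery coverage uses a logit-linear curve
(intercept −1, slope 0.02 per trial) over 300 trials × 50 sessions with
100 replicates, sharing marginal-likelihood-tuned hyperparameters across
replicates of the same generating process; the agent-separation check
uses 3 subjects × 20 sessions per family; the naive-reversal check uses
33 single-session subjects; distance-effect recovery uses 30
single-session subjects with accuracy
$\operatorname{logit}^{-1}\{-0.8 + 0.35 d + 0.004\,d\,(t - t_0)\}$ in
phase 3. Oracles are independent by construction: dense closed-form
linear algebra for the Gaussian path, lattice integration of the exact
posterior for the Laplace path on one- to three-point problems, central
finite differences for the derivative operator, and kernlab as an
external cross-check of the Gaussian fit.

## Known limitations

* The Laplace approximation understates skew in small-count,
  extreme-probability regimes; its error against exact integration is
  below 0.01 in the validated settings and shrinks as counts grow, but
  single-session analyses at ceiling should be read with care.
* Pooling across subjects is the default (species-level curves); fitting
  per subject is possible by subsetting records, but no hierarchical
  model links subjects.
* The derivative estimand is the slope of the *latent* log-odds
  function; near ceiling, large latent slopes correspond to tiny changes
  in probability.
* Agents are caricatures: supported claims are about what the analysis
  pipeline can detect, not about mechanism in real subjects.
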