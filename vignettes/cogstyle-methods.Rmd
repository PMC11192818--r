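---
title: "Models and methods behind cogstyle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cogstyle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogstyle)
```

cogstyle analyzes attempt-level logs from 2D physical problem-solving
games: a participant places one of three tools at an `(x, y)` position in a
600×600 px scene, physics runs, and the level ends on success or at a 60 s
bound. This vignette explains the statistical machinery, the choices made
where the design was genuinely open, and what the validation on synthetic
data does and does not establish.

## The data model

Four tables form a dataset: participant profiles (age group, limb group,
age in years), attempt records (tool, position, seconds since level
start), per-play outcomes (solved flag, end time), and motor pre-test
trials (ten per participant, five at each of two target distances).
Validation enforces the structural invariants — coordinates inside the
play area, strictly increasing timestamps and attempt indices within a
play, solved plays non-empty, constant group labels, exactly 5+5 motor
trials — so that every downstream stage can assume well-formed input.
Timestamps are stored in seconds relative to level start; files carrying
milliseconds are converted on read. Coordinates use the screen convention
(origin top-left, y down), which no analysis depends on.

## Performance metrics

Per play: whether it was solved; the attempt count; time to solution (the
timestamp of the solving attempt, which is always the last one); time to
first attempt; and the mean gap between consecutive attempts, equal to
`(t_last − t_first)/(n − 1)`. The gap preceding the solving attempt is
included — it is thinking time spent before the solution. Per participant,
metrics other than solution rate are averaged over solved plays by default
(`solved_only = TRUE`): process measures on failed plays mix problem
solving with frustration and perseverance, so the package conditions on
success and exposes the flag for robustness checks. A played level with no
recorded attempts counts as unsolved in the solution-rate denominator,
since the time bound guarantees exposure.

## Attempt types: DP Gaussian mixture with collapsed Gibbs

Attempt types are data-defined clusters of placements. The model is a
Dirichlet-process mixture: a Chinese-restaurant-process partition prior
with concentration `alpha`, and within each cluster bivariate Gaussian
placements under a conjugate normal-inverse-Wishart (NIW) prior. Because
the NIW is conjugate, clusters can be integrated out analytically and
assignments sampled by collapsed Gibbs: point *i* joins existing cluster
*k* with weight `n_k^(−i)` times the cluster's bivariate Student-t
posterior predictive (NIW updated without *i*), or a new cluster with
weight `alpha` times the prior predictive.

Defaults, all data-scaled rather than fixed in pixels: `alpha = 1`;
`mu0` = the empirical mean; `psi0` = diag(empirical variances) × (`nu0` −
3) with `nu0 = 4`, so the prior covariance mean matches the data scale;
`kappa0 = 0.1` keeps the prior mean weak; 500 sweeps with 250 burn-in.
Clustering uses raw pixel coordinates — standardization is unnecessary
precisely because the hyperparameters adapt to the data scale.

Numerical choices that matter:

- **Point estimate.** The returned partition is the retained sweep with
  maximal joint log-probability (CRP prior plus NIW block marginals), not
  the last sweep: it is reproducible, comparable across runs, and directly
  checkable against exact enumeration.
- **Initialization.** Chains start from all-singleton partitions. Under
  single-point Gibbs moves, merging is easy and splitting is hard, so
  singleton starts avoid under-segmented local modes (an all-in-one start
  demonstrably sticks at a merged partition whose log-joint is ~100 units
  worse on two-blob data).
- **Responsibilities.** "The probability that an attempt belongs to each
  cluster" is its size-weighted posterior-predictive membership under the
  returned partition, renormalized over existing clusters only: downstream
  switch logic needs a fixed K, so no phantom new-cluster column is kept.
  Labels are the row-wise argmax, ties to the lowest index.
- **Oracle.** `partition_posterior_bruteforce()` enumerates all set
  partitions (n ≤ 8; Bell(8) = 4140) and scores them in closed form. The
  test suite requires the Gibbs partition frequencies to sit within total
  variation 0.05 of this exact posterior on n = 5 fixtures across three
  seeds (measured ≈ 0.025 at the suite's sweep budget), and the CRP
  simulation to match the expected-cluster-count formula
  `sum(alpha / (alpha + i − 1))`.

Split-merge moves and inference on `alpha` are out of scope; with the
per-level data sizes involved (tens to a few hundred points), plain
collapsed Gibbs mixes adequately.

## Leave-one-out group classification

For each participant and level, the first attempt is scored by
`s = p_own / (p_own + p_other)`, where each `p` is a group density over
(tool, position): a Laplace-smoothed categorical over the level's three
tools (pseudo-count 1) times a Gaussian product-kernel density with
per-dimension plug-in bandwidth `sd_d · m^(−1/6)`, floored at 1e−12.
Tool and position enter as a product — the simplest estimator consistent
with forming distributions over both — and only first attempts enter
training and query, since the question is whether groups *start* their
solution search differently. The queried participant is excluded from both
densities (a no-op for the other group, which never contains them); this
makes scoring an attempt against (own, other) and (other, own) exactly
complementary. Levels with fewer than two contributing participants after
exclusion are skipped and reported, never silently dropped. Per-participant
mean scores are tested against chance (0.5) with a two-sided one-sample
t-test across participants, so the degrees of freedom are the number of
scored participants minus one.

A calibration caveat, established by simulation during development:
because every participant's scores share the same training densities, the
per-participant scores are positively correlated, and the one-sample
t-test is anticonservative — under exchangeable groups it rejected at
α = 0.05 in roughly 20% of replicates at two scales, even though the mean
score stayed unbiased at 0.50. The *mean score* is therefore the reliable
chance-level diagnostic (the suite verifies 0.50 ± 0.03 on exchangeable
groups and > 0.9 on 300-px-separated groups); the t statistic should be
read as descriptive, and small p-values near chance treated with caution.

## Switch rates

For switching, attempts are labeled by per-(level, population) DP-mixture
models fit to the `(x, y)` positions of *all* attempts (tool identity
ignored). The default population scheme fits separate models per age ×
limb cell; a pooled scheme is available through `group_by` for analyses
that form clusters from combined populations. A switch is a change of
highest-likelihood cluster label between consecutive attempts of a play;
plays with one attempt contribute no transitions. Group comparisons use a
mixed logistic regression of the transition-level switch indicator on
group with random intercepts for participant and level, tested by a 1-df
likelihood-ratio chi-square; a pooled 2×2 chi-square is available as a
fallback, and all-identical outcomes are reported as separation with no
test.

## Group-comparison models

Game metrics are modeled at the participant × level grain with random
intercepts for participant and level. Fixed effects are limb group, age
group, and (for its test) their interaction; covariates are age in years
and median motor reaction time, each centered at its own age group's mean
and given separate child/adult slopes, so the covariate columns are
orthogonal to the age-group indicator and group effects are evaluated at
group-typical covariate values. Links: identity for the timing metrics,
log for attempt counts, logit for solving. Attempt counts are modeled as
Gaussian on log counts — matching the multiplicative, symmetric-CI style
of the reported ratio — with a Poisson option behind a flag; the limb
effect is reported as `exp(coef)` with its CI. Tests are likelihood-ratio
chi-squares from maximum-likelihood nested refits (Wald CIs are also
in the coefficient table); the motor pre-test uses ordinary linear models
with nested-model F tests. Boundary (singular) fits — a variance component
estimated at exactly zero — are legitimate estimates and are not flagged
as non-convergence; real optimizer failures set `converged = FALSE` on the
result rather than raising. Time-between-attempts models use one row per
participant × level (the play's mean gap), matching the random-intercept
structure.

## The synthetic-study generator

The generator exists so that every stage has an input with known ground
truth. It emulates a four-cell study (child/adult × LD/NLD, defaults 25,
45, 35, 40 participants — the published cell sizes) playing 14 levels:

- **Placements.** Each level has K = 3 Gaussian attempt-type clusters
  (sd 40 px) at centers drawn once from a structural seed; the attempt-type
  sequence is a first-order Markov chain (initial state from the group's
  mixture weights; with probability `switch_p` — 0.39 children, 0.33
  adults — it moves to a different cluster by renormalized weights).
  Placements are truncated to the play area by resampling, with clipping
  after 100 draws. Tools follow per-cluster categoricals.
- **Group structure.** Mixture weights vary by *age* group only; limb
  groups share all placement and tool distributions, so limb contrasts of
  placements are exchangeable by construction — this is what makes the
  chance-level classification check meaningful. Age-group weight
  differences stand in for the real developmental differences in first
  attempts.
- **Latencies.** First-attempt times and gaps are lognormal (defaults
  meanlog 1.3/2.0, sdlog 0.5 — means ≈ 4.2 s and ≈ 8.4 s) plus additive LD
  offsets of 3.79 s and 2.80 s and a per-participant intercept
  (sd 1 s, a free parameter: the study reports no variance decomposition
  for latencies). Additive offsets on lognormals keep times positive while
  making group mean differences equal the configured effects exactly, so
  recovery has a closed-form target.
- **Solving.** Each attempt solves the level with a per-attempt
  probability (memoryless geometric process): 0.235 for adults and 0.185
  for children on the NLD scale — calibrated once so simulated NLD
  solution rates land near the published 85% (adults) and 77% (children)
  given the latency defaults and the 60 s bound — and divided by the
  attempt ratio 0.839 for LD, so expected LD attempts are 83.9% of NLD.
  Plays truncate at the bound; first-attempt latencies are resampled to
  fall inside it, so every play has at least one attempt.
- **Motor pre-test.** Trial values are a participant-level center (group
  median ± between-participant noise; LD RT offset −0.356 s) times
  lognormal trial noise, so the distribution's median equals the center
  and the ten-trial median is an unbiased estimate of it.
- **Reproducibility.** All structural draws come from `structure_seed`;
  participant-level randomness is split hierarchically by (participant,
  level) substreams, so enlarging the study never perturbs existing
  participants.

What the generator does *not* emulate: no physics (placements are density
samples, not simulated tool outcomes); no level geometry, so structured
error types and geometry-based switch measures are out of reach; no child
latency offsets (the configuration surface carries only limb offsets, so
child/adult timing contrasts in synthetic data are near null); no
age-in-years trends within groups for motor skill; and a mild limb effect
on solution rates is a side effect of LD taking fewer, better attempts
inside a fixed time budget. Passing recovery tests on this generator
establishes that the estimators are consistent and approximately unbiased
under the assumed data-generating process — not that the assumptions hold
for any particular real dataset.

## Validation scales and results

The test suite runs every stage at sizes chosen to balance statistical
resolution against a default test run of a few minutes: Gibbs-vs-oracle at
n = 5 with 7000 retained sweeps × 3 seeds; chance-level classification at
40 participants per group × 14 levels × 5 replicate studies (the same
configuration the acceptance script reports, measured at 50.3% with
chance at 50%); switch-rate recovery at > 2000 transitions (binomial
tolerance ± 0.03); effect recovery at 60 participants per cell × 5 seeds
(first-attempt offset recovered to 3.74 s on average against 3.79
configured, gap to within 0.2 s of 2.80 after right-truncation at the
time bound, attempt ratio within [0.75, 0.93]); motor RT offset over 20
replicate studies; and type-I calibration of the motor F-test over 200
null replicates. The mean-gap estimate is mildly attenuated by the 60 s
bound (long gaps are censored) — visible in recovery means around 2.6 s —
which is a property of the bounded design, not of the estimator.

## Known limitations

- The classifier's t-test is anticonservative under the null (see above);
  use the mean score against chance, or a permutation scheme outside this
  package, for confirmatory claims.
- The collapsed Gibbs sampler uses single-point moves only; grossly
  multimodal partition posteriors at large n may mix slowly, which is why
  the point estimate is the max-log-joint sweep rather than a posterior
  summary.
- Attempt counts as Gaussian-on-log assumes multiplicative effects and
  roughly lognormal counts; the Poisson flag exists for count-like
  robustness checks.
- The archive adapter is best-effort column mapping; layouts it cannot
  recognize fail loudly with the list of columns found.
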