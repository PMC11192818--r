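# cogstyle

Behavioral analysis of attempt-level logs from 2D physical problem-solving
games ("virtual tools" tasks), in which a participant repeatedly places one
of three tools in a 600×600 px scene until a physics goal is met or a 60 s
level bound runs out. The package targets studies that compare *cognitive
styles* across participant groups — for example children vs. adults, or
people with vs. without congenital limb differences — using only the log
footprint of play: who placed which tool where, and when.

## What it computes

From one attempt record per tool placement, the package derives:

- **Performance metrics** per (participant, level) play: solution rate,
  attempts to solution, time to solution, and the two thinking-time
  measures — time to first attempt and mean gap between consecutive
  attempts (`level_metrics()`, `aggregate_participant()`,
  `motor_summary()`).
- **Attempt types** — clusters of `(x, y)` placements found by a
  Dirichlet-process Gaussian mixture with a normal-inverse-Wishart base
  measure, sampled by collapsed Gibbs: an existing cluster attracts a point
  with weight `n_k` times its bivariate Student-t posterior predictive, a
  new cluster with weight `alpha` times the prior predictive. The reported
  state is the retained sweep maximizing the joint log-probability (CRP
  prior × cluster marginal likelihoods), and an exact enumeration oracle
  (`partition_posterior_bruteforce()`) verifies the sampler on small
  problems (`fit_dpmm()`, `map_labels()`, `label_sequences()`).
- **Group classification** of first attempts by leave-one-out relative
  likelihood `s = p_own / (p_own + p_other)`, where each `p` is a
  Laplace-smoothed tool categorical times a Gaussian product-kernel density
  over placements, built without the queried participant; `s > 0.5`
  classifies the attempt into its own group and 0.5 is chance
  (`loo_classify()`).
- **Switch rates** — the fraction of consecutive same-level attempts whose
  highest-likelihood cluster labels differ — compared across groups by a
  mixed logistic likelihood-ratio test (`switch_rate()`,
  `compare_switch_rates()`).
- **Group contrasts** via mixed-effects models with random intercepts for
  participants and levels, age and median motor reaction time as covariates
  centered within age group with separate child/adult slopes, and 1-df
  likelihood-ratio chi-squares for the limb, age and interaction terms
  (`fit_timing_model()`, `fit_attempts_model()`, `fit_solution_model()`,
  `fit_motor_lm()`).
- A **synthetic-study generator** (`generator_config()`,
  `generate_dataset()`) whose defaults (`default_paper_config()`) encode
  published group effects — LD first-attempt offset 3.79 s, gap offset
  2.80 s, attempt ratio 0.839, switch probabilities 0.39/0.33, motor
  medians 7.65/2.92 px and 3.04/1.91 s, LD motor-RT offset −0.356 s — so
  every stage can be validated by parameter recovery against known ground
  truth.

`run_pipeline()` chains all stages and writes `report.json` / `report.md`;
`read_attempt_log()` / `write_dataset()` round-trip the canonical CSV
schema, and `adapt_archive()` maps common column synonyms of externally
archived logs onto it.

## Worked example

```r
library(cogstyle)
cfg <- default_paper_config()
d <- generate_dataset(cfg, seed = 1)
d
#> <cogstyle_dataset>
#>   participants: 145 (child-LD: 25, child-NLD: 45, adult-LD: 35, adult-NLD: 40)
#>   plays: 2030 (1648 solved), attempts: 7015, levels: 14
#>   motor trials: 1450

fit_timing_model(d, "time_to_first")
#> <cogstyle_fit> response: time_to_first (n = 1648)
#>             term estimate      se    ci_lo ci_hi
#> 1    (Intercept)  3.83144 0.16667  3.50476 4.158
#> 2   limb_groupLD  3.79322 0.20971  3.38219 4.204
#> ...
#> tests:
#>          term   chisq df        p
#> 1  limb_group 171.781  1 3.02e-39
#> 2   age_group   1.177  1 2.78e-01
#> 3 interaction   0.119  1 7.31e-01

loo_classify(d, grouping = "age_group")
#> <cogstyle_classification> contrast: age_group
#>   mean score 0.566 over 145 participants (chance = 0.5)
#>   t(144) = 14.74, p = 1.52e-30
```

The limb-difference coefficient (3.79 s, CI [3.38, 4.20]) recovers the
generator's configured first-attempt offset; the age-group classification
sits above chance because the generator gives children and adults different
attempt-type mixture weights, while the limb groups — which share placement
distributions by construction — classify at chance.

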