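# fetchr

Statistics for forced-choice **fetch-task** experiments in comparative
cognition: a subject (typically a label-trained dog) hears a novel word and
must retrieve the matching object from a small array. The package is for
researchers analysing trial-level records of such experiments — and for
anyone who wants to stress-test the statistics themselves, since it ships
agent-based simulators of the three canonical designs alongside the tests.

## The statistics

**Monte-Carlo chance null for the mean-attempts statistic.** When a design
allows a second retrieval attempt, the informative statistic is the mean
attempt index $\bar a = \tfrac1n \sum_i a_i$, where $a_i$ is the draw at
which the target was obtained on trial $i$. Under chance, a searcher draws
objects without replacement until it hits the target, so $a_i$ is uniform
on $\{1,\dots,s\}$ for $s$ objects. `build_null()` simulates the null
distribution of $\bar A$ (default 10,000 runs) and `mc_p()` returns
$\Pr(\bar A \le \bar a)$ with ties counted as extreme; `exact_p()` is the
enumeration twin computed by convolving the uniform distribution. Trials
where the subject never obtained the target are scored as attempt index
$s$ by default (see `observed_mean_attempts()` for the alternatives).

**Exact binomial tests with explicit tail conventions.** `binom_pvalue()`
computes exact tails at an arbitrary chance level, including the `smaller`
one-tailed convention and the tail-doubling two-sided convention
$p = \min(1,\, 2\min(P(X\le k), P(X\ge k)))$ used throughout this
literature. The 3-object analyses use chance level 0.33 (the reporting
convention; not 1/3 — the two differ visibly at $n = 24$).

**Pearson chi-square for 2×2 tables** without continuity correction
(`chisq2x2()`), for pair-asymmetry contrasts.

**Agent models** (`agent_spec()`): `random`, `knower` (accuracy θ on the
true referent), `associative` (θ on whatever was visible during naming),
`enhancement` (extra weight on the attended location) and `learner`
(logistic accuracy ramp). `simulate_exp1/2/3()` generate full synthetic
sessions under counterbalanced schedules; `estimate_type1()` and
`power_curve()` calibrate the tests against them.

## Worked example

The package bundles `study_trials()`, a trial-level reconstruction of a
published four-dog study whose aggregates match every printed count.
Analysing one subject's 3-object run:

```r
library(fetchr)

rep1 <- analyze_exp1(study_trials("Paddy", "exp1"), n_sims = 10000, seed = 101)
rep1
#> Subject Paddy, exp1 (run 1)
#>   mean_attempts_mc             p = 0.0079  [lower]  (observed mean attempts; failure policy assign_set_size)
#>   first_attempt_binomial       p = 0.0631  [smaller]
#>   conventions:
#>     chance_level = 0.33
#>     binomial_tail = smaller
#>     failure_policy = assign_set_size
#>     null_kind = monte_carlo
#>     n_sims = 10000
#>     seed = 101
```

Reading the output: over 24 trials this subject retrieved the target in 22
(12 on the first attempt). The Monte-Carlo test asks how often a chance
searcher would average as few attempts: about 0.8% of simulated runs — the
subject beat chance on the two-attempt statistic. The first-attempt
binomial at chance 0.33 is only marginal (p = 0.063), which is why the
two-attempt statistic exists. Every report carries the conventions block
that fully determines its numbers.

Everything returns tibbles, so whole-study summaries are one pipe:

```r
library(dplyr)
analyze_study(exact = TRUE) |>
  filter(label == "first_attempt_binomial") |>
  select(subject_id, run, k, n, p_value)
```

and simulated data drop into the same pipeline:

```r
simulate_exp3(agent_spec("associative", theta = 1), seed = 1) |>
  analyze_exp3() |>
  tidy()
```

A θ = 1 associative agent scores 14/14 when the target was visible during
naming and 0/14 when it was occluded — exactly at chance overall, which is
the dissociation the barrier design exploits.

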