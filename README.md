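# birdquiz

Adaptive birdsong-identification quiz training, simulated end to end.

## The problem

Citizen-science acoustic monitoring of birds depends on volunteers who can
identify species from recorded songs, and quiz-style online training is a
cheap way to build that skill. An *adaptive* quiz tracks a per-species
proficiency counter for each trainee: species learned to mastery mostly
leave the question pool (returning occasionally for review), and the
incorrect alternatives get harder — including expert-designated
similar-sounding species — as proficiency on the correct species grows.
Evaluating such a training policy on humans is slow and expensive;
`birdquiz` lets you exercise it on simulated learners instead, so that
scheduling policies, review mechanisms and metrics can be developed and
compared before anyone runs a human trial.

The package provides, for R users working on training-policy design or
spaced-repetition research:

* a **species catalog** of 26 common Japanese birds with four confusable
  pairs (similarity levels E = easier, D = more difficult), plus a validated
  CSV format for custom catalogs;
* the **adaptive quiz engine** (five choices: one correct, four
  distracters) and a uniformly random **baseline** engine;
* a **forgetting-curve learner**: recall decays as `2^(-Δt/h)` per species,
  and each exposure multiplies the half-life `h` by
  `1 + (α−1)(1−r)^β` — repetition and spacing benefits in one rule — with
  guessing confused toward similar-sounding species (weight γ);
* the **experiment protocol**: pretest (day 0), 50-question training days
  (1, 2, 4, 5), midterm (day 3), posttest (day 6), delayed test (day 20),
  for two-arm cohorts with per-participant reproducible RNG streams;
* **metrics** from JSON-lines event logs: test scores, per-species question
  counts, inverse lag times (1/days), median question intervals (in
  question units), accuracies with binomial SEs, confusion matrices, and a
  permutation test for arm contrasts;
* a **command-line interface** (`simulate`, `metrics`, `quiz`).

The core scheduling rule is the review probability

```
P = p · w·N_u / (N_u + w·N_m),        p = 0.25, w = 0.5
```

with `N_u`/`N_m` the unmastered/mastered species counts: the chance that a
training item reviews an already-mastered species. Both this printed form
(under which review vanishes at full mastery) and a variant with `w·N_m` in
the numerator are implemented; see the vignette for why.

## Worked example

```r
library(birdquiz)
logs <- run_cohort(30, master_seed = 1)   # 30 participants per arm, ~5 s
summarize_scores(logs)
```

```
      arm    phase  n mean_score        se
 adaptive  pretest 30  0.9666667 0.1624761
 baseline  pretest 30  1.1333333 0.1776820
 adaptive  midterm 30  7.2666667 0.3773268
 baseline  midterm 30  7.5333333 0.3481753
 adaptive posttest 30 20.4666667 0.3579422
 baseline posttest 30 20.0000000 0.3619869
 adaptive  delayed 30  4.3666667 0.4193134
 baseline  delayed 30  5.4666667 0.3481753
```

Scores are correct answers out of 26. The cohort starts at chance (~1 of
26), learns across the four training days, and forgets much of it by the
delayed test two weeks later — the qualitative shape of a real training
curve. The two arms are statistically indistinguishable here because the
simulated learner benefits from both policies equally:

```r
a <- sapply(Filter(function(l) l$arm == "adaptive", logs), test_scores, "posttest")
b <- sapply(Filter(function(l) l$arm == "baseline", logs), test_scores, "posttest")
set.seed(1)
permutation_arm_test(a, b)
#> [1] 0.3958604
```

Per-participant, per-species training variables (the explanatory variables
used to analyse what drives test performance):

```r
head(species_metrics(logs[[1]]), 5)
```

```
 participant_id      arm species n_training_questions inverse_lag median_question_interval
              1 adaptive    Hyam                    7   1.0098928                     18.0
              1 adaptive    Cedi                    2   0.5026672                     12.0
              1 adaptive    Pamo                    4   1.0199833                     61.0
              1 adaptive    Coma                    9   1.0195589                     15.5
              1 adaptive    Gaca                    7   1.0191348                     27.0
```

E.g. Hyam (Brown-eared Bulbul) was the correct choice of 7 training
questions, last trained ~0.99 days before the posttest (inverse lag
1.01 /days), with a median of 18 questions between its occurrences.

From the shell:

```sh
BQ=$(Rscript -e 'cat(system.file("cli", "birdquiz", package = "birdquiz"))')
Rscript "$BQ" simulate --seed 1 --out out/           # logs + CSVs + summary
Rscript "$BQ" metrics  --in out/logs --out out/m2    # recompute from logs alone
Rscript "$BQ" quiz --mode adaptive                   # play it yourself
```

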