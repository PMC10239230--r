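---
title: "Adaptive birdsong quiz training: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive birdsong quiz training: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Citizen-science acoustic monitoring needs volunteers who can identify bird
species by ear. A practical way to train them is a five-choice quiz: play a
song, offer one correct species and four distracters, reveal the answer. An
*adaptive* version of such a quiz keeps a per-species proficiency counter for
each trainee and uses it in two ways: species that have been learned
("mastered") largely leave the question pool, and the distracters get harder
as proficiency on the correct species grows. `birdquiz` implements that
engine, a control ("baseline") engine that draws everything uniformly at
random, a simulated trainee whose memory follows classic forgetting-curve
mechanisms, the full test/training experiment schedule, and the metrics used
to analyse the resulting event logs. No audio is involved anywhere: items
reference species identities only, which is all the scheduling algorithm ever
sees.

```{r}
library(birdquiz)
catalog <- builtin_catalog()
catalog
```

The bundled catalog holds 26 species of common Japanese birds with four
expert-designated confusable pairs (three at similarity level E, "easier",
one at level D, "more difficult"):

```{r}
similar_species(catalog, "Pami")   # Japanese Tit ~ Varied Tit (E)
similar_species(catalog, "Mogr")   # Japanese Wagtail ~ White Wagtail (D)
```

## The adaptive engine

Every species starts at proficiency level 0. A correct answer adds 1 to the
correct species; a wrong answer subtracts 1 from both the correct species and
the wrongly chosen distracter, floored at 0. A species is **mastered** once
its level exceeds 2 (threshold 3, configurable).

The correct choice of a training item is drawn uniformly from the unmastered
pool, except that with the **review probability**

$$P \;=\; p\,\frac{w\,N_u}{N_u + w\,N_m}$$

it is drawn from the mastered pool instead, where $N_u$ and $N_m$ count
unmastered and mastered species, $p = 0.25$ is the maximum review
probability and $w = 0.5$ the review weight. Note a property of this printed
formula: its numerator contains $N_u$, so review *vanishes* as mastery
spreads ($P \to 0$ when $N_u \to 0$), which is arguably the opposite of what
a review mechanism is for. Because the intent is ambiguous, both forms are
implemented behind `engine_config(review_numerator =)`: `"printed"` (the
default, for fidelity) and `"mastered_variant"`, which uses $w\,N_m$ in the
numerator and approaches $p$ as mastery spreads.

```{r}
review_probability(26, 0)   # everything unmastered: p * w
review_probability(13, 13)  # halfway
review_probability(0, 26)   # printed form: review vanishes at full mastery
```

Distracters depend on the proficiency level $L$ of the correct species, with
all proficiency ties broken uniformly at random:

| tier | composition of the 4 distracters |
|------|----------------------------------|
| $L = 0$ | the 4 highest-proficiency species |
| $L = 1$ | 2 highest + 2 lowest, the E-level similar species (if any) taking one low slot |
| $L \ge 2$ | all similar species of the correct choice (E before D), then lowest-proficiency fillers |

The tier table is this package's concretization of the qualitative design
rule "easy items get familiar distracters, hard items get confusable and
unfamiliar ones": the slot counts per tier are not uniquely pinned down by
the published description, so they are fixed here once and tested against an
exhaustive enumeration oracle. E-level similar species enter at $L = 1$ and
D-level ones only at $L \ge 2$ because E pairs are the easier
discrimination. The baseline engine ignores proficiency entirely and samples
the correct species and all distracters uniformly.

## The simulated learner

The learner holds a retention half-life $h_s$ (days) per species. Recall
probability decays exponentially since the last exposure:

$$r_s(t) = 2^{-\Delta t / h_s}, \qquad \Delta t = t - t^{\text{last}}_s,$$

and is 0 for a never-exposed species. Each training item ends with the
answer revealed, so every item is an exposure of its correct species
regardless of the answer given; an exposure at recall probability $r$
multiplies the half-life by

$$1 + (\alpha - 1)\,(1 - r)^{\beta},$$

with $r = 0$ on the first exposure. This is the simplest form exhibiting the
three mechanisms the design is built on: exponential forgetting, a
repetition benefit (every exposure grows $h$), and a spacing benefit (longer
gaps mean lower $r$ and hence a larger boost; back-to-back exposures
consolidate almost nothing). When recall fails, the learner guesses among
the presented choices with weight $\gamma$ on species whose song is similar
to the correct one and weight 1 elsewhere — the correct species stays in the
guess pool, so lucky hits occur at roughly chance rate.

Parameters, all exposed in `learner_config()`:

| parameter | default | unit | meaning |
|-----------|---------|------|---------|
| `initial_half_life` ($h_0$) | 0.02 | days | fragile fresh trace, ~30 min |
| `consolidation_gain` ($\alpha$) | 4 | — | max per-exposure half-life multiplier |
| `spacing_exponent` ($\beta$) | 0.5 | — | curvature of the spacing benefit |
| `similarity_confusion_weight` ($\gamma$) | 3 | — | guess weight on confusable species |
| `test_feedback` | `FALSE` | — | do tests update memory? |

`test_feedback = FALSE` mirrors a protocol in which test answers are
withheld until after the delayed test; whether merely *hearing* a test item
strengthens a human trainee's memory is unknowable from the published
account, so the conservative default is "no", switchable for sensitivity
analyses.

## The experiment protocol

`run_participant()` executes, on elapsed days (pretest = day 0):

```{r}
default_schedule()
```

Each training day asks 50 questions (200 total), timestamped evenly across a
0.02-day (~30 min) session. Tests present all 26 species once, in shuffled
order, with the whole catalog as the choice set. The calendar-day schedule
of the original experiment (tests on calendar days 1, 4, 7 and 21) maps to
elapsed days 0/3/6/20 used here, preserving the 14-day posttest-to-delayed
gap. One RNG stream per participant is seeded from
`(master_seed, participant_id)`, so runs are bit-reproducible and a
participant's pretest is identical across arms. Dropouts are not simulated;
cohorts are complete by construction.

```{r}
log <- run_participant("adaptive", participant_id = 1, master_seed = 1)
test_scores(log)
```

## Metrics

All metrics are computed from the serialized JSON-lines event logs alone:

* **Test score** — correct answers per 26-item test.
* **Training question count** — training items with the species as correct
  choice.
* **Inverse lag time** — 1 / (days between the species' last training
  appearance and a test). Never-trained species are *missing*, not zero:
  zero would fabricate an infinite lag.
* **Median question interval** — median gap between successive occurrences
  of the species as correct choice, in *question-index* units, not days.
  Day units would be bounded by the 6-day training window, while observed
  interval magnitudes (tens of questions) only make sense on the item axis.
* **Per-species accuracy** with the binomial standard error, and test
  **confusion matrices**.
* **`permutation_arm_test()`** — a two-sided Monte-Carlo permutation test
  for the arm contrast. It deliberately replaces the mixed-model machinery a
  full analysis of human data would use (GLMMs with random slopes, ordered
  logit, MANOVA variants); fitting such models is a consumer's job on the
  exported CSVs, not this package's.

```{r}
head(species_metrics(log), 8)
```

## What the simulator does and does not establish

The generator emulates: chance-level pretest performance, learning across
training days, recency-driven forgetting by the delayed test, spacing
effects, and similarity-driven confusion. A pinned 30+30 cohort at the
defaults reproduces the qualitative score curve (pretest < midterm <
posttest, delayed < posttest, pretest at chance) in both arms — this is
learning-by-construction, and a green test establishes only that the
machinery is wired correctly, not that the parameter values describe any
human population.

It does **not** emulate persistent per-species difficulty: apart from the
four confusable pairs, every species is equally learnable, whereas for
humans some songs are intrinsically harder to remember. This has a concrete
consequence. In the human experiment the adaptive arm showed a *negative*
correlation between per-species question count and posttest accuracy (hard
species attract questions and stay inaccurate). In this simulator two
opposite channels dominate instead: every question is an exposure, so
high-count species end with longer half-lives, and species mastered early
stop being asked and then decay until the posttest — "mastered but
forgotten". The measured rank correlation is therefore near zero to
mildly positive (about +0.1 to +0.4 across seeds at the defaults), and the
corresponding acceptance test is intentionally left failing rather than the
learner being re-tuned around it; reproducing it faithfully would require a
per-species learnability parameter, which is out of scope for this learner.

## Numerical and design choices

* Proficiency floors at zero; the wrongly selected distracter is
  decremented on review items too (one universal update rule).
* The unmastered pool is sampled uniformly, not lowest-level-first: the
  published behaviour at the all-zero start is explicitly random, and
  nothing pins down a stratified rule.
* `review_probability` is clamped to $[0,1]$ (reachable only under extreme
  configurations, not the defaults).
* Tie-breaking in distracter ranking uses a fresh uniform permutation per
  draw; the test suite enumerates all permutations to validate the induced
  distribution exactly.
* Zero-length training sessions are legal (all timestamps coincide);
  recall queries before a species' last exposure are an error, not a clamp.
* Catalog CSVs use one fixed dialect (7 fixed columns, `;`-separated
  multi-similar lists, empty string = none) rather than autodetection; the
  similarity relation must be symmetric with equal levels, which holds for
  all four bundled pairs. The data model allows several similar species per
  species even though the bundled catalog never has more than one.
* JSON-lines logs serialize doubles at 17 significant digits so that a
  write/read/recompute cycle is byte-identical.

## Known limitations

* No per-species learnability differences (see above) — the main gap
  between simulated and human cohorts.
* The learner is memoryless across species: confusing two species does not
  create a persistent association, only a biased guess at answer time.
* Test items share a single timestamp (the scheduled day); within-test
  timing is not modelled.
* Human-subject outcomes (attitudes, satisfaction, dropout, the published
  arm gaps in scores) are expressly out of scope and are not targets of any
  test in this package.
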