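---
title: "Chaos-embedded SPEA2 interval-rule mining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-embedded SPEA2 interval-rule mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(spea2rules)
```

## The problem and the model

The European cherry fruit fly lays its eggs preferentially in ripening
fruit, so the pomological profile of a cherry sample — colour, weight,
dimensions, firmness, pit weight, soluble solids, NaOH maturity,
acidity — carries information about the adult population pressure in
the orchard. The package models the three-level infestation class
(Low / Medium / High, defined from adult trap captures as 0–5, 6–10 and
more than 10 flies) as the consequent of **interval rules**: a rule is
a conjunction of closed intervals over a subset of the measured
features plus a target class, and a sample is asserted to belong to
that class when every condition holds.

Rule quality is inherently multi-objective. Accuracy
$(TP+TN)/(TP+TN+FP+FN)$, precision $TP/(TP+FP)$ and recall
$TP/(TP+FN)$ — computed one-vs-rest, with samples of the target class
as positives — pull in different directions: a narrow rule can be
perfectly precise yet miss most positives, a broad one the reverse.
Rather than scalarise, the package evolves a **Pareto front** of rules
with SPEA2 and leaves the final pick to the decision maker.

### Genome and decoding

A candidate rule is encoded as three vectors in $[0,1]$ of schema
length: inclusion scores, lower-bound scores and upper-bound scores.
Feature $i$ enters the rule iff its inclusion score exceeds the
threshold $\lambda$ (default 0.5, so on average half the features are
active in a random genome). Bound scores are decoded affinely onto the
feature's observed range. Three totality repairs keep the decode map
well defined:

* decoded lower above decoded upper → the bounds are swapped (not
  discarded: discarding would waste evaluations and bias the search
  toward narrow genomes);
* no feature active → the feature with the maximal inclusion score is
  forcibly activated, since a rule needs at least one condition;
* interval boundaries are **inclusive**. The rendered text uses `<` as
  a display convention, but matching is $\le$; on continuous data the
  distinction has measure zero.

Degenerate metric cases are defined as zero: a rule that never fires
has precision 0, a rule mined for an absent class has recall 0. Zero
is the correct value in a maximisation context — it penalises such
rules instead of silently propagating `NaN`.

### SPEA2 fitness and archive

Each generation pools the population with the external archive and
assigns: strength $S(i)$ (members $i$ dominates), raw fitness
$R(i) = \sum_{j \succ i} S(j)$ (0 exactly for non-dominated members)
and density $D(i) = 1/(\sigma_i^k + 2)$ with $\sigma_i^k$ the Euclidean
distance in objective space to the $k$-th nearest other member. The
$+2$ bounds $D \le 1/2 < 1$, so the selection rule "fitness below 1
enters the archive" admits exactly the non-dominated set. The
neighbour index defaults to $k = \lfloor\sqrt{N + \bar N}\rceil$, the
usual heuristic for a pool of population size $N$ plus archive size
$\bar N$. An under-full archive is topped up with dominated members in
ascending fitness; an over-full one is truncated by repeatedly removing
the member with the smallest nearest-neighbour distance, ties resolved
by the second-, third-, … nearest distances and finally by lowest
index. Mating is binary tournament on fitness from the archive only,
and offspring replace the population wholesale.

### Chaotic initialisation and mutation

Randomness enters the genome through the **tent map**
$x_{n+1} = \delta x_n$ for $x_n < 1/2$, $\delta(1-x_n)$ otherwise, at
the fully chaotic control value $\delta = 2$ where the invariant
density is uniform on $(0,1)$. One continuous stream per run fills the
initial population row-major (individual 1 takes the first $3p$
iterates for $p$ features, and so on) and then feeds mutation, which
**replaces** each gene with the stream's next value with probability
$p_m$ — value replacement, not perturbation, is the reading under which
mutation is genuinely chaotic. All other randomness (tournament draws,
crossover masks, mutation masks) uses R's seeded PRNG, so a run is
fully determined by the pair (chaos seed, PRNG seed).

A numerical subtlety motivates the **degeneracy guard**. Both tent
branches are exact in binary floating point ($2x$ is an exponent shift;
$1-x$ is exact for $x \in [\frac12, 1]$ by the Sterbenz lemma), so
every double-precision orbit drains its mantissa and collapses through
$0.5 \mapsto 1.0 \mapsto 0$ within about 50 steps. Re-seeding with a
fixed constant would make the guarded stream *periodic* with that
period — enough to keep orbits in $(0,1)$ but disastrous for mutation,
which would then cycle over ~50 distinct values. The guard therefore
replaces any raw iterate outside $(\varepsilon, 1-\varepsilon)$,
$\varepsilon = 10^{-9}$, with $\mathrm{frac}(x_{raw} + n\,\phi)$,
$\phi = 0.6180339887$, where $n$ is the iterate's index in its stream:
the guard events form a golden-ratio Weyl sequence, equidistributed and
never repeating, so the stream is aperiodic with near-uniform long-run
density (empirical mean 0.492 over $10^4$ iterates; ~79% distinct
values).

### Crossover granularity

Uniform crossover operates on whole `(incl, lo, hi)` triples: for each
feature index, the triple is swapped between offspring with probability
1/2 (given the per-pair crossover probability $p_c$ fired). Keeping a
feature's three genes together preserves the coherence of its decoded
interval; the cost — lower and upper bounds of one feature cannot
recombine from different parents — is borne by mutation, which the
aperiodic chaotic stream makes effective. Genes are enumerated in the
order `c(incl, lo, hi)` when the mutation stream is consumed.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pop_size` | 20 | population size $N$ |
| `archive_size` | 20 | archive capacity $\bar N$ |
| `generations` | 100 | fixed run length $T$ (no early stopping) |
| `p_c` | 0.8 | per-pair crossover probability |
| `p_m` | 0.1 | per-gene mutation probability |
| `lambda` | 0.5 | inclusion threshold of the genome decode |
| `knn_k` | $\lfloor\sqrt{N+\bar N}\rceil$ | density neighbour index |
| `chaos_seed` | 0.7 | tent stream seed in (0,1) |
| `prng_seed` | 1 | seed of all non-chaotic randomness |

Population/archive 20, $\lambda$ 0.5, $p_c$ 0.8 and $p_m$ 0.1 mirror
the field survey's experimental protocol, as do the 70/30 stratified
split and the 10 independent runs per class in `run_experiment()`.
The run length was not part of that protocol; 100 generations is this
package's default, at which the planted-rule recovery below saturates.

Two protocol ambiguities were decided as follows. A trap count of
exactly 10 — claimed by both the Medium ("6–10") and High ("10 or
more") definitions — is labelled **Medium** (High is strictly greater
than 10); the thresholds are arguments of `label_from_trap_count()`.
Per-class training sizes use round-half-up of
`train_fraction × class_count` independently per class with no global
correction, which preserves stratification exactly.

## What the synthetic generator does and does not emulate

`generate_dataset()` reproduces the survey's *composition*: 381
samples, 204/101/76 per class, ten features clamped to the published
ranges, and per-class trap counts consistent with the labels (High
counts are drawn from 11–30; the survey only bounds them below). Class
structure is injected by displacing each class's feature distribution
along its range: values are drawn from a normal centred at
`min + (0.5 + shift_c) × range` with `shift_c` = −`class_shift`/2, 0,
+`class_shift`/2 for L, M, H, standard deviation range/6, then clamped.
The default `class_shift = 0.25` yields class overlap that produces
per-class test accuracies in the 0.7–0.85 range — comparable in
difficulty to the field data; `class_shift = 0` is a negative control
under which the classes are statistically indistinguishable
(two-sample Kolmogorov–Smirnov $p$ well above 0.01 per feature) and any
apparent skill is overfitting.

What it does **not** emulate: the real measurements' covariance
structure (features are generated independently within class; real
fruit weight and width are strongly correlated), multimodality across
ripening stages, orchard-level clustering, and any genuine biological
relation between traits and infestation. Passing recovery tests on
these data therefore show the *search machinery* works — they say
nothing about classification skill on real orchards.

`generate_planted_rule_dataset()` provides ground truth: features are
uniform over the schema box, a fixed fraction of samples
(default 0.4) is forced inside a planted rule's intervals and the rest
rejection-sampled outside, labels follow rule membership and are then
flipped with a noise probability. The fixed harness rule is
single-condition — `Weight` in the central 40% of its range, class H —
chosen because a one-interval ground truth makes "did the search find
it" unambiguous: with 5% label noise the planted rule's own training
accuracy is ≈0.95, and a recovered rule needs total bound error below
≈0.05 of the range to reach the 0.90 bar used in the tests.

## Problem sizes used by the test suite

The archive-invariant checks run 50 full evolutionary runs at 15
generations on 80-sample datasets; the recovery experiment runs the
full protocol (population/archive 20, 100 generations, 500 samples,
noise 0.05) over 10 seeds; fitness assignment is verified against a
brute-force $O(n^2)$ oracle on 200 random pools of up to 60
individuals; chaotic-stream containment is checked over $10^6$ guarded
iterates (1000 seeds × 1000 steps). These sizes were chosen to
exercise every code path at desk scale while keeping the suite around
two minutes.

## Known limitations

* Antecedents are conjunctions of closed intervals only — no
  disjunctions, negations or categorical tests.
* One-vs-rest: each class is mined separately; the per-class rule sets
  are not calibrated against each other, and a sample can match rules
  of several classes (or none).
* The truncation operator is $O(\bar N^3)$ per overflow event; fine at
  archive size 20, noticeable if the archive is scaled by orders of
  magnitude.
* Objectives are evaluated on the full training split each generation;
  no fitness caching or subsampling is attempted.
* Printed rule text rounds bounds to three decimals; `parse_rule_text()`
  recovers a rule only to that precision. Exports meant for machine
  consumption (`export_pareto_front()`, `write_samples_csv()`) keep
  full double precision.
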