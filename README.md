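# spea2rules

Multi-objective evolutionary mining of interpretable if–then interval
rules for classifying cherry-fruit-fly (*Rhagoletis cerasi*) infestation
levels — Low / Medium / High, derived from adult trap captures — from
numeric pomological measurements (fruit colour, weight, width, length,
stem length, firmness, pit weight, soluble solids, NaOH maturity,
acidity).

The package is aimed at agricultural data-mining work where a black-box
classifier is not acceptable: every model it fits is a small set of
human-readable rules of the form

```
IF (a_4l <= F_4 <= a_4u) and (a_8l <= F_8 <= a_8u) THEN C
```

i.e. a conjunction of closed numeric intervals over a subset of the
measured attributes, predicting one target class one-vs-rest.

## The method

Rules are evolved with a chaos-embedded **SPEA2** (strength Pareto
evolutionary algorithm) loop over three conflicting, simultaneously
maximised objectives — accuracy, precision and recall of the rule on the
training data:

* Each individual encodes a rule as three vectors in [0, 1] per feature:
  inclusion scores (feature *i* is used when its score exceeds a
  threshold λ, default 0.5) and lower/upper bound scores decoded
  affinely onto each feature's observed range.
* SPEA2 fitness: strength `S(i)` = number of pool members individual *i*
  dominates; raw fitness `R(i)` = sum of the strengths of *i*'s
  dominators (0 ⇔ non-dominated); density `D(i) = 1/(σ_i^k + 2)` from
  the distance to the k-th nearest neighbour in objective space;
  `F(i) = R(i) + D(i)`, minimised. Individuals with `F < 1` — exactly
  the non-dominated ones — enter a bounded external archive, with the
  classic fill/truncation operators.
* Population initialisation and mutation draw from a **guarded tent
  chaotic map** `x ← δx (x < ½); δ(1−x) (x ≥ ½)` at δ = 2, whose
  invariant density is uniform; a step-indexed golden-ratio re-seed
  keeps double-precision orbits aperiodic.
* Variation: binary tournament on `F` from the archive, uniform
  crossover at whole-feature granularity, and chaotic value-replacement
  mutation.

The result of a run is the archive's Pareto front: mutually
non-dominated rules trading accuracy against precision and recall, from
which a field expert picks according to their priorities (e.g. high
precision to avoid needless spraying, high recall to avoid missing an
outbreak).

Because the original field survey data are not redistributable, the
package ships a synthetic-data generator that emulates the survey's
composition (381 samples; 204 L / 101 M / 76 H; ten features with the
published ranges; trap-count classes 0–5 / 6–10 / >10) plus
planted-rule datasets with known ground truth for recovery testing.

## Worked example

```r
library(spea2rules)

survey <- generate_dataset(generator_config(seed = 1))   # 381 samples
parts  <- stratified_split(survey, 0.7, seed = 1)        # 70/30 per class

fit <- spea2_rules(class ~ ., parts$train[, c(cherry_schema()$name, "class")],
                   target = "H",
                   control = spea2_control(generations = 100, prng_seed = 1,
                                           chaos_seed = 0.7))
summary(fit, data = parts$test)
#> Pareto rule sets:
#>  class n_rules best_accuracy best_precision best_recall  arl max_len coverage
#>      H      20         0.858              1       0.981 1.95       4    0.991
#>  dominant_features
#>    Acidity, Weight
```

The fitted object holds 20 mutually non-dominated rules for the High
class; the best training accuracy on this synthetic survey is 0.858,
and some archive rule attains perfect precision (1.0) while another
attains recall 0.981 — the Pareto trade-off the method exists to
expose. Picking the best-accuracy rule and scoring it on the held-out
30%:

```r
rs   <- fit$rule_sets$H
best <- which.max(rs$objectives[, "accuracy"])
rule_to_text(rs$rules[[best]])
#> IF (4.945 < Weight < 6.797) and (38.676 < Hardness < 56.110) and
#>    (14.553 < SCKM < 16.695) and (0.797 < Acidity < 1.043) THEN H
objectives(evaluate_rule(rs$rules[[best]], parts$test))
#>  accuracy precision    recall
#> 0.8245614 0.6666667 0.2608696
```

`run_experiment()` repeats the whole protocol (fresh stratified split,
one evolutionary run per class, train and test scoring) across seeds
and tabulates min/max/mean/median/sd per class and metric;
`interpretability_table()` reports average/maximum rule length, rule
coverage and dominant features per class. A thin command-line wrapper
with `generate`, `mine` and `report` subcommands lives in
`inst/cli/spea2rules.R`.

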