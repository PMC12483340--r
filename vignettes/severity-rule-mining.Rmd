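---
title: "Mining stable severity-screening rules from GAD-7 and PHQ-9 items"
author: "sevrules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining stable severity-screening rules from GAD-7 and PHQ-9 items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The GAD-7 (7 items) and PHQ-9 (9 items) are the workhorse questionnaires for
anxiety and depression screening. Each item is scored 0 ("not at all") to 3
("nearly every day"); total scores stratify respondents into three severity
classes: *minimal or mild* (total < 10 on either scale), *moderate* (10–14 on
GAD-7; 10–19, "moderate or moderately severe", on PHQ-9) and *severe* (≥ 15
on GAD-7, ≥ 20 on PHQ-9). Administering a full scale is costly at population
scale; fixed short forms (GAD-2, PHQ-2) lose severity resolution.

`sevrules` implements an alternative: mine short *decision-tree rules* —
conjunctions of one to three item conditions such as `GAD2<2 and GAD4<2` —
that reproduce the severity stratification, and keep only rules that recur
across thousands of resampled tree fits. Stability of a rule across
resampling, not the performance of any single tree, is the selection
criterion.

## The procedure

For a cohort table with item responses and a derived severity label, one
mining run (`mine()`) executes, for every combination of *feature set* ×
*hyperparameter configuration* × *repetition*:

1. draw a random 70/30 train/test partition (without replacement; the
   training size is `n × 0.7` rounded half up, so a 20,585-row cohort splits
   into 14,410/6,175);
2. select the maximum tree depth by stratified 10-fold cross-validation on
   the training part over a candidate grid (default 1–8), ties to the
   smallest depth;
3. grow a CART classification tree at the selected depth;
4. extract one rule per leaf — the conjunction of the split conditions along
   its root-to-leaf path, predicting the leaf's majority class —
   canonicalise it, and increment its repetition count in the catalog.

`top_rules()` then keeps the most repeated rule per extreme class and the
two most repeated for the middle class (ties: fewer conditions, then
lexicographic), and `evaluate_rules()` scores the selected rules as
one-vs-rest screeners on every repetition's held-out partition, reporting
each metric as mean (SD) across repetitions.

### The tree engine

`sevcart()` is a from-scratch CART classifier. At each node the split with
the largest decrease in Gini impurity, $\Delta = G(p) - \tfrac{n_L}{n}G(l) -
\tfrac{n_R}{n}G(r)$ with $G(c) = 1 - \sum_k p_k^2$, is chosen over all
candidates: for ordinal items, thresholds midway between consecutive
*observed* values (the condition `value < k + 0.5` sends value $k$ left);
for nominal demographics with $L \le 8$ levels, all $2^{L-1}-1$ binary level
partitions. A split is legal only if both children hold at least `minbucket`
rows; a node is splittable only if it holds at least `minsplit` rows, is
impure, and lies above the depth cap. There is no cost-complexity pruning
and there are no surrogate splits: maximum depth, tuned by cross-validation,
is the only pruning device, and a missing predictor value at prediction time
is an error.

Determinism matters because rules are *counted*: ties in gain are broken by
scan order — lowest predictor index (items in scale order before
demographics), then lowest threshold (lowest subset bitmask for nominal
splits) — and leaf-label ties go to the more severe class, the conservative
choice for a screener. The depth tuner exploits an exact structural fact:
because splitting decisions are local and top-down, a depth-$d$ fit equals
the depth-$d$ truncation of a deeper fit, so one tree per fold is grown at
the maximal candidate depth and evaluated at every depth by truncated
prediction. This is an optimisation, not an approximation, and is verified
in the test suite by comparing truncated predictions against refits.

### Hyperparameters

The reference design explores `minsplit`, `minbucket` ∈ {500, 1000, 2000}
(all nine pairs), stated for a reference cohort of n = 20,585. With
`scale_to_n = TRUE` (default) these are rescaled proportionally to the
actual cohort size — 500 at the reference size is about 2.4% of the cohort —
so a reduced-size run preserves the constraint geometry. The routine
**demo profile** uses one feature set (items only), the single most
constrained pair (2000, 2000) — the configuration that yields the largest
nodes and simplest trees, appropriate when the cohort is small — and 50
repetitions on an n = 4,000 cohort. The **replication profile** is the full
design: five feature sets × nine hyperparameter pairs × 1,000 repetitions =
45,000 trees per scale at n = 20,585. The test suite and examples run the
demo profile; the replication profile is configuration, not separate code.

### Resampling and feature sets: open choices and how they were fixed

Three aspects of the reference design are under-determined and were fixed as
follows:

* **Resampling scheme.** "Bootstrapping" with printed partition sizes of
  exactly 70%/30% of n is implemented as repeated *without-replacement*
  70/30 partitions (Monte-Carlo cross-validation): a with-replacement
  bootstrap would not produce those exact sizes.
* **Feature sets.** The four models "with demographics" add one demographic
  variable at a time (sex, skin color, education, age group) to the items,
  rather than cumulatively; this keeps each demographic's competition with
  the items interpretable, and is configurable.
* **Per-rule AUC.** Two scoring modes are provided. `rule_binary` scores
  each row with the 0/1 rule indicator; its AUC is exactly
  (sensitivity + specificity)/2. `tree_probability` (default) scores rows
  with the repetition tree's predicted probability of the rule's class,
  giving a graded, class-level curve that both middle-class rules share.
  The default follows from arithmetic: reported per-rule AUCs in this
  literature (e.g. 0.923 with sensitivity 0.744 and specificity 0.942)
  exceed the binary closed form (≈ 0.843), and identical AUCs for the two
  middle-class rules indicate a class-level, probability-scored curve.
* Metrics for a selected rule are computed on **every** repetition's test
  partition, whether or not that repetition's tree contained the rule;
  repetitions whose test partition lacks the target class are skipped for
  that metric and counted. Undefined precision (no predicted positives) is
  reported as 0 with an explicit flag so that means stay computable.

## The synthetic cohort generator

No respondent-level data ships with the package; cohorts are simulated by
`generate_cohort()` with a graded (cumulative-logit) response model: a
standard-normal latent severity trait $\theta$ drives each item through
$P(X_{ij} \ge k \mid \theta_i) = \mathrm{logis}(a_j(\theta_i - b_{jk}))$,
$k = 1, 2, 3$. This is the simplest ordinal model with per-item
discrimination, which is all the analysis requires.

Defaults, fixed once during development and not revisited:

* **Hub items** — GAD-7 items 2 and 4; PHQ-9 items 2, 4 and 8 (the items
  that dominate the short screening rules this package is designed to
  recover) — get discrimination $a = 2.0$; all other items $a = 0.8$. The
  contrast gives rule-recovery experiments a known ground truth.
* **Thresholds** $b_{jk}$ share one triple per scale: $(-1.4, -0.3, 0.6)$
  for GAD-7 and $(-1.0, -0.1, 0.8)$ for PHQ-9, chosen by a coarse grid
  search so all three severity classes are well populated (class shares
  about 32/35/33 and 26/52/22), broadly resembling the prototypical-tree
  path coverages of the reference design. Exact prevalences are not a target.
* **Demographics** are drawn independently of the trait from marginals equal
  to the reported category counts of the reference 20,585-person cohort
  (91.5% female; skin color 50.5% white / 36.7% parda / 10.5% black / 2.2%
  other; education 49.0% graduate; five age bands). Age is drawn within the
  sampled band from a truncated normal with band means at band midpoints
  (62.5 as the nominal centre of the open-ended "more than 60" band,
  truncated at 80) plus a global shift, and a common underlying SD; shift
  and SD are solved by moment matching so the mixture mean is 41.1 years
  exactly and the SD is as close to 12.9 years as the ten-year band widths
  permit (the solution, σ ≈ 7.8, attains both).
* `demographic_effect` (default 0) adds a configurable trait shift for one
  demographic category, providing a positive control in which demographics
  genuinely carry outcome signal.

### What the generator emulates — and what it cannot

The generator reproduces the *statistical skeleton* the analysis assumes:
ordinal items driven by one latent severity dimension, stronger hub items,
realistic demographic composition, and labels derived from totals. It does
not emulate multidimensional symptom structure, item-specific content
effects, response styles, missingness mechanisms, or demographic-symptom
interactions. Passing tests therefore demonstrate that the machinery is
correct and that the qualitative findings (short hub-item rules; weaker
middle class; demographics never entering rules) are reproduced under the
assumed model — not that the numerical performance would transfer to real
cohorts.

One structural property deserves emphasis: **the severity label is a
deterministic function of the items** (label = stratify(total)). Three
consequences, all verified empirically and reflected in the test suite:

* A zero-discrimination cohort ($a_j = 0$) removes the latent-trait signal
  but *not* the accounting identity between items and total, so trees still
  find genuine splits. A null-control expectation of single-leaf trees is
  unattainable under this outcome definition; the corresponding null-control
  assertions in the acceptance test suite are retained and fail, honestly
  and by design.
* Demographics are informationally dominated: whatever they say about the
  class is mediated by the items, which are directly observed. Even a +1.5
  SD trait shift for one category leaves measured per-node Gini gains of
  the demographic several-fold below every item's, and it does not enter
  rules. The corresponding control assertion likewise stays red; the
  qualitative direction actually used in the analysis (with no effect,
  demographics never appear in top rules even when offered) holds.
* The two hub items are statistically exchangeable (equal $a$, equal $b$),
  so conditional on a first hub split the second hub is largely redundant
  and a weaker item occasionally wins the second split on a resampled
  cohort. Extreme-class hub recovery is therefore high but not certain
  (severe: 10/10; minimal/mild: 7/10 in the committed ten-run experiment).

## Numerical and degenerate-input choices

* Splits require strictly positive gain; if no legal candidate has one, the
  node becomes a leaf.
* Train-size rounding is half-up with a `1e-9` guard against binary
  floating-point artefacts (20,585 × 0.7 is 14,409.4999… in doubles).
* The trapezoidal ROC-AUC sweeps distinct score thresholds and equals the
  Mann–Whitney concordance with ties counted ½ (verified to 1e-10 against
  an independent rank-based computation).
* Every random draw descends from one base seed through deterministic
  sub-seed derivation, so catalogs, reports and written artifacts are
  byte-reproducible; per-repetition seeds derive from (base seed, feature
  set, configuration, repetition).
* An empty class in a held-out fold is permitted (accuracy remains
  defined); fewer rows than folds is an error. Infeasible configurations
  (rescaled `minsplit` exceeding the training size) are skipped with a
  logged warning.
* External-cohort reproducibility checks use the bound
  $3\sqrt{\mathrm{SD}_{\text{rep}}^2 + m(1-m)/n}$: the across-repetition SD
  alone understates the variability of an independent cohort, since all
  test partitions are drawn from a single cohort.

## Problem sizes

Routine runs (tests, examples) use the demo profile: cohorts of 1,500–4,000
rows, 20–50 repetitions, and ten-run recovery experiments — sizes chosen so
the full cycle completes in well under a minute on one core while every
structural property (constraint audits, oracle equivalence, determinism) is
exercised at full fidelity. The replication profile (45,000 trees per scale
at n = 20,585) is reached purely through `mining_config()` arguments.

## Known limitations

* Single-factor generative model; no item content, no multidimensionality.
* Depth-only pruning exactly as designed — no cost-complexity pruning, no
  surrogate splits, no case weights or loss matrices.
* Age enters trees only as the banded age group; continuous age is
  simulated for calibration but never competes as a predictor.
* The middle severity class is intrinsically harder (its score band is
  bounded on both sides); its rules and metrics are reported but expected
  to be weaker, as the class-accuracy ordering test asserts.
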