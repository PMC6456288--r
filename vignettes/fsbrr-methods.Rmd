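---
title: "Redundancy-removal filter feature selection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundancy-removal filter feature selection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsbrr)
```

## The problem and the model

High-dimensional biomedical classification tables — expression matrices with
tens of thousands of genes and a few dozen samples — mix three kinds of
columns: a small set of genuinely class-informative features, many columns
that are exact or near copies of those, and a large mass of features
statistically independent of the outcome. A filter selector should remove
the last two kinds using only intrinsic data statistics, so the selected
subset is classifier-agnostic.

`fsbrr` measures both axes with one statistic, the symmetric uncertainty

$$R(X, Y) = \frac{2\,IG(X;Y)}{H(X) + H(Y)}, \qquad
IG(X;Y) = H(X) + H(Y) - H(X,Y),$$

with Shannon entropies in bits over empirical (plug-in) category
frequencies. $R \in [0,1]$; it is 0 for independent variables and 1 exactly
when the variables determine each other. $R_{i,c}$ (feature vs class) is the
*vertical* relevance, $R_{i,j}$ (feature vs feature) the *horizontal* one.

Selection has three stages: an irrelevance filter ($R_{i,c} < \tau$ drops
the feature), a descending sort on $R_{i,c}$, and a single pass of pairwise
redundancy removal in which each surviving feature acts once as pivot and
removes lower-ranked survivors under two rules:

* **rule 1** — gap $R_{i,c} - R_{j,c} \le \delta$ and
  $R_{i,j} \ge R_{i,c}$: the two features are nearly interchangeable in
  class relevance and the pivot explains $F_j$ at least as well as it
  explains the class;
* **rule 2** — $\delta < R_{i,c} - R_{j,c} < \alpha$ and
  $R_{i,j} > (\bar R + R_{j,c})/2$: $F_j$ is clearly weaker, so a milder
  correlation with the pivot suffices, the bar being the midpoint between
  the mean relevance $\bar R$ of the retained set and $F_j$'s own relevance.

The contrapositive is a guarantee the tests exercise directly: a feature
whose $R_{i,j}$ with every pivot stays below both bars is never removed,
regardless of its own (possibly tiny) class relevance — weak horizontal
correlation means no feature can substitute for it.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `tau` | 0 | $[0, 1]$ on $R_{i,c}$ | irrelevance cut-off; 0 keeps weakly relevant features when no prior knowledge justifies a cut |
| `delta` | 0.08 | $[0, 1]$ gap on $R_{i,c}$; recommended $[0.05, 0.13]$ | boundary between the strict (rule 1) and relaxed (rule 2) removal regimes |
| `alpha` | 0.64 | $[0, 1]$ gap; recommended $[0.60, 0.66]$ | largest relevance gap at which rule 2 may still fire; beyond it $F_j$ is too different to be substituted |
| `n_bins`, `binning` | 10, equal width | — | discretization of continuous features |
| `w1`, `w2` | 0.999, 0.001 | sum to 1 | weights of accuracy vs subset sparsity in the composite score |
| `n_folds`, `n_repeats` | 10, 5 | — | evaluation protocol scale |

Values of `delta`/`alpha` outside the recommended ranges warn but run:
the ranges are empirical optima, not hard constraints, and `fsbrr_sweep()`
exists precisely to profile them (one parameter swept, the other fixed).

## Numerical choices

* **Bits, base-2 logs, plug-in frequencies.** No pseudocounts and no bias
  correction; the statistic is the maximum-likelihood one throughout.
* **Exact symmetry.** Entropies are accumulated over *sorted* non-zero
  count vectors, so any two inputs with the same count multiset give
  bit-identical entropy. $IG$ is computed in the joint-entropy form
  $H(X)+H(Y)-H(X,Y)$ and is therefore exactly symmetric in its arguments;
  the conditional-entropy form $H(X)-H(X|Y)$ is implemented independently
  and agrees to $10^{-10}$ (a property the test suite checks on a thousand
  random contingency tables). Self-relevance is exactly 1 and exact
  duplicates score $R_{i,j} = 1$ with no floating-point slack, which is
  what makes duplicate elimination deterministic.
* **Discretization.** Continuous features default to equal-width binning
  with 10 bins — the simplest reproducible convention; equal-frequency
  binning and pass-through of already-coded data are available. The last
  equal-width interval is closed so the maximum never overflows; constant
  columns map to a single code. Class labels are factor-coded, never
  binned.
* **Degenerate inputs.** Two constant variables give $R = 0$ (the
  denominator $H(X)+H(Y)$ vanishes; a constant carries no usable
  relevance). Constant features pass `tau = 0` — the filter is
  $R_{i,c} \ge \tau$ — and are retained literally, with a warning
  recommending a positive `tau`. Missing values are rejected at load with
  the offending cells named; the method has no imputation semantics.
* **Ties.** The descending sort breaks relevance ties by original column
  order, making the whole selection bit-for-bit reproducible; exact
  duplicates tie on $R_{i,c}$, so the earlier column becomes the pivot and
  the later copy is removed.
* **Strictness.** Rule 2's upper gap test is strict (`< alpha`), and
  rule 1's correlation test is non-strict (`>= R_{i,c}`), matching the
  operational definition of the procedure. $\bar R$ is the mean over the
  $\tau$-retained features; with the default $\tau = 0$ this coincides
  with the mean over all features, since $R \ge 0$ always.

## The evaluation harness

`cross_validate()` implements repeated stratified $k$-fold cross-validation
(default 10 folds; 5 repeats as the desk-scale default, with the
published-protocol scale of 100 repeats available through `n_repeats`).
Feature selection runs *inside* each training fold by default, so the
held-out fold never influences the selected subset; the single-selection
variant (`outside_folds = TRUE`) exists as a compatibility switch because
evaluation tables reporting one feature count per dataset imply that
convention. Classifier hyperparameters are fixed — random forest with 10
trees, 1-nearest-neighbour, linear-kernel SVM — and everything else stays
at the backing libraries' defaults, echoed in the report for audit. The
report carries fold-level accuracy mean/max/min/sd (and the repeat-level
sd separately, since either aggregation is defensible), the mean number of
features used, and the composite score
$w_1 \cdot Acc + w_2(1 - n/N)$.

## What the synthetic generator emulates — and what it does not

`synth_table()` plants the structure the selector is designed to find:
class-conditional Gaussian informative features (unit variance, mean
separation `shift`, default 2 — a clearly detectable but not trivial effect
on a couple of hundred samples), exact copies, noisy copies
(`noise_sd`, default 0.2), and standard-normal irrelevant features, under a
Bernoulli class with `class_balance` (default 0.5). Ground-truth roles
travel with the table, so tests can assert recovery rather than eyeball it.

It deliberately does **not** simulate microarray-specific structure: probe
effects, batch structure, heavy-tailed intensity distributions, correlated
noise blocks, or multi-class outcomes. Passing tests on these tables show
the algorithm implements its stated rules and recovers planted structure
under clean conditions; they do not certify accuracy gains on any
particular real dataset.

## Problem sizes used in the checks

The test suite runs the transcription-equivalence check on 50 random tables
of up to 30 features and 200 instances against a naive line-by-line
re-implementation of the procedure, the duplicate-elimination invariant on
100 tables, the information-theory oracle suite on 1,000 random contingency
tables, and the harness checks at 10 folds × 5 repeats on tables of 200–400
instances and up to 63 features. `scripts/acceptance.R` uses the same
63-feature planted-structure table (3 informative, 10 exact duplicates, 50
irrelevant, 200 instances). These sizes were chosen so the planted effects
are comfortably detectable while the full suite stays fast; the algorithm
itself has no scale-dependent switches.

## Known limitations

* The plug-in mutual-information estimate is biased upward, and the bias
  grows with bin count and shrinks with sample size. At a few hundred
  instances and 10 bins, independent feature pairs can show
  $R_{i,j} \approx 0.1$–$0.3$; rule 2's bar then occasionally prunes a
  genuinely informative feature, so the accuracy benefit of selection is
  not uniform across data realizations (it holds for most planted-structure
  tables, not all). Users with very small samples should reduce `n_bins`.
* Equal-width binning is a convention, not a recommendation; relevance
  values are only comparable across runs using the same discretization,
  and published relevance figures computed under unknown discretizations
  cannot be reproduced exactly.
* The single pass in descending relevance order makes the selection greedy:
  the most relevant member of a redundant group always survives, but the
  retained set is not optimal under any global criterion.
* Binary and multi-class categorical outcomes are supported; multi-label
  outcomes and missing data are not.
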