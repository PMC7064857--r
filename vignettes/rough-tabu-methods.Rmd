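---
title: "Rough-set attribute reduction by Tabu search: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-set attribute reduction by Tabu search: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughtabu)
```

## The model

`roughtabu` treats feature selection as **attribute reduction on a decision
table**. A decision table holds a universe $U$ of objects described by
discrete conditional attributes $C$ and one decision attribute $D$. A subset
$P \subseteq C$ induces the indiscernibility relation — two objects are
indiscernible when they agree on every attribute of $P$ — whose equivalence
classes partition $U$. For a concept $X \subseteq U$,

- the *lower approximation* $\underline{P}X$ is the union of classes wholly
  inside $X$ (certain members),
- the *upper approximation* $\overline{P}X$ is the union of classes meeting
  $X$ (possible members),

so $\underline{P}X \subseteq X \subseteq \overline{P}X$ always. The
*positive region* $POS_P(D)$ collects the objects whose class is pure, i.e.
$\bigcup_{X \in U/D} \underline{P}X$, and the *dependency degree*

$$\gamma_P(D) = \frac{|POS_P(D)|}{|U|} \in [0, 1]$$

measures how completely $P$ determines the decision. $\gamma$ is monotone
under subset inclusion and depends only on *equality* of attribute codes —
codes are opaque integers, never ordered quantities. A *reduct* is an
inclusion-minimal $P$ with $\gamma_P(D) = \gamma_C(D)$.

Key assumption: the table is a sample of a discrete joint distribution in
which indiscernibility is meaningful. For continuous features that holds
only after discretization, and the granularity of the discretization governs
how informative $\gamma$ is (see *Limitations*).

## The search

Reduct search is exponential, so `tabu_reduce()` explores binary inclusion
masks with an adaptive-memory local search:

1. **Neighborhood search.** Each iteration mutates the current mask at $k$
   random positions ($k$ uniform on $1..k_{\max}$, positions without
   replacement) to produce up to $m$ trial solutions. Masks equal to an
   entry of the Tabu list — a FIFO of the recently visited masks — are
   discarded and redrawn (bounded retries), as is the all-zero mask unless
   the decision is constant. The best trial under the objective is accepted
   *even when it does not improve*, which is what lets the walk leave local
   optima; there is no aspiration rule, tabu masks are avoided outright.
2. **Diversification.** After `stagnation_limit` iterations without
   improving the incumbent, the current mask is rebuilt with per-attribute
   inclusion probability proportional to $w_j = 1/(1 + \text{count}_j)$,
   where $\text{count}_j$ counts appearances of attribute $j$ across all
   trial solutions so far; weights are scaled so the expected mask size is
   half the attribute count (clamped per attribute). The incumbent is never
   replaced, and the Tabu list is retained across diversifications.
3. **Shaking.** At termination the incumbent is shrunk greedily: attributes
   are visited one by one and removed whenever removal leaves $\gamma$
   unchanged (by monotonicity removal can never raise it). The result is a
   subset of the incumbent with identical $\gamma$.
4. **Elite reduct.** `shake_rounds` independent shakes under random visit
   orders are intersected; the intersection is returned when it preserves
   the full-set $\gamma$, otherwise the best shaken solution is returned —
   the intersection of *distinct* minimal reducts can lose dependency, and
   the fallback covers that degenerate case.

The objective is lexicographic: maximize $\gamma$, then (toggleable,
`cardinality_tiebreak`) prefer fewer attributes, since the shaking and
elite stages explicitly target minimal sets.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_neighbors` (m) | 10 | trial solutions per iteration; enough for steady descent on tables up to a few hundred attributes |
| `tabu_tenure` | 20 | recently visited masks remembered; short enough not to freeze small search spaces |
| `max_iterations` | 200 | outer loop length; T1-scale and 30–400-attribute tables finish in seconds |
| `max_flip` (k_max) | 3 | largest mutation; small flips keep the walk local |
| `stagnation_limit` | 15 | patience before diversification |
| `shake_rounds` | 5 | shaken copies feeding the elite intersection |
| `seed` | 1 | drives every random draw; echoed in the result |

The initial mask is Bernoulli(1/2) from the seeded RNG. All of these are
search hygiene, not science: any setting yields a valid (possibly worse)
reduct, and identical seed plus input reproduces the result bit for bit.

## Discretization

The rough-set stage requires integer codes, so `fit_bins()` learns
per-feature cut points — `"quantile"` (equal frequency, the default) or
`"width"` (equal spacing) — and `bin_apply()` maps values to the half-open
bin $[e_{k-1}, e_k)$, clamping beyond-range values to the outermost bins.
Duplicate quantile edges (heavily tied features) collapse bins; constant
features yield one bin. Defaults are 3 quantile bins: equal-frequency
binning is robust to the heavy tails typical of morphometry features, and
three levels is the coarsest resolution that still distinguishes
low/middle/high. Bins are always fitted on training rows only and applied
to test rows, so the selection stage never sees held-out data. The
classifiers themselves consume the raw continuous features — discretization
exists solely for the selector.

## Synthetic data

`simulate_decision_table()` plants a known reduct: the decision is the
parity of the code sum of `reduct_size` uniform attributes, so the planted
set fully determines the decision; redundant attributes are injective
recodings (seeded code permutations) of planted columns and thus induce the
same partition — either member of such a pair can substitute for the other
in a minimal reduct, which is why tests verify minimality with the
brute-force oracle rather than against the planted index set; noise
attributes are independent uniform codes; `inconsistency_rate` flips that
fraction of decisions, pulling $\gamma_C(D)$ below 1. Parity keeps
$\gamma$ analytically controllable: flips, not attribute noise, are the
only inconsistency source.

`simulate_classification()` emulates a two-class morphometry table: a few
informative dimensions (class-conditional normals separated by a
standardized `effect_size`), optional redundant features (noisy random
linear combinations of the informative ones, noise sd 0.3), and pure-noise
features. What it does **not** emulate: the strong block correlation, skew
and mixed scales of real histopathology feature tables, or label noise.
Passing tests on this generator therefore show that the machinery is
correct and that the selector behaves as designed under clean assumptions —
not that selection improves diagnosis on any particular real dataset.

## Numerical choices

- $\gamma$ comparisons use an absolute tolerance of $10^{-12}$; the values
  are small-denominator rationals, so this only guards float noise.
- Partitions are computed by grouping subset-restricted value tuples; the
  contract is set equality of blocks, never block order.
- Neighbor ties under the objective resolve to the earliest generated
  trial; elite-fallback ties keep the first best shaken solution — both
  deterministic under the seed.
- Degenerate inputs: an attribute-free table returns the empty selection
  with $\gamma(\emptyset)$; a constant decision makes the empty set the
  (unique) reduct; the all-zero mask is otherwise excluded from the search.
- `brute_force_min_reducts()` refuses tables wider than 15 attributes
  ($2^p$ enumeration); it exists as an oracle, not a production path.
- Undefined metric ratios (zero denominators) report 0 with a warning; AUC
  uses midranks, so ties count one half.
- The boosted-ensemble classifier slot is gradient-boosted shallow trees
  (xgboost, depth 2, 100 rounds); k-NN uses $k = 5$ on unstandardized
  features; extremely randomized trees use 200 trees with one random split
  per candidate feature. Single-threaded settings keep runs reproducible.

## Design decisions on open points

- **F1** uses the standard harmonic mean $2PS/(P+S)$; both precision and
  specificity are computed, and reports carry the five-column layout
  (accuracy, precision, sensitivity, F1, AUC) as percentages.
- **Evaluation protocol** when no fixed split is supplied: stratified 70/30
  holdout, seeded; explicit train/test index lists are supported for
  datasets that ship with a fixed split. Metrics are always computed on
  held-out rows only.
- **LR** is logistic regression (binomial GLM); the positive class defaults
  to label 1 and is configurable.
- **Diversification** replaces the current solution once and keeps the Tabu
  list; restarting the list would discard exactly the memory that prevents
  re-treading the stagnated region.
- Problem sizes used in the shipped property suites — random tables up to 8
  objects × 5 attributes for oracle comparisons, 10-attribute planted
  tables for recovery, a 200 × 50 classification table for the selection
  benchmark — were chosen so each suite completes in seconds to a few
  minutes on one core while still exercising nondegenerate combinatorics.

## Known limitations

- **Dependency degree saturates on wide discretized tables.** With $n$
  objects and $b$-bin codes, a subset of $k$ attributes spans $b^k$ cells;
  once $b^k \gg n^2$ almost every pair of objects separates, so
  $\gamma = 1$ is attainable by many small subsets regardless of their
  relevance, and the criterion stops discriminating informative from noise
  attributes. The shipped selection-benefit suite measures exactly this
  regime (3 informative among 50 features, 140 training rows, 3 bins):
  the Tabu selector reliably finds *minimal* subsets at full dependency,
  yet their median held-out accuracy falls short of the all-features arm
  for every classifier — the selected minimal reducts are dominated by
  noise attributes whose rare cell collisions happen to be pure in
  training. On such data the dependency criterion rewards overfitting; a
  practitioner should use far coarser bins relative to $n$, or prefer
  tables where $\gamma_C(D) < 1$ so the criterion has a real gradient.
- Rough-set variants that would mitigate this (variable-precision rough
  sets, fuzzy indiscernibility, discernibility-matrix algorithms,
  supervised/MDL discretization) are out of scope.
- The search is single-objective and sequential; no parallel walks, no
  alternative metaheuristics.
- `is_relative_reduct()` checks one-deletion minimality, which equals full
  inclusion-minimality only for dependency-preserving subsets (guaranteed
  here by monotonicity).
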