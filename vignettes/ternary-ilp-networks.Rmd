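---
title: "Ternary-state ILP inference of cell-specific signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary-state ILP inference of cell-specific signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

Phosphoproteomic perturbation screens measure, for each small-molecule
compound, the log2 ratio of a phosphoprotein's abundance under treatment
versus control at a single time point.  A single snapshot cannot support
kinetic (ODE) modeling, but it can support a *discrete* question: which
reactions of a literature-curated signaling map are actually used by
this cell line, and how does a new compound redistribute signal through
them?

`ternet` answers that question with an integer linear program over
ternary node states.  Its inputs are:

* a **generic pathway map**: a signed directed graph whose nodes are
  phosphoproteins, transcription factors (TFs), and cell-function
  *output* nodes, and whose edges are candidate activation (+1) or
  inhibition (-1) reactions;
* a **ternary profile** `m[j, k]` in {-1, 0, +1}: the discretized
  response of observed protein `j` to compound `k`;
* **prior knowledge**: literature-confirmed direct targets, e.g.
  "fulvestrant down-regulates ER", imposed as hard constraints.

## Discretization

A log2 ratio `rho` is mapped with a fold-change threshold `t > 1`
(default 1.2):

* `+1` (up-regulated) if `rho >= log2(t)`,
* `-1` (down-regulated) if `rho <= -log2(t)`,
* `0` otherwise; both boundaries are inclusive.

Replicate columns sharing a condition id are averaged on the log2 scale
before thresholding; no combination rule is standard for two-replicate
designs, and the mean is the least informative-looking choice.  Missing
entries stay missing and contribute neither constraints nor error terms.

## Decision variables

For every node `j` and condition `k` an integer `x[j,k]` in {-1, 0, +1}
holds the predicted state (output nodes carry the signed sum of their
TFs, with correspondingly wider bounds).  Binary auxiliaries:

* `xp`, `xm`: the sign split `x = xp - xm`, `xp + xm <= 1`;
* `y[i]`: 1 when candidate edge `i` is removed from the map;
* `z[i,k]`: 0 when reaction `i` takes place under condition `k`, 1 when
  it does not (the inverted convention is kept as the field prints it);
* `a[j,k]`: 1 when the predicted state of an observed protein differs
  from its observation;
* `w`-products and `pos`/`neg` support indicators described below.

## Objective

```
minimize  sum_{k,j} a[j,k]  +  gamma * sum_i y[i]
```

with `gamma` in the open interval `(-1/n_removable, 0)` (default
`-0.5/n_removable`, the midpoint).  Because `|gamma| * n_removable < 1`
and mismatch counts are integers, **simplicity can never buy back a unit
of data fit**: the optimal mismatch count equals the best achievable one,
and among perfect-fit-equivalent solutions the solver removes as many
unused edges as possible.  The mismatch indicator replaces the squared
error `(m - x)^2` (which would weight a 2-unit miss four times a 1-unit
miss) with the uniform pair

```
m - x <= 2a,    x - m <= 2a .
```

## Constraint system

1. **Sign split / domains** as above.
2. **Mismatch coupling** for every observed, non-missing entry.
3. **Removal/occurrence coupling**: `z[i,k] >= y[i]` (a removed edge
   occurs nowhere) and `1 - y[i] <= sum_k (1 - z[i,k])` (a kept edge
   occurs somewhere).
4. **Support (linking pattern)**: a node may change only if some
   occurring incoming edge delivers a matching signal,
   `xp[d,k] <= sum pos[i,k]` and `xm[d,k] <= sum neg[i,k]`, where
   `pos[i,k]` can be 1 only if edge `i` occurs (`z = 0`) and its parent
   delivers +1 (parent up for activation, parent down for inhibition);
   `neg` mirrored.  Root nodes (no incoming edges) are exempt — they are
   the receptor/compound entry points — and so is a prior-pinned node in
   the condition where the compound acts on it directly
   (`exempt_prior_targets`, default `TRUE`).  Conflicts between parents
   are resolved by the data-fit objective.
5. **Consistency bounds**: with `p = x_u * x_d` linearized through four
   AND binaries, `-1 <= p + z <= 1` for activation edges and
   `-1 <= p - z <= 1` for inhibition edges.  These force an activation
   edge to occur when its endpoints are co-directed (and an inhibition
   edge when anti-directed), preventing "missing edge" solutions in
   which a signal appears downstream of a pruned path.
6. **Occurrence guard**: `1 - z <= xp_u + xm_u` — a reaction cannot take
   place from an unchanged parent.
7. **Prior knowledge**: `x[j,k]` fixed to the literature direction.  A
   prior that contradicts an observation wins (and is logged); the
   mismatch it causes is charged to `a`.
8. **Output equalities**: each cell-function node equals the signed sum
   of its upstream TF states.  These edges are definitional: they carry
   no `y`/`z` variables and are never candidates for removal.  The
   literature calls the readout an "OR gate"; the arithmetic is a signed
   sum, which we implement as printed, noting the terminological
   mismatch.

Prediction mode re-optimizes a previously inferred network for a new
compound: the `y` variables and constraint 3 are dropped, occurrence is
free per condition subject to 4–6, and the objective is the mismatch
count alone.

The support constraints (4) and the occurrence guard (6) reconstruct the
linking-pattern rules from their described behavior — a child node is
regulated by at least one of its parents, and a "did not occur" reaction
cannot transmit — rather than from a printed constraint list; the
package's brute-force oracle and property tests validate the
reconstruction behaviorally.

## Solving

The program is solved by the **HiGHS** mixed-integer solver through the
bundled `scipy` bridge (`inst/python/milp_solve.py`), with
`mip_rel_gap = 0` so every reported optimum is proven.  HiGHS is
deterministic for a fixed model, so runs are reproducible bit-for-bit;
the `seed` argument exists so run manifests can record one uniformly.
Returned values must be integral within `1e-6` and are rounded on
extraction; the removal/occurrence coupling is re-asserted during
decoding.  Multiple optima are possible (the data rarely pin down every
unobserved intermediate); no tie-break is imposed and the solver's first
optimum is reported.  Batched problems (cross-validation folds, oracle
sweeps) share a single backend call.

With no prior constraints the all-zero state (`x = 0`, `z = 1`
everywhere, all candidate edges removed) is always feasible, so training
problems without priors can never be infeasible.  An infeasibility can
only be constructed by pinning a non-root node to a direction no parent
can deliver while disabling the prior exemption.

## Effect readouts

* **Outcome vector**: one signed integer per cell-function output
  (for the packaged map: cell cycle = RB + PLK1, DNA repair = P21 +
  RRM2, cell survival = NFKB - BAD + BCL2, cell growth = PGSK3 +
  P70S6K + CMYC + CJUN), each bounded by the sum of absolute
  coefficients of its definition.
* **Similarity score**: the Pearson correlation of two outcome vectors.
  A zero-variance vector has no defined correlation; the package raises
  an error rather than inventing a convention value.
* **Fitting precision**: the exact-match fraction over observed,
  non-missing (protein, condition) pairs — the only definition
  consistent with per-compound values such as 14/15 = 93.33%.
* **Topology similarity**: the fraction of a reference network's signed
  edges present in a query network.
* **Edge labels** (four-way alteration semantics): an occurring edge is
  `up` or `down` by the sign it delivers; a non-occurring edge between
  two unchanged nodes is `no-change`; any other non-occurring edge is
  `not-occurring`.

## The synthetic generator

`generate_network()` builds layered signed DAGs (multi-parent linking
patterns, terminal TFs wired to outputs) and designates a random
fraction of candidate edges as truly absent.  `simulate_profiles()`
perturbs root nodes to +/-1 per condition and propagates states in
topological order over the true edges: a node takes the sign of the sum
of delivered parent signals, 0 on ties (a zero child needs no support,
so the tie rule matches the constraint semantics).  Observed entries are
then flipped to one of the two other ternary values with probability
`flip_noise_rate` — the simplest exchangeable corruption for
precision/recall curves.

Noise-free simulated profiles are exactly feasible for the generating
subnetwork, so inference must reach a zero mismatch count on them; this
is asserted for every generated instance in the tests.  What the
generator does **not** emulate: feedback loops (real maps may be
cyclic — the ILP handles cycles, the propagation model does not),
correlated or intensity-dependent measurement noise, batch structure,
and partially effective perturbations.  Passing the synthetic recovery
tests therefore demonstrates correctness of the optimization, not
field performance on real phosphoproteomics.

The `preset_mcf7_like()` preset mirrors the shape of the packaged
study: 35 nodes, 50 edges including 4 outputs and 11 TF-output links,
10 training conditions, at most one prior target per condition, 15 of
31 signaling nodes observed.

## Validation machinery

`brute_force_solve()` is an independent oracle for instances with at
most 8 non-output nodes, 8 candidate edges and 2 conditions.  It
enumerates every ternary state assignment per condition and derives
occurrence/removal analytically: per candidate "occurs-somewhere" edge
set, a reaction is forced to occur where the endpoint product demands
it, support needs are covered within the set, and the objective is
scanned over all `2^n_edges` sets.  This shrinks the enumeration from
`3^(nL) * 2^(E(L+1))` to `3^(nL) * 2^E * poly` without borrowing
anything from the MILP encoding.  The test suite checks the MILP
optimum, the optimal mismatch count, and the removal/occurrence logic
against this oracle on 100 seeded random instances (3–6 nodes, edge
density 0.3–0.6, 30% inhibition, 1–2 conditions, 60–100% observation
coverage).

`loo_crossval()` holds out each condition in turn, re-infers the
network from the rest, predicts the held-out compound on the fold
network, and reports per-fold fitting precision plus the fold network's
topological similarity to the all-data network (the all-data network is
the reference, matching the convention of reporting fold similarity
against the full fit).  The held-out compound's prior record, when one
exists, is supplied to the prediction step: it encodes literature
knowledge about the compound, not training data.  Prediction-mode
fitting precision is computed on the final optimal states, after all
support constraints have acted.

## Problem sizes and runtime choices

The packaged 35-node, 50-edge map with 10 conditions builds to roughly
3,900 variables (350 integer node states and the rest binary) and 8,900
constraints and solves to proven optimality in a few seconds.  The test
suite uses 12-node synthetic networks with 4 conditions for
solver-backed integration tests and instances within the enumeration
bounds for oracle comparisons; these sizes exercise every constraint
family while keeping the suite fast.  Recovery experiments default to 3
replicates per noise rate.

## Known limitations

* The optimal network need not be unique; alternate-optima enumeration
  is out of scope, and downstream conclusions should rely on aggregate
  quantities (fit, outcome vectors) rather than the identity of any
  single borderline edge.
* The packaged map's edge list is a best-effort transcription of a
  published figure: only its aggregate shape (35 nodes, 50 edges, 15
  observed, 4 outputs) is asserted, and individual links should not be
  treated as curated facts.
* Constraint counts depend on reconstruction details of the linking
  pattern and are reported but not asserted.
* Mismatch penalties are uniform by design: a 2-unit miss costs the
  same as a 1-unit miss.
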