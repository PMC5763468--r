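# ternet

Ternary-state integer linear programming for inferring cell-specific
signaling networks from compound-perturbation phosphoproteomics, and for
predicting a compound's treatment effects on the inferred network.

## Who this is for

Systems biologists with (i) a literature-curated signed signaling map —
candidate activation/inhibition reactions among phosphoproteins,
transcription factors (TFs), and cell-function readouts — and (ii) a
panel of single-time-point perturbation profiles (log2 treatment/control
ratios per protein and compound, e.g. LINCS-P100-style data).  `ternet`
prunes the map down to the subnetwork a specific cell line actually
uses, then re-optimizes that subnetwork per new compound to read off
pathway alterations and quantitative outcome vectors.

## The model

Protein responses are discretized to ternary states with a fold-change
threshold *t* (default 1.2):

> *m*ⱼₖ = +1 if ρ ≥ log₂ *t*;  −1 if ρ ≤ −log₂ *t*;  0 otherwise,

where ρ is the log2 ratio of protein *j* under compound *k*.  The
inference problem is the mixed-integer program

> minimize  Σₖ Σⱼ *a*ⱼₖ + γ Σᵢ *y*ᵢ

over ternary node states *x*ⱼₖ ∈ {−1, 0, 1}, per-condition reaction
occurrences *z*ᵢₖ (0 = takes place), edge removals *y*ᵢ, and mismatch
indicators *a*ⱼₖ (1 iff *x*ⱼₖ ≠ *m*ⱼₖ for an observed entry).  Linear
constraints tie them together: a removed edge occurs nowhere and a kept
edge somewhere; a changed node needs an occurring incoming edge
delivering a matching signal (roots and literature-confirmed compound
targets exempt); an activation edge with co-directed endpoints — and an
inhibition edge with anti-directed endpoints — is forced to occur, so
pruning can never fake a downstream signal; cell-function outputs equal
the signed sum of their TF states.  With γ ∈ (−1/|E|, 0), simplicity
never trades away a unit of data fit: the solver first minimizes
mismatches, then removes as many unused edges as possible.  Prediction
for a new compound re-runs the same program on the inferred network with
removals disabled.

Treatment effects are compared through the outcome vector (one signed
integer per cell function, e.g. cell cycle = RB + PLK1, cell survival =
NFKB − BAD + BCL2) and the similarity score — the Pearson correlation of
two compounds' outcome vectors.

Programs are solved to proven optimality by the HiGHS solver through a
bundled Python/scipy bridge (`python` with `scipy >= 1.9` must be on the
PATH; no R solver dependency).

## Worked example

```r
library(ternet)

map <- mcf7_generic_map()     # packaged breast-cancer map
map
#> <signaling_network> 35 nodes (15 observed), 50 edges (39 removable, 8 inhibitory)

# synthetic study with known ground truth, shaped like the MCF7 panel:
# 10 compounds, one literature target each, 15 observed proteins
preset <- preset_mcf7_like(seed = 42)

fit <- infer_cell_specific_network(preset$network, preset$profile, preset$prior)
fit
#> <network_inference> 24/39 candidate edges removed | fit term 0 | fitting precision 100.00%
glance(fit)[, c("n_edges_kept", "n_edges_removed", "fit_term", "fitting_precision")]
#> # A tibble: 1 × 4
#>   n_edges_kept n_edges_removed fit_term fitting_precision
#>          <int>           <int>    <dbl>             <dbl>
#> 1           26              24        0                 1
```

The fit term is the number of observed (protein, condition) pairs the
optimal states fail to reproduce — 0 here because the profiles are
noise-free — and 24 of the 39 candidate edges are pruned because no
condition ever uses them.  Predicting one compound on the inferred
network:

```r
k <- colnames(preset$profile)[1]
resp <- predict_compound_response(fit, preset$profile[, k, drop = FALSE],
                                  prior = subset(preset$prior, condition == k))
resp
#> <response_network> condition=cond01 | outcome [-1, 1, 0, 0] | fitting precision 100.00%
tidy(resp)          # per-edge up / down / no-change / not-occurring labels
```

The outcome vector holds the predicted change of each cell-function
readout; compound-to-compound similarity is its Pearson correlation:

```r
similarity_score(c(0, 0, -3, -1), c(0, 0, -2, -2))
#> [1] 0.8164966
```

Leave-one-out cross-validation (train on 9 compounds, predict the
held-out one) and noise-sweep recovery experiments:

```r
glance(loo_crossval(preset$network, preset$profile, preset$prior))
#> # A tibble: 1 × 4
#>   n_folds n_failed mean_precision mean_similarity
#>     <int>    <int>          <dbl>           <dbl>
#> 1      10        0              1               1

autoplot(recovery_experiment(noise_rates = c(0, 0.1, 0.3), replicates = 3))
```

A command-line interface covering `discretize`, `infer`, `predict`,
`effects`, `similarity`, `crossval`, `simulate` and `benchmark` is
installed at `system.file("cli", "ternet", package = "ternet")`.

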