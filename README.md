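# symptomnet

Regularized partial-correlation networks for ordinal symptom data, with
two-group comparison. The package is aimed at researchers analysing
questionnaire surveys — here nine PHQ-9 depression items (scored 0–3) and,
optionally, the two intolerance-of-uncertainty dimensions, prospective
anxiety (`AA`) and inhibitory anxiety (`IA`) — who want the full symptom-
network workflow as reproducible, tested code: estimation, node indices,
stability, and a permutation test of group differences.

## What it computes

Items are modeled as a Gaussian graphical model: edges are partial
correlations `w_ij = -θ_ij / sqrt(θ_ii θ_jj)` from a sparse precision
matrix Θ estimated by the graphical lasso,

```
maximize  log det Θ − tr(SΘ) − λ Σ_{i≠j} |θ_ij|
```

over a 100-point log-spaced λ path, with λ selected by the extended
Bayesian information criterion `EBIC = −2ℓ(Θ) + E log n + 4 E γ log p`
(γ = 0.5 by default). S is the Spearman correlation matrix of the items.
On top of the estimated network the package computes:

* node **strength**, **expected influence**, harmonic **closeness**,
  **betweenness**, and nodewise **predictability** (R² of each item on the
  rest);
* **flow decompositions**: which symptoms touch a focal node (e.g.
  suicidal ideation, or an IU dimension) directly and which only through
  intermediaries;
* **bootstrap** edge confidence intervals, edge/centrality difference
  tests, and the case-dropping **CS coefficient** (stability);
* the permutation **network comparison test** (NCT) between two groups:
  global-strength invariance `S = |GS_A − GS_B|` and structure invariance
  `M = max |w_A,ij − w_B,ij|`;
* PHQ-9 totals, depression screening prevalence (total ≥ 8), group
  descriptives, pooled-variance t tests and 2×2 chi-square tests;
* a latent-Gaussian threshold **simulator** producing ordinal datasets
  with known network structure, marginals calibrated to a published
  urban/rural adolescent survey, and a controllable between-group
  edge-weight scaling.

## Worked example

```r
library(symptomnet)

# a two-group study with known truth: 11 nodes (9 symptoms + AA/IA),
# 30% of possible edges, urban/rural sizes, no true group difference
truth <- make_true_network(11, density = 0.3, weight_range = c(0.2, 0.35),
                           seed = 1)
study <- make_two_group_study(truth, nA = 439, nB = 1049,
                              group_scale = 1, seed = 42)

urban <- select_items(study$A, paste0("PHQ", 1:9))
net <- estimate_network(urban)
net
#> <network_model> 9 nodes, 21 edges (lambda = 0.07717, gamma = 0.5, EBIC = 2972.72, n = 439)

head(centrality_table(net, data = urban)[, c("node", "strength",
                                             "expected_influence",
                                             "predictability")], 3)
#>   node  strength expected_influence predictability
#> 1 PHQ1 0.6797370          0.6797370      0.3898111
#> 2 PHQ2 0.2127937          0.2127937      0.1051439
#> 3 PHQ3 0.5504288          0.5504288      0.3418838

flow_decompose(estimate_network(study$A), "IA")
#> <flow_decomposition> focal = IA
#>   direct: PHQ1, PHQ2, PHQ3
#>   indirect layer 2: PHQ4, PHQ5, PHQ6, AA, PHQ8, PHQ7, PHQ9

comp <- nct(urban, select_items(study$B, paste0("PHQ", 1:9)),
            n_perm = 500, seed = 7)
comp
#> <nct_result> 500 permutations
#>   global strength: S = 0.230, p = 0.172
#>   structure:       M = 0.122, p = 0.355
```

The flow view says which symptoms carry the association with inhibitory
anxiety directly (in this simulated truth: anhedonia, sad mood and sleep)
and which connect only through them. The NCT p-values are
consistent with the two groups sharing one generating network, which is
how they were simulated.

`run_full_analysis(data, analysis_config(...), out_dir)` executes the
whole pipeline (descriptives → networks/centrality → flows → bootstraps →
stability → comparison → covariate sensitivity) and writes CSV/JSON
artifacts plus a manifest; identical config and seed give byte-identical
files.

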