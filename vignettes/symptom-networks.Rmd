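---
title: "Estimating and comparing symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`symptomnet` analyses ordinal questionnaire data — nine PHQ-9 depression
items scored 0–3 and, optionally, the two intolerance-of-uncertainty
dimension scores (prospective anxiety `AA`, inhibitory anxiety `IA`) on a
1–5 scale — as a Gaussian graphical model (GGM). Nodes are items; an edge
between items $i$ and $j$ is their partial correlation
$\rho_{ij} = -\theta_{ij} / \sqrt{\theta_{ii}\theta_{jj}}$, where $\Theta$
is the precision matrix. A zero entry of $\Theta$ means conditional
independence given all other items, so a sparse $\Theta$ is the network of
direct symptom–symptom associations.

$\Theta$ is estimated by the graphical lasso: maximize

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda \sum_{i \ne j} |\theta_{ij}|,$$

with $S$ the item correlation matrix and the $\ell_1$ penalty on
off-diagonals only. The penalty $\lambda$ is chosen by the extended
Bayesian information criterion,

$$\mathrm{EBIC}_\gamma = -2\,\ell(\Theta) + E \log n + 4 E \gamma \log p,$$

where $E$ is the number of nonzero upper-triangle precision entries,
$\ell(\Theta) = (n/2)(\log\det\Theta - \mathrm{tr}(S\Theta))$ up to an
additive constant, and $\gamma$ trades likelihood against extra sparsity.
The additive likelihood constant is dropped deliberately: EBIC is only ever
compared along a single penalty path, where constants cancel.

### Correlation input

The correlation matrix feeding the glasso is pairwise Spearman (average
ranks for ties), computed identically for the ordinal PHQ items and the
near-continuous IU dimension scores. The common alternative for ordinal
items, maximum-likelihood polychoric correlation, is deliberately not
implemented: it is much heavier numerically, fragile for sparse cells, and
rank correlation preserves the monotone associations the network model
uses. Users should know that Spearman correlations of coarsely discretized
items are attenuated relative to the latent scale, so edge weights are
conservative; the simulation suite quantifies what this costs (below). If
the Spearman matrix is not positive definite (possible with duplicated or
near-duplicated items), it is repaired by clipping eigenvalues at
$10^{-6}$ and rescaling to unit diagonal; the estimate carries a
`repaired` flag, and the repair is idempotent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC sparsity weight; 0 recovers plain BIC, larger values give sparser networks |
| `n_lambda` | 100 | penalty path length, log-spaced |
| `lambda_min_ratio` | 0.01 | smallest penalty as a fraction of $\lambda_{max} = \max_{i\ne j}|S_{ij}|$ |
| `boot_B` / `B` | 1000 | bootstrap resamples for edge intervals and difference tests |
| `curve_B` | 1000 | case-dropping resamples per drop fraction (200 is a reasonable fast setting) |
| `drop_grid` | 0.05–0.75 by 0.05 | case-dropping fractions |
| `n_perm` | 1000 | permutations of the comparison test |
| `cutoff` | 8 | PHQ-9 total at or above which a subject screens positive for depression |

The estimator defaults (`gamma = 0.5`, 100-point path, min-ratio 0.01) are
the long-standing conventions of this literature; none of them is fitted
to data. EBIC ties are broken toward the larger penalty, i.e. the sparser
model. Off-diagonal precision entries below $10^{-8}$ in magnitude are
snapped to exact zero so the edge count is well defined under floating
point.

## Node indices

* **Strength** $\sum_j |w_{ij}|$ and **expected influence**
  $\sum_j w_{ij}$; they coincide on all-positive networks and the
  difference is exactly twice the negative edge mass.
* **Closeness and betweenness** use the distance transform
  $d_{ij} = 1/|w_{ij}|$ on nonzero edges. Closeness is *harmonic*
  ($\sum_{j \ne i} 1/d(i,j)$, unreachable pairs contributing 0) so it stays
  well defined on disconnected networks; this deviates from classical
  closeness, which is undefined across components, and the two orderings
  can differ on fragmented networks. Betweenness is shortest-path
  betweenness with fractional credit for tied geodesics.
* **Predictability** is the in-sample $R^2$ of each item regressed on all
  remaining items — the share of a node's variance its neighbors explain.
* **Global strength** is the sum of absolute edge weights over the upper
  triangle, identically half the node-strength total.

The flow decomposition partitions the non-focal nodes into direct
neighbors of a focal node, successive breadth-first indirect layers, and
unreached nodes, and also reports the focal edges ranked by magnitude —
wording about "direct/indirect" symptoms in applied work sometimes means
the partition and sometimes the edge ranking, so both are exposed.

## Resampling machinery

Edge accuracy uses a nonparametric bootstrap of subjects with percentile
95% intervals; BCa intervals are not offered, matching the convention of
the field's bootstrap tooling for these models. Differences between edges
(and between node strengths or expected influences) are flagged
significant when the percentile interval of the bootstrap differences
excludes zero; deliberately, no multiple-testing correction is applied,
matching the descriptive use of these tests. The case-dropping bootstrap
re-estimates the network on subsets, correlates subset centralities with
the full-sample ones, and summarizes stability as the CS coefficient: the
largest drop fraction at which that correlation stays at or above 0.7 with
95% probability (0.25 is conventionally acceptable, 0.5 preferred). When
the full-sample network is empty — routine below roughly 100 subjects with
`gamma = 0.5` — the centrality vector is constant, every subset correlation
is undefined, and the CS coefficient is reported as 0 (no usable fraction)
or `NA` (no usable curve at all) rather than being silently invented.

The permutation comparison test (NCT) between two groups tests
global-strength invariance $S = |GS_A - GS_B|$ and structure invariance
$M = \max_{i<j} |w_{A,ij} - w_{B,ij}|$ by re-estimating both networks under
label permutations that preserve the two sample sizes. P-values are
one-sided exceedance with the +1 correction, $p = (1 + \#\{perm \ge
obs\})/(1 + n_{perm})$, hence never zero. The pooled rows are ordered
canonically (smaller group first, lexicographic tie-break), so swapping the
two arguments reproduces the identical permutation stream and p-values for
the same seed. Per-edge invariance tests with Holm correction are
available behind a flag but off by default, since $S$ and $M$ are the
primary statistics. When both IU dimensions are included the comparison
runs on the full 11-node network by default; 10-node variants (one
dimension at a time) are reachable by subsetting items.

## The synthetic-data generator

Because item-level survey data of this kind are typically not publicly
releasable, every pipeline stage is exercised on synthetic data with known
ground truth. The generator is a latent-Gaussian threshold model, the
standard generative model for ordinal psychometric items:

1. `make_true_network()` draws a sparse edge pattern (exact edge count
   `round(density * p(p-1)/2)`), weights uniform in `weight_range` with an
   optional negative-sign probability, and builds a positive-definite
   precision whose *realized* partial correlations match the drawn weights
   within 0.02 (diagonal inflation plus recalibration). Patterns with no
   positive-definite realization are rejected and redrawn from the seeded
   stream; a spec for which no draw succeeds raises a constructive-failure
   error. `scalable_to` restricts acceptance to truths that stay valid
   when all edges are multiplied by a planned group-scale factor.
2. `sample_ordinal_dataset()` draws latent multivariate-normal scores with
   the implied correlation, discretizes PHQ columns at per-item thresholds,
   and maps IU columns to 1–5 by a truncated affine transform. The default
   thresholds are calibrated so the marginal means and SDs of the nine
   items match the urban reference descriptives shipped with the package
   (strongly right-skewed, mostly-zero responses; the suicidal-ideation
   item the most so), with the mean weighted more heavily in the
   calibration objective.
3. `make_two_group_study()` emulates the reference two-group design
   (439 urban / 1049 rural by default) and injects a group difference as a
   uniform multiplicative scaling of all edge weights — the minimal
   mechanism that moves global strength without changing which edges
   exist.

What the generator does *not* emulate: item-level IU responses (only the
two dimension scores are modeled, as analyzed in practice), covariate
dependence of the network, differential item functioning between groups,
and non-monotone dependence. Passing simulation tests therefore show that
the pipeline recovers latent-Gaussian ordinal structure of realistic
marginals and size — not that any particular empirical dataset satisfies
those assumptions.

## Numerical choices

* Graphical-lasso convergence: mean absolute change of the working
  covariance below $10^{-6}$ times the mean absolute off-diagonal of $S$,
  capped at 500 sweeps (exceeding the cap is an error, not a warning).
  At $\lambda = 0$ the exact unpenalized solution $S^{-1}$ is returned.
* The coordinate-descent solver was cross-checked against an independent
  implementation and against closed forms: identity input, penalty
  dominance ($\lambda \ge \max|S_{ij}|$ gives the empty graph), the
  equicorrelation closed form $\rho = r/(1 + (p-2)r)$, and the
  $\lambda \to 0$ limit against inverse-covariance partial correlations.
* Degenerate inputs are contracts, not crashes: constant items are refused
  by name, non-symmetric matrices are refused by the repair, zero
  marginals are refused by the 2×2 test, a two-SD-zero t test returns 0
  (equal means) or a flagged infinite statistic, and unknown focal nodes
  or covariates are lookup errors.
* All resampling is seed-deterministic; stage seeds of the pipeline are
  derived from one master seed, and result files contain no timestamps, so
  identical configuration and data give byte-identical outputs.

## Design choices made where the design was open

* **Spearman, not polychoric**, as the correlation input (above).
* **Pooled-variance Student t** for the group comparisons: recomputing the
  reference table's statistics from its printed means and SDs reproduces
  the printed values within ±0.03 under pooled variance, and not under
  Welch — so pooled is what those summaries imply.
* **Uncorrected Pearson chi-square**: the printed gender statistic (1.11)
  is reproduced exactly without the Yates correction and not with it. The
  shipped reference counts for depression screening give a prevalence
  chi-square of 3.70; the corresponding published summary prints 4.09 and
  a rural prevalence of 40.1% where the counts give 39.9% — the package
  reports the exact values computed from counts and leaves the
  inconsistency in the source summaries documented rather than reproduced.
* **Listwise deletion** at read time, with dropped rows counted and
  reported: the conventional default of this toolchain; imputation is out
  of scope.
* **Covariate adjustment by node inclusion**: the covariate enters as an
  extra node and the symptom submatrix is returned, so each edge is
  additionally conditioned on the covariate. Residualizing items on the
  covariate first is a defensible alternative but is not the default.
* **CS coefficient read literally** as the largest qualifying drop
  fraction on the grid, 0 when none qualifies; it is computed separately
  for strength and expected influence, since which index the convention
  targets varies across applications.

## Problem sizes used by the test suite

The simulation checks run at the sizes the reference design implies:
null-calibration of the comparison test on 200 random 439/1049 splits of a
pooled sample of 1488 with 200 permutations each; power at a 1.5-fold
edge-weight difference with 1000 subjects per group over 50 replicates;
edge recovery at $n = 2000$ over 20 truths (density 0.3, weights 0.2–0.4,
$p = 9$); and case-dropping stability with 200 resamples per fraction at
$n = 2500$ and $n = 60$. The power replicates draw truths with weights
0.15–0.3 so that the 1.5-scaled group remains a valid GGM by construction.

## Known limitations

* EBIC selection with $\gamma = 0.5$ is not a false-positive guarantee: at
  large $n$ it admits small spurious edges once the likelihood gain from
  genuine structure pulls the selected penalty below the noise level of
  sample partial correlations. On density-0.3 truths at $n = 2000$ the
  package's simulations measure median specificity near 0.4–0.6 (ordinal
  and continuous data alike) at perfect sensitivity — an inherent property
  of the criterion confirmed against an independent implementation, not a
  solver artifact. Raising `gamma` trades those spurious edges against
  sensitivity. Interpreting individual weak edges is correspondingly
  discouraged; the bootstrap difference tests exist for exactly that
  reason.
* Spearman input attenuates latent edge weights for coarse ordinal items;
  absolute weights are not comparable with polychoric-based analyses.
* With ~60 subjects and 9+ nodes the selected network is typically empty;
  centrality and stability are then uninformative by design, not by bug.
* The NCT re-estimates networks per permutation with the full selection
  path, which is the computationally honest version of the test; very
  large `n_perm` on large samples is correspondingly expensive.
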