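---
title: "Methods: co-expression communities and single-gene classification with acode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression communities and single-gene classification with acode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`acode` implements a three-stage analysis of case/control expression data:

1. **Network construction.** Genes with flat profiles (sample SD at or
   below 0.1) are removed; Spearman correlations are computed among all
   remaining gene pairs, and every pair with signed correlation at or
   above 0.1 becomes a weighted edge. The threshold is deliberately low —
   the interesting structure is found afterwards, by community detection,
   not by the cutoff.
2. **Community detection (A-CODE).** Every edge seeds a greedy search
   that repeatedly absorbs the strongest edge touching the current
   community. Candidates are scored by *compactness* — the mean of the
   community's edge weights divided by their sample standard deviation —
   and filtered by an empirical permutation q-value.
3. **Classification.** A single gene's standardized expression feeds a
   ridge-penalised logistic model (penalty 1e-8 on the slope only),
   evaluated by leave-one-out cross-validated ROC/AUC with a
   label-permutation test against a random model, and transferable to
   independently standardized external cohorts.

This vignette records the modelling choices, the tunable parameters, the
behaviour of the permutation machinery (including a calibration property
the method does *not* have), and what the synthetic-data generator does
and does not emulate.

# The community search

## Compactness

For a candidate community with edge weights $w_1, \dots, w_k$,

$$\mathrm{compactness} = \frac{\bar w}{s_w},$$

the mean weight over its sample standard deviation ($n-1$ denominator).
Dividing by the spread penalises communities whose mean is driven by a
few strong but inconsistent correlations. A community whose weights are
identical has zero spread and is assigned $+\infty$, which sorts above
every finite value; in the permutation test a sentinel observed value is
exceeded only by sentinel null values. Spreads at the floating-point
cancellation level (relative variance below $10^{-13}$) are treated as
exactly zero.

## Greedy growth and the stopping rule

From a seed edge, the search repeatedly adds the neighbourhood edge of
maximal weight, where the neighbourhood is every network edge outside
the community touching at least one member gene. Ties are broken toward
the lexicographically smallest (gene1, gene2) pair, which makes the
whole pipeline deterministic. The q-value is evaluated at every size
from `min_edges` (default 5) to `max_edges` (default 20): the accepted
community is the greedy prefix at the *first* size whose q-value reaches
`min_q` (default 1e-4), extended while q stays at or below the cutoff;
growth stops just before the first size where q would exceed it. Seeds
whose component is exhausted before `min_edges`, or that never reach
`min_q` in range, yield nothing. With the default
`n_perm = 10000`, acceptance at `min_q = 1e-4` means at most one
permutation matched or beat the observed compactness.

Every edge is used once as a seed; accepted communities with identical
edge sets are merged, retaining all originating seeds. Communities are
ranked by q ascending, then compactness descending, then smallest
lexicographic gene set.

## Permutation nulls and a calibration caveat

Two null schemes are available for the per-size null compactness
distributions (cached once per size and shared across seeds; the
per-size random substream is derived deterministically as
`rng_seed + k`):

* `"subset"` (default): each null value is the compactness of `k` edge
  weights sampled uniformly without replacement from the network's full
  edge-weight multiset.
* `"growth"`: each permutation replays the greedy search itself from a
  uniformly drawn seed edge on a network whose weights were randomly
  permuted over the topology, recording compactness at every size.

The subset null asks "is this weight set unusually strong and
homogeneous relative to random weight sets?" — but the observed
community is not a random weight set: the greedy rule actively collects
the largest available weights. On networks whose weights are pure
i.i.d. noise, nearly every seed's greedy community beats all 10000
random subsets, so the nominal q is **not** a seed-level false discovery
rate: in our simulations at the default operating point (30-node,
100-edge uniform-weight networks), the fraction of noise seeds accepted
at `min_q = 1e-4` approaches 1. The q-value should therefore be read as
a *ranking score relative to random weight sets*, not as a calibrated
error rate — consistent with its practical use, where a large network
yields hundreds of "significant" candidates that are then ranked and
inspected.

The `"growth"` null fixes the calibration by exchangeability: under
i.i.d. weights the observed greedy statistic and the replayed null
greedy statistic are identically distributed, so acceptance at `min_q`
occurs at rate about `2/(n_perm + 1)`. The price is power: because the
greedy rule extracts the top of the weight multiset on the permuted
network too, a genuinely coherent module is barely distinguishable from
its own shuffled weights, and in our planted-module simulations nothing
survives `min_q = 1e-4` under this null. No null that preserves the
weight multiset can be simultaneously calibrated against greedy
selection and sensitive to planted structure with this statistic; the
package keeps the permissive subset null as the default (matching the
method's reference behaviour) and offers the growth null for users who
need a strict error rate.

## Consolidating communities into modules

A single community is capped at `max_edges` edges, so it can cover at
most `max_edges + 1` genes and in practice far fewer (greedy growth
concentrates on the strongest gene pairs; a 20-edge community typically
spans 11–15 genes). A larger co-expressed module therefore appears as
many overlapping accepted communities. `merge_communities()`
consolidates them by *seed closure*: starting from the top-ranked
community, a module repeatedly absorbs any community seeded on what is
effectively one of the module's own edges — both seed endpoints already
member genes, or one endpoint a member and the seed weight no weaker
than the module's weakest member edge. The strength condition is taken
from the module's own observed weight range, so the rule has no tuning
parameter. It deliberately excludes communities seeded on weak edges
elsewhere whose greedy growth merely wandered into the strong region
(such "run-in" candidates are common, because the permissive subset
null accepts them); absorbing those would dilute the module with their
entry trails.

# The classifier

`fit_ridge_logistic()` maximises the binomial log-likelihood minus
`ridge * coefficient^2` by Newton/IRLS (intercept unpenalised;
convergence when the coefficient step falls below 1e-10, at most 100
iterations). At the default `ridge = 1e-8` the penalty is numerically
immaterial away from separation — the fit agrees with `glm()` to six
decimals — but it guarantees a finite maximiser on separable data.

AUC is the normalised Mann–Whitney statistic (ties get half credit);
the ROC curve thresholds at every distinct score with tied scores
grouped, so the trapezoidal area of the curve equals the AUC exactly.
Significance against a random model uses a label-permutation test with
add-one correction, `p = (1 + #{permuted AUC >= observed}) / (1 +
n_perm)`, which cannot return zero and hits its floor `1/(n_perm + 1)`
on perfectly separated data; a one-sided tie-corrected normal
approximation to Mann–Whitney is available as
`method = "rank_approximation"`.

## LOOCV pooling and its null bias

`loocv_auc()` fits on each leave-one-out training set and pools the
held-out predicted probabilities into one ROC — the only coherent
aggregation for leave-one-out. Users should know a subtle property of
this estimator: the training class balance of each fold depends
deterministically on the held-out label (a held-out case leaves
`n_case - 1` cases behind), so the fold intercepts alone shift all case
predictions slightly down and all control predictions slightly up.
When the feature carries no signal, this offset dominates the ranking
and the pooled AUC is biased *below* 0.5 — in simulations at
n = 200/200 the null LOOCV AUC averages about 0.38 and can reach 0. The
bias is pessimistic, never optimistic, so a high LOOCV AUC remains
trustworthy; but the estimator should not be used as evidence that a
marker is *uninformative*. With an informative marker (a 2-SD shift,
theoretical AUC $\Phi(2/\sqrt 2) \approx 0.921$) the pooled estimate
lands within a few hundredths of the closed form.

Cross-dataset transfer standardizes each dataset with its own mean and
SD per gene, which places cohorts on a common scale without touching
the frozen model.

# The synthetic-data generator

`generate_dataset()` emulates the structure of a two-group cardiac
transcriptome study with planted co-expression. For gene $g$ in module
$m$ and sample $s$:

$$x_{gs} = a_g F_m(s) + \varepsilon_{gs}, \qquad
F_m(s) \sim N(0,1),\; a_g \sim U(\mathrm{lo}, \mathrm{hi}),\;
\varepsilon_{gs} \sim N(0, \sigma^2),$$

with background genes pure noise and marker genes additionally shifted
in case samples by `d` times their realized pooled within-class SD (so
`d` connects directly to the theoretical AUC $\Phi(d/\sqrt 2)$). The
single-factor form is the simplest generator with controllable pairwise
correlation, $\rho_{ij} = a_i a_j / \sqrt{(a_i^2+\sigma^2)(a_j^2+\sigma^2)}$;
at the default loadings the Spearman/Pearson distinction is immaterial
under Gaussian noise.

Defaults are the reference study design, chosen once: 36 case / 23
control samples; one 18-gene module with loadings 0.85–0.95, which at
the default `noise_sd = 0.3` gives within-module correlations near 0.9,
matching the strong reported communities; and 150 background genes, so
the thresholded network lands near the reference network's scale
(about 170 connected nodes and a few thousand edges).

What the generator does **not** emulate: probe-level microarray noise,
batch effects, time-course structure within the case group, correlated
background genes, or heavy-tailed expression distributions. Passing the
planted-structure tests therefore demonstrates algorithmic correctness
and statistical behaviour under the factor model, not performance on
real microarray data with unknown preprocessing.

`generate_null_network()` draws a simple random graph with i.i.d.
uniform weights and is used only to probe the behaviour of the
community search under pure noise.

# Numerical and design notes

* Spearman correlation uses average ranks for ties (Pearson on ranks),
  computed by `stats::cor`. Vectors of length < 3 or constant vectors
  are rejected.
* The edge threshold is applied to *signed* correlation by default;
  `absolute = TRUE` thresholds the magnitude instead. The default
  follows the method's definition literally, and all strong reported
  communities are positively correlated.
* Path length and clustering are computed on the unweighted skeleton
  (igraph); disconnected networks average geodesics over connected
  pairs with a warning; degree < 2 nodes contribute 0 to mean
  clustering (set `exclude_low_degree = TRUE` to drop them instead).
* Duplicate gene IDs on input collapse to the highest-variance row;
  rows with missing values are dropped and counted. Matrices are used
  on the scale supplied; no log transform is applied.
* Null banks use running-sum moments; relative variances below
  `1e-13` are treated as exact zeros (the compactness sentinel).
* All randomness flows through explicit integer seeds; identical
  inputs and seeds give byte-identical reports, and no function
  perturbs the caller's RNG state.

## Problem sizes used by the test-suite and acceptance script

The shipped validation runs are sized for quick, repeatable execution:
ten replicate synthetic studies (168–170 network genes, ~3000 edges,
10000 permutations per community size), ten 100-edge noise networks for
the acceptance-rate measurement, classifier cohorts of 200/200 samples,
and small enumerable fixtures (an 8-edge network whose 56 weight
subsets are enumerated exactly) for the permutation machinery.

# Known limitations

* The nominal community q is not a seed-level FDR under the default
  null (see above); treat it as a ranking score.
* Pooled LOOCV AUC is pessimistically biased at the null (see above).
* The GEO reader parses only the series-matrix sample-table block; SOFT
  full-format files and probe-to-gene annotation are out of scope.
* Exact reproduction of results derived from externally preprocessed
  microarray data depends on that preprocessing, which is not part of
  this package.
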