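---
title: "Methods: distance-based cryptic species delimitation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based cryptic species delimitation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crypticscan` implements a delimitation procedure for a single aligned
mitochondrial locus: p-distance structure, consensus clustering with
data-driven cluster-number selection, and cross-validated classification
with per-site importance. This vignette documents the model assumptions,
the tunable parameters, the numerical choices, and what the package's
synthetic calibration does and does not demonstrate.

## The distance model

All genetic distances are uncorrected p-distances with *pairwise
deletion*: for a pair of aligned sequences, every column where either
member carries a gap (`-`) or a non-ACGT IUPAC symbol is removed for that
pair, and the distance is the fraction of mismatches over the remaining
`n_valid` columns. This matches the pairwise-deletion semantics of the
standard distance software used in molecular taxonomy. Distances are
proportions in [0, 1] throughout; percentages appear only in reports. A
pair with no overlapping unambiguous site has no defined distance and is
treated as an error rather than silently imputed.

No substitution-model correction (JC69, K2P) is applied: the delimitation
logic rests on *relative* distance levels (intra- versus inter-group), and
model corrections are monotone at the short distances involved
(within-group means of order 0.01, between-group of order 0.1).

The working assumption inherited from the study design is that a cryptic
species manifests as a bimodal distance structure: within-group distances
at the intra-specific level, between-group distances at or above the
inter-specific level defined by a pair of accepted species. The
`group_distance_sets()` summary exposes exactly those two families of
distance sets; within-group lists contain each unordered pair once
(`m(m-1)/2` values for `m` members — plotting conventions that count both
orientations double these cardinalities without changing any mean).

## Clustering and consensus

Five algorithms partition the same upstream object, chosen so that a
method disagreement is informative rather than an artifact of different
inputs:

* **k-means** (Lloyd, best of `n_init = 10` seeded restarts) and
  **Brunet NMF** consume the rows of the p-distance matrix — each sequence
  described by its distance profile;
* **complete-linkage hierarchical clustering** and **DBSCAN** consume the
  matrix as a precomputed metric;
* **affinity propagation** consumes the similarity `1 − p`. The
  similarity is pinned to `1 − p` because only its monotone relation to
  the p-distance matters; this is the simplest choice preserving [0, 1].

DBSCAN's defaults (`eps = 0.5`, `min_pts = 20`, the point itself counted)
follow the original protocol, but `eps = 0.5` is meaningful only on
min–max-scaled distances — raw control-region p-distances rarely exceed
0.1, and an 0.5 radius on the raw scale would merge everything. The
pipeline therefore scales the off-diagonal distances to [0, 1]
(`ScaleD = (D - min D)/(max D - min D)`) before DBSCAN; the constant-vector
degenerate case maps to all zeros rather than erroring, so trivial
fixtures pass through. Brunet NMF uses KL-divergence multiplicative
updates; the update is monotone (non-increasing divergence), restarts only
matter near degenerate optima, and the restart count is configurable
(`nrun`; the original protocol used 1000, the pipeline default uses far
fewer because on two-block distance matrices every restart converges to
the same partition). Affinity propagation uses the median off-diagonal
similarity as its shared preference — the conventional default that lets
the cluster number emerge from the data — with damping 0.9 and a tiny
seeded jitter to break exact symmetry ties, as reference implementations
do.

Labels follow the R convention: integers `1..k`, with `0` reserved for
DBSCAN noise. The consensus aligns every partition to the hierarchical
result (deterministic given the matrix) by maximal-overlap label matching
(exact over all assignments up to 7 clusters, greedy beyond), then takes a
per-sequence majority vote; noise points cast no vote. A tie is flagged
and resolved by the hierarchical label — ties are degenerate here because
the procedure is designed for data where methods nearly agree, and a
deterministic rule keeps reruns identical. Agreement is reported as the
pairwise adjusted Rand index over points that are noise in neither
partition; `unanimous` means all pairwise ARI equal 1.

## Choosing the number of clusters

The validity curve evaluates, at each k over seeded k-means partitions of
the distance profiles:

* `SSE(k)`, the within-cluster sum of squared errors;
* the mean silhouette `s_i = (b_i − a_i)/max(a_i, b_i)`, with `s_i = 0`
  for singleton clusters (the standard convention; a singleton has no
  within-cluster scale);
* the gap statistic, `gap(k) = mean_b log W_k(ref) − log W_k(data)` with
  `B` uniform reference draws over each feature's observed range and
  `se = sd·sqrt(1 + 1/B)`. `B = 100` gives standard errors far below the
  gap increments seen here; the original protocol's `B = 1000` changes
  nothing but runtime.

Decision rules: the **elbow** is the k maximising the second forward
difference of `log SSE`. The log scale is a deliberate choice: SSE spans
orders of magnitude across k, and the absolute second difference is
dominated by the k = 1 term (total variance), which provably prevents it
from ever selecting k = 3 on clean three-cluster data with a large first
drop; relative curvature selects the visually obvious inflection in both
two- and three-group calibrations. The **silhouette** criterion is the
argmax of the mean silhouette. The **gap** criterion applies the 1-SE
rule (smallest k with `gap(k) ≥ gap(k+1) − se(k+1)`). `k_best` is the
majority over the three, ties resolved toward the elbow.

On tightly clustered sequence data the gap curve typically *keeps rising*
with k — the uniform reference loses dispersion slower than near-duplicate
real data — so the 1-SE rule often selects nothing small and the criterion
honestly reports that, while the curve's dominant increment still sits at
the true k. This mirrors how the gap statistic behaved in the motivating
analysis, where the well-separated cluster number was read from the
elbow/silhouette inflection instead. The full curve is always reported,
never just an argmax.

## Classification stage

Sequences are ordinally encoded (A=1, T=2, C=3, G=4, gap=0; N and other
ambiguity codes also 0, since the encoding defines no rank for them and 0
is its missing-data sink). The encoding is kept as-is — no one-hot
expansion — which is a known limitation: it imposes an arbitrary metric
(A closer to T than to G), and the tree-based model is the only one truly
indifferent to it.

Three models are trained on the encoded matrix, every stochastic element
seeded: a 500-tree random forest (`sqrt(m)` features per split); an
RBF-kernel SVM with Platt probability estimates (inputs left unscaled —
the encoding already lives on a fixed 0–4 range); and a single-hidden-layer
MLP (100 units, ReLU, sigmoid output) trained by minibatch stochastic
gradient descent on the log-loss with L2 penalty `1e-4`, inputs
standardised internally, no early stopping (determinism). The MLP is
implemented in-package so that its training procedure is exactly the
stated one (SGD on log-loss) and bit-reproducible under the master seed.

Evaluation is stratified 5-fold cross-validation — stratified rather than
plain random because a 65/30 imbalance can otherwise yield single-class
test folds; fold sizes differ by at most one. Per fold and per model:
precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1, and ROC AUC computed by
the rank (Mann–Whitney) formulation with ties counted one half. Per-fold
metrics, their mean/sd, and the summed confusion matrix are all reported.

Site importance is the normalised mean decrease in Gini impurity of a
random forest fitted on *all* sequences (no held-out split — the profile
describes the data, not generalisation). `key_sites()` applies strict
thresholds (`> 0`, `> 0.1` by default) and returns 1-based alignment
columns sorted by importance; `logo_data()` attaches per-column A/C/G/T/gap
frequencies for logo rendering, with ambiguity codes counted in the gap
bin.

## The synthetic-data generator

`simulate_alignment()` emulates the statistical shape of a two-group
control-region dataset: a uniform-random ancestor; one founder per group,
each site mutated with probability `d_between` (uniform choice among the
three alternative bases — a Jukes–Cantor-like, site-independent model,
the simplest consistent with a model-free p-distance analysis); individuals
mutated off their founder at `d_within`; `n_diagnostic` planted columns
overwritten with fixed, distinct, within-group-monomorphic bases; gaps
injected at `gap_rate` outside planted columns. Defaults — 733 columns,
group sizes 65/30, `d_within = 0.005`, `d_between = 0.05`,
`gap_rate = 0.005`, six diagnostic columns — copy the shape of the real
dataset the procedure was designed around; the divergence rates are
calibration choices (the motivating study reports boxplots, not numbers)
placing the within-group mean near 0.01 and the between-group mean near
0.11, a 10x contrast typical of cryptic-species reports.

Closed-form expectations back the calibration tests: an edge with
mutation probability p scales the non-identity eigenvalue by `1 − 4p/3`,
so sequences separated by edges `p_1..p_k` differ per site with
probability `(3/4)(1 − Π(1 − 4 p_i/3))`; within-group paths are
`(w, w)`, between-group paths `(w, b, b, w)`, planted columns always
differ between groups and never within.

Two properties of real data the generator deliberately does **not**
emulate. First, rate heterogeneity and indel evolution: gaps are
i.i.d. noise, not evolutionary events. Second — and consequentially —
between-group divergence under this model arises at ~70 random founder
substitutions across the alignment, of which ~30 survive within-group
noise as clean fixed differences. The planted diagnostic columns are
therefore *not* statistically privileged: a random forest spreads
importance over all fixed differences (typically ~100 sites with positive
importance, none dominant), and the top-6 importance columns are an
essentially random draw from the clean fixed differences. Passing
end-to-end tests consequently demonstrate partition recovery, correct
cluster-number selection and classifier separation — not that importance
ranking singles out the planted six. Real control regions, where
divergence concentrates in hypervariable stretches and sites differ in
cleanliness, are precisely the situation where the importance profile
becomes selective; the simulator's uniform substitution model is the
worst case for it. Every planted site does receive positive importance,
which is what the tests assert.

## Reproducibility and numerical details

* One master seed drives everything; each stage derives a fixed offset
  seed. Reruns of `cryptic_scan()`, `run_pipeline()` and the acceptance
  script are bit-identical (checksum-tested).
* `log W_k` is guarded against zero dispersion (`max(W, 1e-300)`); the
  gap SE is defined as 0 at `B = 1`.
* Min–max scaling of a constant vector returns zeros; silhouette of a
  single overall cluster, an empty distance list, and a pair with no
  comparable sites are errors, not NaNs.
* k-means restarts use `nstart` inside one seeded call; `k` above the
  number of distinct rows is rejected with a message.
* Problem sizes in the test-suite calibrations: the full 95 x 733 default
  condition for the acceptance checks (gap `B = 100`, NMF `nrun = 20`),
  and reduced 24/12 x 250 variants for the per-module end-to-end tests;
  these sizes were chosen to exercise the same shape at interactive
  runtimes.

## Known limitations

* Single-locus, distance-based evidence only: no tree-based delimitation
  (GMYC/bPTP), no coalescent model, no nuclear corroboration. The output
  is a *putative* cryptic group for downstream taxonomic work.
* Ordinal encoding imposes an arbitrary base metric (see above).
* The gap statistic's 1-SE rule is uninformative on near-duplicate
  sequence data; the majority rule covers this, but a user selecting by
  gap alone should read the full curve.
* Random-forest hyperparameters are sensible defaults, not tuned; the
  importance profile depends on them only weakly but the exact key-site
  counts do vary with seed and tree count.
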