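# crypticscan

Delimitation of putative cryptic species from aligned mitochondrial
sequences.

Cryptic species are lineages that are genetically distinct but nearly
indistinguishable morphologically — a recurring situation in sharks and
other fishes, where a "single" species sampled across its range can hide
two diverged mitochondrial lineages. `crypticscan` takes one aligned locus
(typically the fast-evolving control region, or *COI*/*ND2*) and asks, in
a reproducible pipeline:

1. **Do the sequences fall into distance-separated groups?**
   Pairwise p-distances are computed with pairwise deletion: for each pair
   of sequences the proportion of differing sites over the sites where
   neither carries a gap or ambiguous base,
   `p = n_mismatch / n_valid`. Within- and between-group distance sets and
   averages quantify whether candidate groups sit at the intra- or
   inter-species distance level.
2. **Is the grouping robust?** Five clustering algorithms — k-means,
   complete-linkage hierarchical clustering, Brunet non-negative matrix
   factorisation (KL-divergence multiplicative updates), DBSCAN on the
   min–max-scaled distance matrix, and affinity propagation on the
   similarity `1 − p` — are run on the same distance object and combined
   into a consensus partition; agreement is measured by the adjusted Rand
   index.
3. **How many groups?** The cluster number is selected from a validity
   curve by three criteria: the elbow of the within-cluster
   `SSE = Σ_i Σ_{p∈C_i} ||p − m_i||²`, the mean silhouette
   `s_i = (b_i − a_i)/max(a_i, b_i)`, and the gap statistic
   `gap(k) = E*[log W_k] − log W_k` against uniform reference samples,
   with majority vote across criteria.
4. **Can new sequences be assigned?** The alignment is ordinally encoded
   (A=1, T=2, C=3, G=4, gap/ambiguity=0) and three classifiers — random
   forest, RBF support-vector machine, and a single-hidden-layer
   multilayer perceptron trained by SGD on the log-loss — are evaluated by
   stratified 5-fold cross-validation (precision, recall, F1, ROC AUC).
   A random forest fitted on all sequences yields a per-site importance
   profile (normalised Gini impurity decrease) that pinpoints the key
   diagnostic sites, with per-column base frequencies exported for
   sequence-logo rendering.

A seeded simulator generates control-region-like alignments with planted
group structure (shared ancestor, per-group founders, within-group noise,
diagnostic columns, sparse gaps), so the whole pipeline is testable and
calibratable without any sequence downloads.

## Worked example

```r
library(crypticscan)

sim <- simulate_alignment(sim_config(seed = 42))   # 65/30 groups, 733 bp
sc  <- cryptic_scan(sim$alignment, seed = 1, nmf_nrun = 20)
print(sc)
```

```
Cryptic-species scan
  95 sequences x 733 columns, master seed 1
  clusters k = 2 (elbow 2, silhouette 2, gap NA)
  consensus partition: [65/30], all five algorithms agree
  putative cryptic group: cluster 2 (30 sequences)
  rf   CV mean AUC 1.000 (sd 0.000)
  svm  CV mean AUC 1.000 (sd 0.000)
  mlp  CV mean AUC 1.000 (sd 0.000)
```

Reading the output: the elbow and silhouette criteria both select two
clusters (the gap statistic's 1-SE rule reports none on such tightly
clustered data — its curve keeps rising, with its dominant jump at k = 2);
all five algorithms return the identical 65/30 partition; the smaller
cluster is flagged as the putative cryptic group; and all three
cross-validated classifiers separate the two groups perfectly (AUC 1.0).
`summary(sc)` adds the full validity curve and group distance averages,
`plot(sc)` draws the three criterion curves and the importance profile,
and `predict(sc, new_alignment)` scores new sequences. On this run

```r
key_sites(sc$importance, thresholds = 0)[["0"]]$count
#> 96
```

96 of 733 sites carry positive importance — group divergence is spread
over all fixed differences between the founders, not only the six
guaranteed diagnostic columns planted by the simulator.

For real data, start from a file:

```r
sc <- cryptic_scan(read_alignment("control_region_aligned.fasta"),
                   seed = 1, reference_id = "new_specimen")
```

or use the file-based pipeline / CLI, which writes TSV reports and a JSON
run manifest:

```r
run_pipeline("aln.fasta", "out/", seed = 1)
```

```sh
Rscript inst/scripts/crypticscan.R run --input aln.fasta --out out --seed 1
```

Alignments are consumed pre-aligned (e.g. `mafft --auto raw.fa > aln.fa`).

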