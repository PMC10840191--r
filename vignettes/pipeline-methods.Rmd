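---
title: "Methods: an HDAC-inhibitor embryo transcriptome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an HDAC-inhibitor embryo transcriptome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgapipe)
```

# Scope and data model

`zgapipe` re-implements, as composable tested functions, a microarray
transcriptome workflow for pre-implantation mouse embryos treated with
selective histone-deacetylase inhibitors (HDACi; a Class I inhibitor such as
MGCD0103 and an HDAC3-selective inhibitor such as T247). The design is a
stage x treatment grid (MII oocyte, 1-cell, 2-cell, 4-cell; control and two
inhibitors) with replicate pools of embryos hybridized to a two-color
expression array. The pipeline runs from probe-level signal tables to:

* a normalized gene x sample log2 expression matrix with PCA,
* per-contrast differentially expressed genes (DEGs) and their
  treatment-pattern groups,
* over-representation and ranked gene-set enrichment with redundancy
  reduction,
* a Jaccard similarity network over enriched terms with automatic cluster
  annotation,
* dense-module detection and hub-gene ranking on a gene-interaction graph,
* classification of genes into programmed expression waves (maternal, minor
  zygotic genome activation (ZGA), major ZGA, mid-preimplantation gene
  activation (MGA)) with Fisher contingency tests against DEG direction,
* promoter epigenetic-mark enrichment from scored interval tracks.

Because the real study data live in external repositories, the package ships
a synthetic-data generator that emulates the *structure* of all inputs with
planted ground truth; every downstream stage is validated against what was
planted.

# Preprocessing

**Flag filtering and probe collapsing.** Only spots flagged
`"positive and significant"` count as observed; everything else is missing.
A probe is a *valid detection* in a condition (stage x treatment) when at
least one of its replicates is observed, and only probes valid in every
condition are kept. When one gene is covered by several probes, the probe
with the highest mean log2 signal over the retained samples represents the
gene. The mean-aggregation is a package decision: the rule "highest signal
intensity" does not by itself say how to aggregate across samples, and the
mean is symmetric across conditions.

**Imputation.** Missing entries are filled by the median of the observed
replicates of the same condition, falling back to the gene's row median when
a condition has no observation. Median imputation is robust to outliers,
reproduces constant rows exactly, and never touches observed values. The
imputer sits behind a single function (`impute_missing()`) so an alternative
can be swapped in.

**Global-distribution test.** Before normalizing we test whether sample-level
signal *distributions* differ between condition groups: each sample is
reduced to its sorted value vector, and a quantile ANOVA F-ratio (between-
over within-group variability of the quantile vectors) is calibrated by
permuting group labels (default 1000 permutations; the permutation p-value
is never smaller than `1/(n_perm + 1)`). This implements the same contract
as published quantile-distribution tests without reproducing any specific
package's statistic.

**Smooth quantile normalization.** When distributions differ by group, full
quantile normalization would erase real global effects. `qsmooth_normalize()`
replaces each sample's sorted values with
`w * q_overall + (1 - w) * q_group`, where for quantile k the weight is
`w_k = 1 - SSB_k / SST_k` (between-group over total variability of that
quantile across samples), median-smoothed along k (window 5% of the quantile
index) and clipped to `[0, 1]`. Identically distributed groups drive `w`
toward 1 (plain quantile normalization); genuine group differences keep
weight on the group reference. Within-sample ranks are preserved exactly; a
single-sample group has itself as its group reference.

# Differential expression and pattern groups

`fit_degs()` fits an ordinary least-squares one-way model per gene over the
condition groups and tests a treated-minus-control contrast with a two-sided
t-test on the pooled residual variance. There is deliberately **no**
empirical-Bayes variance moderation: the implementation covers exactly the
stated linear-model-plus-least-squares procedure, and the two-condition
equal-n case reduces to the classical equal-variance t-test (checked to
1e-12 in the tests). P-values are Benjamini-Hochberg adjusted; a gene is
`up` when `LFC >= 1` and adjusted p < 0.05, `down` under the mirrored rule.

DEG pattern groups mirror the published analysis step that separated
"common", "T247" and "MGCD0103" effects. Clustering only proceeds when the
Hopkins statistic of the standardized DEG profiles reaches 0.75 (below that
the data are treated as unclustered). The cluster count comes from the
elbow rule (second difference of the within-cluster sum of squares) and can
be cross-checked with the gap statistic (uniform column-range reference
sets, one-standard-error rule). Ward minimum-variance (`ward.D2`)
hierarchical clustering on Euclidean distances of row-standardized profiles
is cut at k, and each cluster is labeled algorithmically from the sign
pattern of its mean log2 fold changes: differential in both treatments =>
`common`, in exactly one => that treatment's group. The original study
assigned these labels by visual inspection; making the rule algorithmic
(threshold: cluster-mean |LFC| at least 1) keeps it reproducible. Genes are
standardized before clustering because pattern clustering should be
scale-free.

# Enrichment

Over-representation uses the upper-tail hypergeometric test against the
detected-gene universe with BH control. Ranked enrichment (`gsea_rank()`)
implements the weighted running-sum statistic: hits increment by
`|score|^w / sum(|score|^w)` (default exponent 1), misses decrement by
`1/(N - n)`, and the enrichment score (ES) is the maximum deviation of the
running sum. The null permutes gene labels — a sample permutation is
impossible when the ranking comes from principal-component loadings — and
the normalized score is `NES = ES / mean(|ES_perm|)` over same-sign
permutations with an empirical same-sign p-value. Core ("leading edge")
genes are the hits before the peak for positive ES, after it for negative.
Set-size bounds default to 15-500 in spirit (5-500 in code, configurable);
ranking ties break by stable input order.

Redundancy among significant terms is reduced in-house rather than through
an external web service: a greedy pass in order of ascending adjusted p
drops any term whose gene-set Jaccard similarity to an already retained term
reaches 0.7 (default). This is self-contained, monotone, and consistent
with the Jaccard machinery the term network uses anyway.

# The enriched-term network

`build_term_graph()` computes the complete Jaccard adjacency over the
retained terms' gene sets, flagging edges where one set contains the other
(inclusion is invisible to the Jaccard coefficient alone). The published
method clusters this adjacency matrix with "K-median"; on a similarity
matrix the natural reading is k-medoids (PAM) on the distance `1 - J`, which
is what `cluster_term_graph()` does, after the same Hopkins gate as above
(no structure => every node `"not categorized"`). Any cluster whose mean
pairwise Jaccard similarity is below 0.05 is dissolved into
`"not categorized"`; singleton clusters count as mean 0. The layout is
Fruchterman-Reingold with Jaccard edge weights as attraction; "outlier"
nodes are defined as nodes with no incident edge of weight >= 0.05 —
consistent with the merge rule — and are dropped from the drawn layout while
staying in the exported data. Node size is `-log10(p)`.

Cluster annotation follows the published three-feature scheme. The corpus
is the set of term definitions; TF-IDF (`tf = token share`,
`idf = ln(N/df)`) yields each term's representative vocabulary (top 5 words
by default). Candidates are 1- and 2-grams over member term *names* after
stop-word removal (a small shipped list of English function words plus
ontology boilerplate such as "process" and "involved"). Each candidate is
re-scored as `0.5 * freq + 0.3 * minp + 0.2 * repr` on normalized features:
name-frequency, `-log10` of the lowest enrichment p among member terms whose
name contains the candidate, and a representativeness flag (any candidate
word in any member's TF-IDF vocabulary). The exact weighting was left open
by the source method, so the weights are configurable and the raw features
are exported for audit; the chosen label is the top of the top-3 candidates.

# Interaction modules and hub genes

`detect_modules()` implements the molecular-complex-detection (MCODE)
scheme with the published defaults (degree cutoff 2, node score cutoff 0.2,
k-core 2, haircut on, fluff off): node weight = density of the highest
k-core of the closed neighbourhood times that core number; greedy expansion
from the best unused seed admits neighbours within 20% of the seed weight;
modules lacking a 2-core are discarded, singly-connected members trimmed;
the module score is density x size. Edge confidence weights are available
as a pre-filter (`as_gene_network(min_weight=)`) but the algorithm itself is
unweighted, as in the original.

Hub ranking uses the four local centralities — degree; MNC (largest
connected component of the neighbour-induced subgraph); DMNC (edges of that
component over nodes to the power 1.7); MCC (sum over maximal cliques
containing the node of `(|C|-1)!`, reducing to the degree when the node sees
only 2-cliques) — aggregated by the robust-rank-aggregation rho score:
per item the sorted normalized ranks give `beta_k = P(Bin(L, r_k) >= k)`,
`rho = min_k beta_k`, Bonferroni-corrected by the number of lists. Tied
centrality profiles receive tied ranks so that fully symmetric modules
produce fully tied hubs; the top two nodes (ties broken by degree, then id)
are flagged as hub genes.

# Waves and epigenetic features

`classify_waves()` soft-clusters per-gene stage profiles (standardized
across the four stages MII, 1-cell, 2-cell, 4-cell) with an in-package
fuzzy c-means (fuzzifier m = 2, tolerance 1e-6; the objective trace is
exposed and non-increasing, and the implementation is cross-checked against
an independent one in the tests). The published default of c = 25 clusters
is kept as the function default; the recovery analyses in this package use
c = 8 on 4-point profiles, where 25 clusters would shatter the four planted
shapes. Clusters map to waves either through a user-supplied map (the
primary interface, mirroring the original inspection-based assignment) or
automatically by correlating cluster centroids with the wave stage-profile
templates (`wave_templates()`): maternal decays monotonically from the
oocyte, minor ZGA peaks at the 1-cell stage, major ZGA at the 2-cell stage,
MGA rises afterwards; centroids correlating below 0.8 with every template
become `other`.

DEG direction versus wave membership is tested with the two-sided Fisher
exact test. The default builds the standard disjoint 2x2 table
(in-wave / not-in-wave columns). A second construction,
`table_style = "group_total"`, places the whole DEG-set size in the second
column — the "k out of n" tabulation that published contingency analyses
sometimes use; the package reproduces published p-values under that
construction while keeping the disjoint table as the statistically
conventional default.

Promoter scores sum interval scores over the strand-aware window around the
TSS (default +/-1 kb for histone marks; accessibility and methylation
windows like (-200, +100) are configurable and reflected across the TSS for
minus-strand genes). Intervals contribute proportionally to their overlap
fraction with the promoter; a full-score-on-any-overlap mode exists because
the source procedure only says scores are "summed". The top 1000 genes per
mark (ties at the boundary broken by gene id, for determinism) form the
strongly associated set; DEG sets are tested against them with the
upper-tail hypergeometric test, BH-adjusted across all (DEG set, mark)
pairs, significant at adjusted p < 0.01. No cross-mark normalization is
applied: only within-mark rankings matter.

# The synthetic study

`synth_config()` fixes the simulated conditions: 2000 genes, 1-3 probes per
gene, 4 stages x 3 treatments x 3 replicates, 5% planted DEGs with |log2
fold change| 2 at the 2-cell stage, waves in proportions
maternal/minor/major/MGA/other = 0.20/0.10/0.15/0.10/0.45, spot missingness
5%, log2-scale noise SD 0.3. Signals are drawn log-normal so the log2 scale
has Gaussian noise (the standard microarray noise model); missingness is
independent per spot; flags use the Agilent vocabulary so the filter parses
realistic strings. Replicate variance and the noise model are not published
for the original data, so these defaults were chosen once as typical
microarray magnitudes that make recovery tests meaningful, and are not
tuned thereafter. Wave templates are piecewise stage means implementing the
verbal wave definitions; planted near-clique interaction modules (sizes
10-12, density 0.9-1.0) sit on an Erdos-Renyi background (p = 0.01); planted
promoter-mark associations add high-score intervals inside the promoters of
planted DEGs of one direction.

What the generator does *not* emulate: scanner-level artifacts, dye effects,
probe sequence biases, correlated missingness, batch structure, or any
numerical mimicry of the deposited study data. Recovery results on this
synthetic data therefore demonstrate the pipeline's internal correctness and
calibration, not field performance on real arrays.

# Numerical choices and problem sizes

* Permutation p-values are `(1 + #extreme) / (1 + #permutations)`, never 0.
* Hopkins uses 10% of rows (minimum 5) as probes; degenerate zero-volume
  bounding boxes are an error.
* k-medoids medoid ties and top-N boundary ties break lexicographically;
  ranking ties in GSEA break by stable input order.
* Fuzzy c-means handles zero distances by assigning full membership to the
  coincident centroid(s).
* All randomness flows through explicit integer seeds; every generator and
  stage is byte-reproducible given (config, seed).
* The validation suite runs the full pipeline at 2000 genes (the study
  scale) for recovery checks and 200-600 genes for calibration loops
  (40-100 seeds per loop, 200-1000 permutations per test); exhaustive
  centrality oracles cover all 64 graphs on 4 nodes plus randomized graphs
  on 5-8 nodes. These sizes are the package's own choice of a thorough but
  proportionate test plan.

# Known limitations

* The per-gene linear model offers no variance moderation hook yet; genes
  with near-zero residual variance rely on the LFC threshold to avoid
  spurious calls.
* The enriched-term clustering operates on the Jaccard matrix only; no
  information-content or graph-topology similarity is available.
* The GSEA permutation null is gene-label based; with very small
  collections the BH-adjusted permutation floor limits attainable
  significance (use more permutations for small collections).
* MCODE's greedy expansion can absorb weaker members of overlapping dense
  regions into the first-seeded module; planted-module recovery is exact
  for cliques and approximate (about 70-90% node overlap) for density-0.9
  near-cliques.
* The automatic cluster-to-wave mapping is a convenience built on template
  correlation; for real data a curated map remains the primary interface.
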