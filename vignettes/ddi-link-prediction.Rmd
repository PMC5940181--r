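---
title: "Predicting drug-drug interactions by link prediction on DDI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions by link prediction on DDI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ddilink)
```

## The problem and the model

A drug-drug interaction (DDI) network is an undirected, unweighted simple
graph $G(V, E)$: nodes are drugs, edges record that two drugs potentially
interact. Curated DDI databases are incomplete, so a natural question is
which of the $|U| = |V|(|V|-1)/2$ possible drug pairs that are *not*
recorded are most likely to interact. `ddilink` treats this as binary
classification of drug pairs: every pair gets a 12-dimensional feature
vector — eight topological similarity indices computed on the network and
four semantic similarities computed from drug annotations — and a label
(1 for a recorded interaction, 0 otherwise).

The guiding assumption, which the `group_similarity_comparison()` diagnostic
makes testable, is that similar drugs are more likely to interact: positive
pairs should have systematically larger average similarity than negative or
random pairs.

### Topological features

With $\Gamma(x)$ the neighbour set of $x$, $d(x) = |\Gamma(x)|$, and
$\Lambda_{x,y} = \Gamma(x) \cap \Gamma(y)$ the common neighbours:

| index | definition |
|---|---|
| CN  | $|\Lambda_{x,y}|$ |
| JC  | $|\Lambda_{x,y}| / |\Gamma(x) \cup \Gamma(y)|$ |
| AAI | $\sum_{z \in \Lambda} 1/\ln d(z)$ |
| PA  | $d(x)\, d(y)$ |
| RAI | $\sum_{z \in \Lambda} 1/d(z)$ |
| CCN | $|\Lambda| + \sum_{i \in \Lambda} |C(i) \cap C(x) \cap C(y)|$ |
| CRA | $\sum_{i \in \Lambda} \big(1 + |C(i) \cap C(x) \cap C(y)|\big)/d(i)$ |
| WIC | $|\Lambda^W| \,/\, (|\Lambda^{IC}| + \delta)$ |

The last three need a community assignment $C(\cdot)$. WIC requires a hard
partition ($\Lambda^W$ are common neighbours in the same community as both
endpoints, $\Lambda^{IC}$ the rest); the set notation of CCN and CRA also
admits overlapping communities. `detect_communities()` therefore maintains
both views: the default `"modularity"` method (greedy modularity
maximization, deterministic) yields a partition whose overlapping view is
the singleton set per node, and the optional `"kclique"` method (3-clique
percolation, intended for small graphs) yields genuinely overlapping sets.
Which algorithm "should" be used is underdetermined — community-dependent
indices are only defined relative to a stated method, and the method tag is
recorded in the assignment object.

Numerical conventions worth stating once: logarithms in AAI and IDF are
natural; in a simple graph a common neighbour always has degree $\ge 2$, so
$1/\ln d(z)$ is finite; empty-sum indices are 0; $\delta$ defaults to
0.001 and only matters when all common neighbours are within-community;
JC of two isolated nodes is 0.

### Semantic features

Three channels (ATC codes, MeSH terms, side-effect terms) represent each
drug as a binary vector over the channel vocabulary, weighted by inverse
document frequency $\mathrm{IDF}(t) = \ln(|D|/n_t)$, where $|D|$ is the
number of drugs *in that catalog* (not in the network) and $n_t$ the number
of drugs carrying code $t$; pair similarity is the cosine of the weighted
vectors. The fourth channel is the Tanimoto coefficient $c/(a+b-c)$ over
1024-bit binary chemical fingerprints, equal to the Jaccard similarity of
the supported-bit sets. The package consumes precomputed fingerprints;
producing them from SMILES is left to a chemistry toolkit upstream.

Drugs absent from a catalog are data, not errors: the affected pair gets
similarity 0 on that channel and is counted in a missingness summary. ATC
vectors default to full codes; a `first_level = TRUE` switch collapses them
to the 14 anatomical main groups for users who prefer the coarse view.

## Classifiers

### Unsupervised combined score

`combined_score()` z-scores each feature on the fitting rows, averages the
z-scores per pair, and predicts a link when the combined score is *strictly*
above a percentile threshold (default: the 90th percentile, nearest-rank
definition). Zero-variance features contribute 0, which makes the score
invariant under affine rescaling of any input feature. Labels play no role
in fitting. Two thresholding variants exist because the within-sample
protocol and the honest protocol differ: by default the training threshold
is frozen and applied to new data; `refit_threshold = TRUE` recomputes the
percentile on the scored set itself (the variant that makes train and test
metrics nearly identical).

### Supervised harness

`ddi_classifier()` wraps five established learners behind one interface:
`rpart` trees, `class::knn` (Euclidean metric), `e1071::svm` with a linear
kernel, `ranger` probability forests (500 trees, impurity importance), and
`xgboost` gradient boosting (shallow trees, learning rate 0.1, subsample
0.8). Hyperparameters — tree complexity `cp`, $k \in \{1, 3, \ldots, 25\}$,
SVM cost $\in \{0.01, 0.1, 1, 10\}$, boosting rounds/depth — are selected by
internal 5-fold cross-validated accuracy; the selected configuration's
accuracy is then estimated by 10-fold cross-validation before the final
refit on all training rows. Features are standardized (training mean/sd)
for the distance- and margin-based learners and left raw for tree
ensembles. All randomness flows from one seed; the SVM's Platt scaling and
the forest's bootstraps are seeded explicitly, so fits are reproducible.

`feature_importance()` exposes the mean impurity-decrease (Gini gain)
importances of the two ensemble families, min-max normalized to 0-100
and 0-1.

## Evaluation

`confusion_metrics()` reports counts and rates with zero-denominator ratios
as `NA` (an all-negative predictor has *undefined* precision, not zero).
`curve_metrics()` integrates the ROC and precision-recall curves by the
trapezoidal rule over distinct score thresholds with ties grouped; AUROC
therefore equals the tie-aware Mann-Whitney concordance probability, and
AUPR is the trapezoidal PR area (a fixed convention — not average
precision — recorded here because the two differ for coarse score grids).

`friedman_ranks()` compares classifiers across networks on within-network
ranks (1 = best, average ranks on ties) using the classic statistic
$$\chi^2_F = \frac{12N}{k(k+1)} \sum_j \left(\bar R_j - \frac{k+1}{2}\right)^2,
\qquad df = k - 1,$$
deliberately *without* the tie-correction factor: on the benchmark AUPR
tables shipped with the package (which contain a tie) the classic statistic
reproduces both published chi-squared values exactly, while the
tie-corrected variant does not. `nemenyi_posthoc()` adds pairwise p-values
from the studentized-range distribution and the critical difference
$CD = q_{\alpha,k}/\sqrt{2} \cdot \sqrt{k(k+1)/(6N)}$ at $\alpha = 0.05$;
`plot()` draws the usual CD diagram. Exact reproduction of published
post-hoc p-values is not promised — they depend on unstated approximation
choices — the chi-squared statistics are.

## Pair sampling and the two featurization modes

Positives are (a subset of) the edges; negatives are sampled uniformly
without replacement from $U - E$ of the *full* network, never from $E$,
regardless of any train/test split — so a sampled "negative" can never be a
hidden positive. Sampling is by rejection with a capped number of draws,
falling back to exact enumeration on small graphs. Labelled examples are
split 66/33 stratified (floor on the training count, remainder to test).

Two featurization modes are provided because the within-sample protocol is
ambiguous in this literature and the choice is consequential:

* **within-sample mode** computes features on the full graph. Every positive pair
  then contributes its own edge to both endpoint degrees — a small but real
  information leak (visible most directly in PA), which inflates test
  metrics and makes train and test rows nearly identical.
* **leakage-safe mode** removes the test positives' edges from the graph
  before featurization and freezes the training threshold of the combined
  score.

Both modes are first-class and the mode is recorded in the run config; the
package deliberately does not pick one silently.

## Synthetic data: what it emulates and what it does not

`generate_ddi_data()` draws from a degree-corrected planted-partition
model: equal-sized communities, within/between edge probabilities
$p_{in} \ge p_{out}$, and Pareto-distributed degree propensities
(mean-normalized, tail exponent 2.5 by default; `Inf` gives homogeneous
degrees). A degree-corrected *community* model — rather than a pure
scale-free one — is used because the community-aware indices are only
exercised when communities exist, and the degree correction supplies the
heavy-tailed degrees real DDI networks show. The default configuration
(500 drugs, 5 communities, $p_{in} = 0.3$, $p_{out} = 0.01$) lands in the
regime curated DDI networks occupy: giant component $\ge 0.95$, average
clustering $\ge 0.2$, average path length of a few hops, and roughly
8&nbsp;000 edges, which keeps a full pipeline run under a minute on one CPU.

The signal knob $\lambda \in [0, 1]$ sets the fraction of each drug's
attribute codes drawn from a community-specific pool (disjoint across
communities) versus a global pool, and likewise the fraction of fingerprint
bits copied from a community prototype. At $\lambda = 1$ attribute
similarity is maximally informative of community, hence of adjacency; at
$\lambda = 0$ attributes are independent of the graph. Per-channel
missingness (default 5%) emulates drugs absent from the side-effect or
annotation sources.

What passing tests on this generator do **not** show: real DDI networks
have unequal community sizes, hierarchical and overlapping pharmacological
classes, annotation vocabularies whose IDF spectra are far more skewed, and
fingerprints with correlated substructure bits. Synthetic results
demonstrate that the machinery recovers planted signal and stays at chance
without it — they are not estimates of performance on any real database.

### The no-signal control

The null condition used in the tests is $\lambda = 0$, $p_{in} = p_{out}$,
homogeneous degrees, leakage-safe mode. All four choices matter: planted
communities, degree heterogeneity, and within-sample-mode featurization are each a
*constructed* source of signal, and a control that leaves any of them in
place measures that construction rather than the absence of signal. Under
this control the random-forest test AUROC sits in the chance band; with the
full planted signal at the default sizes it exceeds 0.9 and its test AUPR
beats the unsupervised combined score — the package's synthetic stand-in
for the published finding that the supervised approach clearly outperforms
the unsupervised one.

For the monotone-signal property test, the network is made sparse and
community-pure ($p_{in} = 0.08$, $p_{out} = 0.005$, 150 drugs) so that the
attribute channels — the only thing $\lambda$ controls — have room to move
the forest's AUPR; with the dense default topology the topological features
already saturate the classifier and the $\lambda$ effect drowns in seed
noise.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(
  networks = list(
    demo_a = synth_config(n_drugs = 200, n_communities = 4, seed = 1),
    demo_b = synth_config(n_drugs = 200, n_communities = 4, seed = 2)),
  mode = "leakage-safe",
  classifiers = c("tree", "knn", "random_forest"),
  max_positives = 500, cv_folds = 0, seed = 42)
report <- ddi_run(cfg)
report$metrics
report$rank_comparison
plot(report$dendrograms$demo_a)
```

Problem sizes used by the shipped checks: the oracle-equivalence property
tests run on graphs of up to 30 nodes (where exhaustive set arithmetic and
all-pairs BFS are feasible as independent oracles); the end-to-end
signal-recovery checks use 500 drugs with 2&nbsp;500 positive pairs; the
monotonicity sweep uses 150 drugs over five seeds per $\lambda$.

## Known limitations

* Parsing of the real source databases (DrugBank XML, KEGG, NDF-RT,
  SemMedDB, Twosides) and identifier mapping are out of scope; the shipped
  benchmark tables are transcriptions of published summary results and are
  consumed as inputs by the rank-comparison machinery.
* 3-clique percolation enumerates maximal cliques and is only intended for
  small graphs.
* The edge-list interchange format cannot represent isolated nodes; runs
  started from files operate on the edge-supported node set.
* Probability calibration, imbalance schemes other than undersampling to
  balance, and path-based global indices (Katz, SimRank) are deliberately
  not provided.
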