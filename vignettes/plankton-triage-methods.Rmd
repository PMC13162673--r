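---
title: "Methods: metric-space triage for zooplankton monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metric-space triage for zooplankton monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term plankton monitoring programs count every organism in weekly net
samples, by category, under a microscope. A computer-vision assistant can
take over the bulk of this work only if it knows when *not* to decide: sample
composition drifts with the seasons, previously unseen species appear, and a
mislabelled organism silently corrupts a decades-long time series. The
pipeline implemented here therefore treats classification as an **open-set**
problem in embedding space: a metric-learning network (out of scope here)
maps each detected organism to a 128-dimensional unit vector; everything
downstream — exact cosine-similarity search over expert-verified reference
vectors, a cascade of novelty filters, the simulated expert-in-the-loop, and
the human-vs-machine agreement statistics — is this package.

## The triage cascade

Each detected object carries a detector confidence and an embedding. Stages
run strictly in order; the first failure routes the object to expert review,
and no object is ever left unrouted.

1. **Detection gate.** Confidence strictly below `detection_threshold`
   (default 0.8) fails; the boundary value passes. The gate is applied per
   object, not per image: the detector scores individual detections, and a
   single hard object should not condemn its whole image.
2. **KNN label proposal.** Among the `k_neighbors = 10` nearest verified
   vectors, a label qualifies if it holds at least `min_same_label = 5` of
   them *and* the mean query-to-those-neighbours cosine distance is strictly
   below that label's mean pairwise intra-label distance. We read "distance
   to these objects" as a mean because it is compared against a mean;
   median and max readings are available via `knn_aggregate`. `k = 10` is
   the smallest neighbourhood in which the 5-of-one-label condition is not
   automatically satisfied by a majority. If several labels qualify, the one
   with more representatives wins, then the smaller mean distance, then byte
   order — an arbitrary but reproducible resolution.
3. **Density-cluster membership.** The proposed label's verified vectors are
   clustered (below); the query must join one of the clusters, otherwise it
   is treated as an unusual form or an unknown class.
4. **One-class certainty.** A radial-basis one-class SVM fitted on the
   matched cluster scores the query; calibrated certainty strictly below
   `certainty_threshold = 0.95` reviews. Both strictness conventions follow
   the same rule: "below the threshold" excludes the boundary, so exact
   threshold values pass.

Distance is `1 - cosine similarity` throughout — monotone-equivalent to the
angular metric, and the plain inner product of re-normalized vectors makes
the flat index exact. Vectors are always re-normalized at ingestion rather
than trusted; upstream float drift must not leak into the metric. Nearest-
neighbour ties break by ascending object id (byte order) so that searches
are reproducible across platforms and locales.

## Density clustering on the cosine sphere

No suitable hierarchical density clustering was available as an installed
dependency, so the package implements an HDBSCAN-style procedure natively:
core distances (`min_pts = min_cluster_size = 5`, the point itself counts),
mutual-reachability distances, a single-linkage hierarchy, condensation with
minimum cluster size 5, and excess-of-mass cluster selection in which the
root is an admissible cluster (a label frequently forms exactly one coherent
cluster, which must not dissolve into noise).

Two absolute-scale parameters specialise the procedure to the unit
hypersphere, where — unlike in general metric spaces — cosine distance has
an intrinsic scale (1 means orthogonal, i.e. no directional association):

* `core_dist_floor = 0.5`: a point whose 5-neighbourhood extends past half
  the orthogonality scale is not dense in any ecologically meaningful sense
  and is noise outright. Without an absolute floor, a scale-free procedure
  cannot distinguish a tight class cluster from a uniform scatter — both
  have the same hierarchy topology.
* `cluster_eps = 0.2` (a cluster-selection epsilon): dendrogram splits below
  this distance are ignored. Metric-learned same-class embeddings sit at
  neighbour distances well under 0.2, so micro-splits below that scale are
  sampling noise, not structure.

A new query joins cluster $k$ if its best reachability
$\min_i \max(d(q, x_i), \mathrm{core}(x_i))$ over members $x_i$ of $k$ is
within the largest merge height at which $k$'s members connected.

## Calibrating the one-class certainty

The one-class SVM emits an uncalibrated signed margin, but the routing rule
consumes a probability-like certainty with a fixed 0.95 threshold. We map
scores through the empirical distribution of **cross-fitted** scores: the
cluster is scored 5-fold out-of-fold, and a query's score is rank-
interpolated within that reference distribution. Scoring points against a
boundary they helped shape is optimistically biased — in-sample ranks would
make the 0.95 threshold reject a large share of perfectly typical held-out
objects — whereas the cross-fitted distribution answers the right question:
how do *new* members of this cluster score?

The rank map is anchored so the `nu`-quantile of calibration scores maps to
certainty `1 - nu`. With the defaults (`nu = 0.05`), certainty `>= 0.95`
therefore means exactly "inside the cross-validated 5%-outlier boundary",
which makes the certainty threshold and the training-outlier budget two
views of one contract. The kernel scale uses the median heuristic on
pairwise squared distances; `certainty_mode = "raw"` exposes min-max-scaled
raw scores for users who prefer thresholding the margin directly.

## The active-learning loop

"Retraining" in this package means refreshing the verified reference index
and refitting the per-label cluster and one-class models — the metric-space
consumers of the cascade — not neural retraining, which is out of scope.
The invariant is strict: only records verified by the (simulated) expert
ever enter the index; auto-accepted objects do not, so the model cannot
feed on its own predictions. Per round, a seeded 20% slice of each batch is
held out for evaluation and never indexed; retrieval quality is tracked as
mAP@5. Since the metric is nowhere given a normative definition in the
monitoring context, we use mean average precision over the top-5 retrieved
neighbours with binary label relevance, averaging precision over the
relevant ranks (0 when none is relevant).

## Agreement statistics

* **Permutation test.** The naive reading of a "paired permutation test on
  the L1 distance" — permuting within pairs and recomputing
  $\sum_i |h_i - m_i|$ — is degenerate: swapping $h_i$ and $m_i$ leaves
  every $|h_i - m_i|$ unchanged, so the null distribution is a point mass.
  The package refuses that statistic at runtime with an explanation and
  implements the non-degenerate reading $T = |\sum_i (h_i - m_i)|$ under
  independent per-category sign flips. With $n \le 12$ categories all $2^n$
  flips are enumerated and $p = \#\{T^* \ge T\}/2^n$ (the identity flip
  counts, so $p > 0$); otherwise sampled flips with the add-one convention
  $(1 + \#)/(1 + N)$.
* **Wilcoxon signed-rank** on paired differences, zeros dropped (the
  original convention; the Pratt variant is exposed). Exact enumeration of
  all sign patterns for $n \le 15$ — which handles tied ranks — then a
  normal approximation with exact conditional variance and continuity
  correction. The paired design implies the signed-rank test; the rank-sum
  test is available separately as `mann_whitney_u()`, exact by enumeration
  of group assignments for $nm \le 64$ (ties included).
* **Bland–Altman in log2 space**, bias ± exactly 2 standard deviations (the
  display convention of the monitoring comparison, not 1.96). Categories
  with a zero count in either observer are excluded and listed rather than
  pseudocounted — any pseudocount choice would dominate the limits for rare
  taxa.
* **Areal conversion**: counts scaled by the counted fraction and divided
  by the net mouth area ($\pi (0.375/2)^2 \approx 0.1104\,\mathrm{m}^2$ for
  the 37.5 cm inlet), in thousand specimens per m².

## What the synthetic generator emulates

The generators produce every input the pipeline consumes, with defaults
frozen as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `dim` | 128 | embedding width of the upstream network |
| `kappa` | 800 | within-class concentration: mean same-class pairwise cosine distance ≈ 0.14 (cosine ≈ 0.86), typical of ArcFace-style embeddings |
| `min_separation` | 0.5 | class centers at least 60° apart |
| `mixture` | 0.79 dominant | one dominant copepod-like class, minor classes sharing the rest, echoing observed sample composition |
| `conf_shape1/2` | 18, 2 | detector confidence Beta(18,2): mean 0.90, ~8% of objects under the 0.8 gate |

Members are drawn by tangent-space Gaussian perturbation around each center
followed by renormalization — the standard large-concentration surrogate
for von Mises–Fisher sampling, exact enough for every `kappa >= 1` regime
used here and trivially seedable. Class centers are placed by rejection
sampling under the pairwise separation constraint, which errors out rather
than silently relaxing the constraint.

The generator emulates cluster geometry, novel-class injection, mixture
drift across a stream, detector confidence, and category-specific machine
counting bias (undercounting overlap-prone rotifer-like categories,
overcounting the dominant copepod-like one). It does **not** emulate image
artifacts, focus, chamber scratches, within-class multimodality (e.g.
developmental stages sharing a label), embedding-space drift of the
upstream network, or correlated detector failures. Passing tests on this
geometry therefore demonstrate the correctness and calibration of the
decision machinery under its stated assumptions — not field performance on
real imagery.

## Numerical choices and problem sizes

* Zero vectors cannot be normalized and are rejected with an error; unit
  norms are enforced to 1e-9 and cached statistics to 1e-9 against
  brute-force recomputation.
* Cluster/one-class models are fitted lazily per proposed label and cached
  on the index; any verified addition touching a label invalidates that
  label's entry.
* Exactness cutoffs: sign-flip enumeration at $n \le 12$, signed-rank at
  $n \le 15$, rank-sum at $nm \le 64$; beyond these, seeded sampling or
  tie-corrected normal approximations.
* The test suite and the acceptance script use batches of 150–450 objects,
  reference indices of 220–250 vectors, 10-seed repetitions for soundness,
  a 5-round drift stream, and 500–2000 replicates × 999 flips for
  permutation-test calibration — sizes at which every check, including the
  calibration study, completes in seconds while leaving binomial
  confidence intervals tight enough to be meaningful.

## Known limitations

* The certainty calibration is rank-based within one cluster; certainties
  are not comparable across clusters of very different sizes (small
  clusters have coarse calibration grids).
* The density-clustering membership radius is inherited from the training
  hierarchy; clusters that grow substantially between refits can reject
  legitimate members until the next verified addition triggers a refit.
* The simulated expert draws wrong labels uniformly; real annotator
  confusion is structured (morphologically similar stages), so
  oracle-error experiments here are a lower bound on the damage correlated
  errors could do.
* Abundance agreement statistics treat categories as independent; organisms
  misassigned between two categories induce negatively correlated errors
  that none of the implemented tests model explicitly.
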