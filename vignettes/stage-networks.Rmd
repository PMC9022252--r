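---
title: "Stage-resolved co-expression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

## The problem

Staged diseases such as colorectal cancer are usually analyzed gene by gene:
which transcripts change between tumor and normal tissue, or between
successive clinical stages. stagenet takes the complementary network view: for
every stage it builds a gene co-expression network over the differentially
expressed genes, detects communities (modules) in each network, and asks how
the modular organization itself evolves along the progression
normal → I → II → III → IV. The package implements the full chain —
differential expression, network construction with an analytically calibrated
correlation threshold, Louvain community detection, cross-stage comparison
with a permutation-calibrated NMI statistic, edge-based pathway enrichment,
trend-profile biomarkers, and drug-target network assembly — together with a
synthetic-data generator that plants all of these structures with known
ground truth, so every stage of the pipeline is testable without access to a
real cohort.

## Differential expression between neighboring stages

Expression is assumed log2-scale and normalized (array normalization from raw
intensity files is out of scope). For each of the four neighboring
comparisons (I vs normal, II vs I, III vs II, IV vs III) every probe gets a
two-sided Welch *t*-test; a gene with several probes receives the geometric
mean of its probe *p*-values,

$$p_{\mathrm{gene}} = \exp\!\Big(\tfrac{1}{m}\sum_{j=1}^m \log p_j\Big),$$

and the arithmetic mean of the probe log2 fold-changes. The master DEG list
is the union of genes with raw $p \le 0.05$ in any of the four comparisons;
stage-specific biomarkers are the intersection of the four DEG sets of one
stage against every other group. Two deliberate choices:

* **Welch rather than a moderated *t*.** The downstream pipeline consumes
  only *p*-values and fold-changes; empirical-Bayes variance moderation
  changes borderline calls but not the architecture. The Welch test keeps the
  module self-contained and exactly reproducible. Degenerate inputs are
  pinned down: two constant, equal groups give $p = 1$; constant but unequal
  groups give the smallest positive double, with a warning.
* **No multiple-testing filter on the primary path.** Selection uses raw
  $p \le 0.05$; BH *q*-values are reported in every output table but never
  used for filtering, so the user can apply a stricter rule downstream.

## Correlation networks with an analytic threshold

For a stage with $n$ samples, the Pearson correlation $r$ of a null gene pair
satisfies $t = r\sqrt{n-2}/\sqrt{1-r^2} \sim t_{n-2}$. `critical_r(n, p)`
inverts this relation at the two-sided level $p$ (default 0.001), giving the
per-stage cutoff $r_{\mathrm{th}}$; edges are all gene pairs with
$|r| \ge r_{\mathrm{th}}$, carrying weight $|r|$ (weighted) or 1
(unweighted). Because $r_{\mathrm{th}}$ depends only on the stage's sample
count, stages with few samples get stricter cutoffs — with 13 samples the
cutoff is ≈ 0.80, with 37 it is ≈ 0.52 — which is what makes the small-stage
networks sparser but stronger-edged. Correlations are computed in row blocks
(`block_size` genes at a time, default 512) so that the full gene × gene
matrix is never materialized and master lists of ~16,000 genes remain
feasible; tests exercise $d \le 500$. Genes constant within a stage are
dropped from that stage's network only, with a warning.

Stage-unique networks subtract, from one stage's edge set, every edge present
in **any** other stage-specific network (including normal); membership is by
unordered pair only, and surviving edges keep their weights. Probes are
collapsed to genes before correlation (per-sample median across the gene's
probes); whether probe- or gene-level values should enter the correlations
is a genuinely open choice, and the median collapse is the one made here.

## Communities and cross-stage comparison

Modularity of a partition $C$ is
$Q = \sum_c \big[ W_c/W - (S_c/2W)^2 \big]$ with $W$ the total edge weight,
$W_c$ the intra-community weight and $S_c$ the community's weighted degree.
The Louvain implementation (C++ via Rcpp) alternates local node moves and
community aggregation until the per-level gain drops below `tol` (default
1e-7). Determinism is contractual: the sweep order is shuffled by the `seed`
argument, ties in modularity gain go to the lowest community id, and the
returned $Q$ is recomputed independently in R. Isolated nodes are excluded —
Louvain operates on the edge-bearing subgraph, since community membership of
an isolated gene is undefined.

Partitions are compared with normalized mutual information using the
sum-of-entropies normalization $\mathrm{NMI} = 2 I(A,B)/(H(A)+H(B))$ (natural
logs). Two conventions close the degenerate corners: identical partitions
give exactly 1, and if either partition has a single community (zero entropy)
without being identical to the other, the value is 0. When two networks have
different edge-bearing node sets, NMI is computed on the intersection.
Community-to-community overlap is summarized by the Jaccard matrix
$J_{ij} = |C_i \cap D_j| / |C_i \cup D_j|$.

Significance of an observed NMI uses a degree-preserving null: both networks
are independently rewired by double-edge swaps (an attempted swap replaces
edges $(a,b), (c,d)$ with $(a,d), (c,b)$ unless a self-loop or duplicate
would arise; `10 × |E|` attempts by default, preserving the degree multiset
exactly), communities are re-detected, and the NMI recorded. The *p*-value is
the add-one upper-tail estimator $(1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(1 + n_{\mathrm{perm}})$, whose resolution floor at 1000
permutations is ≈ 0.001 — reported *p*-values at that floor mean "beyond the
null's range", not a literal probability. Randomizing one or both networks
per replicate are both defensible nulls; both are randomized here, which is
the stricter choice.

## Edge-based enrichment

Gene-set enrichment on a network is tested at the *edge* level: with $d$
master-list genes there are $N = d(d-1)/2$ possible edges, $m =
d_s(d_s-1)/2$ of them internal to a set with $d_s$ master-list members. A
network with $n$ edges containing $k$ internal edges is scored by the
hypergeometric upper tail $P[X \ge k]$, computed as
`phyper(k - 1, m, N - m, n, lower.tail = FALSE)` — numerically stable at
$N \sim 10^8$. The population is deliberately the full master list, not the
per-stage node set, so the same query is comparable across stages. A
node-level hypergeometric (`enrich_genes`) ships as a secondary utility; it
approximates web-service pathway enrichment but does not reproduce EASE
scores. Raw $p \le 0.05$ flags significance; BH *q*-values are emitted
alongside.

## Trend profiles over stage medians

Because stage groups have very unequal sizes, each gene is summarized by its
five stage medians (normal, I, II, III, IV). Candidate trends are integer
model profiles starting at 0 with successive steps bounded by $c$ (default 1):
$3^4 = 81$ profiles at five stages. Sixty of them (the default) are chosen by greedy max–min selection under the distance
$1 - \mathrm{corr}(p, q)$: the flat profile seeds the selection and the
candidate maximizing the minimum distance to the selected set is added
repeatedly. Three conventions make this deterministic and total: constant
profiles are at distance 1 from every non-constant profile and 0 from each
other; ties break to the lexicographically smallest profile; genes with
constant median vectors go to the flat profile with score 0. Each gene is
then assigned to the selected profile with maximal Pearson correlation to its
median vector — a score invariant to affine transforms of the gene's scale.
This follows the STEM-style short-time-series profile-clustering scheme in
spirit; exact reproduction of the STEM tool's 60-profile set is not claimed, and
profile-level permutation significance is intentionally out of scope. Both
dominant disease trends, the step profiles (0,1,1,1,1) and (0,−1,−1,−1,−1),
survive the greedy selection (asserted in the tests).

## Key-gene subnetworks and the drug-target network

Supervised subnetworks start from user-chosen key genes: each key gene's PPI
partners at score ≥ 0.4 are ranked by score (ties lexicographic) and capped
at 20; the induced subgraph of the stage network on (key genes ∪ neighbors) ∩
master list, with |PCC| weights, is exported as GraphML. The drug-target-PPI
network restricts targets to the master list (drugs losing all targets are
kept, flagged, for provenance), adds gene–gene edges at PPI score ≥ 0.9, and
annotates every gene with its per-stage *gene weight* — the sum of incident
|PCC| edge weights in that stage's network — and per-stage log2 fold-change.
PPI and drug-target inputs are local TSV snapshots; the shipped fixtures are
synthetic, labelled as such, and illustrative only.

## The synthetic cohort generator

`generate_dataset()` emulates the structure of a staged microarray cohort
with known ground truth:

* **Sample counts** default to the real cohort's groups: 22 normal, 13, 37,
  34, 20 for stages I–IV, plus 2 outlier samples appended to the normal
  group.
* **Correlation blocks** use a one-factor model: within a block, each value
  is $\sigma(\sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon)$ around its mean,
  with a fresh factor $f$ per (stage, block, sample), so the expected
  pairwise correlation is exactly `block_rho` (default 0.9, 4 blocks of 40
  genes).
* **Differential expression** plants a persistent ±`de_effect` (default 2)
  log2 shift from the test stage onward, for a per-comparison fraction of
  genes — 30% for I vs normal and 5% for the later transitions, mirroring the
  strongly asymmetric first transition seen in real staged cohorts, where the
  normal→tumor contrast dwarfs the stage-to-stage ones.
* **Trend biomarkers** follow fixed monotone or step patterns scaled by
  `de_effect`; **outliers** are shifted globally by `10 × noise_sd`;
  **multi-probe genes** (1–3 probes, probabilities 0.4/0.4/0.2) share the
  gene's latent signal and differ by a fixed probe affinity plus independent
  probe noise, exercising the geometric-mean aggregation; a small fraction of
  junk probes carries missing or multi-gene annotations to exercise the
  mapping filter.

The generator does **not** simulate probe-level raw intensities,
normalization artifacts, batch effects, correlated noise between blocks, or
survival outcomes. Passing tests on this cohort therefore demonstrate that
the pipeline recovers planted linear-Gaussian structure at realistic sample
sizes — not that it is robust to the full messiness of real microarray data.

## Numerical and degenerate-input choices

* `critical_r` is the exact inversion $r = t_q/\sqrt{(n-2) + t_q^2}$ with
  $t_q$ the two-sided $t$ quantile; validated against bisection on the $t$
  survival function.
* Correlation edge weights are clamped to $[0, 1]$ against floating-point
  overshoot of $|r| = 1$ pairs.
* Outlier detection replaces visual inspection of PCA/t-SNE plots with a
  deterministic rule: samples are projected on PC1–PC2 of the
  gene-standardized matrix and flagged when the robust z-score of their
  distance from the centroid exceeds `k` (default 5), i.e.
  $(d - \mathrm{median}(d))/\mathrm{mad}(d) > k$. The centering by the median
  is essential: distances have a positive location, so an uncentered rule
  would flag a constant fraction of healthy samples. On cohorts with strong
  stage separation the first components also encode stage structure, and the
  rule may flag extreme members of a distant group in addition to planted
  global-shift outliers — mirroring what a human would see in the same plot.
  t-SNE is omitted as stochastic and visualization-only.
* All randomized components (Louvain sweep order, edge swaps, the generator)
  consume explicit integer seeds; the pipeline derives per-stage seeds from
  one top-level seed via R's RNG.

## Problem sizes in the tests

The test and acceptance suites run the pipeline at desk scale, chosen so the
full suite completes in minutes: cohorts of 60–200 genes at the real
per-stage sample counts; exhaustive-enumeration oracles for the
hypergeometric tail on master lists of up to 8 genes; exhaustive modularity
maximization over all partitions of graphs with up to 10 nodes; 1000 random
graphs for the degree-multiset invariant; and a 200-trial × 99-permutation
calibration of the NMI permutation test on 60-node networks. At full cohort
scale (master lists of ~16,000 genes, 10^5–10^6 edges per stage network) the
same functions apply — the blocked correlation keeps memory bounded — but the
desk-scale suite asserts nothing at that size.

## Known limitations

* The Louvain heuristic is not guaranteed to reach the modularity optimum on
  large graphs; the suite verifies optimality only on graphs small enough to
  enumerate.
* The geometric-mean gene *p*-value is anti-conservative for correlated
  probes and is used as a ranking/selection device, as in the original
  analysis, not as a calibrated significance level.
* Edge-based enrichment conditions on the observed edge count but not on the
  degree sequence; hub-dominated sets can be flagged for topological rather
  than biological reasons.
* The add-one permutation *p* cannot fall below $1/(n_{\mathrm{perm}}+1)$;
  deeply significant comparisons saturate at the floor.
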