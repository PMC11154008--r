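---
title: "Methods: signature matching, hetnet prediction and diffusion mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature matching, hetnet prediction and diffusion mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeR)
```

This vignette documents the models behind each stage of the package, the
parameters that matter, the design decisions that were genuinely open, and
what the synthetic benchmark does and does not establish.

## Disease signatures

A disease contrast arrives as a per-gene table of log fold changes and raw
p-values. P-values are re-adjusted with the Benjamini–Hochberg step-up rule
(`adjust_pvalues_bh()`), so signatures assembled from heterogeneous sources
share a common FDR scale. A note on a property that is sometimes assumed of
BH: the adjusted values are *not* a fixed point of the procedure. Re-running
the step-up rule on its own output can only raise values (for p = (0.4, 0.9)
the first pass gives (0.8, 0.9) and a second pass (0.9, 0.9)); what the rule
does guarantee, and what the tests assert, is that the evidence ordering is
preserved, adjusted values never fall below raw ones, and tied vectors are
fixed points.

Two signature configurations are supported, mirroring the two standard ways
of cutting a ranked differential-expression table:

* `split` — the top `n_up` = 250 most up- and `n_down` = 250 most
  down-regulated significant genes, as two directed tag lists;
* `combined` — the top `n_combined` = 500 significant genes by |log fold
  change| regardless of direction, as one tag list.

"Significant" means adjusted p below a cutoff. The cutoff is not dictated by
the matching method itself; we default to the conventional 0.05 and expose
it everywhere (`significance_cutoff`). Within a direction genes are ranked
by fold-change magnitude, not p-value — the configurations are defined as
"top regulated" cuts — and boundary ties break lexicographically on gene id
so outputs are bit-stable. Genes absent from a drug library's universe are
kept in the signature and dropped only at matching time, which keeps a
signature reusable across libraries.

## Connectivity scoring (DGEM)

Drug signatures are full rankings of the gene universe (rank 1 = most
up-regulated by treatment). For a tag set of size $t$ in a ranking of $n$
genes with ascending tag ranks $V(j)$, the enrichment statistic is

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\qquad
  b = \max_j\left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),\qquad
  \mathrm{ks} = \begin{cases} a & a > b\\ -b & \text{else}\end{cases}$$

For a split signature the connectivity score is $s = \mathrm{ks}_{up} -
\mathrm{ks}_{down}$ when the two statistics disagree in sign and 0 when they
agree (a drug must move the two directions oppositely to count as mimicry or
reversal); $s \in [-2, 2]$, negative for signature reversal. A combined
signature has one tag list and no subtraction; how to score a direction-free
list is genuinely under-determined, and treating it as a single KS tag set
(range $[-1, 1]$) is the main interpretive choice of the module.

Scaled scores divide positive raw scores by the maximum positive and
negative ones by the magnitude of the most negative, giving a bounded
$[-1, 1]$ scale for threshold-style filters. Two consequences drove two
design decisions:

* **Ranking uses raw scores.** Scaling pins the strongest instance of
  *each* sign at exactly ±1, so a noise-level mimicry instance would always
  tie the strongest reversal instance in magnitude. Drugs are therefore
  condensed to the condition of maximum |raw score| (sign retained,
  condition-id tie-break) and ranked by descending |raw|; the scaled value
  of the chosen condition is carried along for filters. Scaling is
  per-contrast: each contrast's result set is scaled independently.
* **Configuration selection uses the signed maximum.** For each candidate
  configuration, the control drug (metformin by default) is condensed to its
  maximum signed raw score across conditions; multiple controls average; the
  configuration with the highest control score wins, ties going to the split
  configuration. The signed comparison expresses that the control should
  *attain* the highest score under the chosen representation: when only one
  direction of the disease signature carries signal, the split score is
  zeroed or dragged negative by the uninformative direction, and the
  direction-free configuration correctly wins. Raw (not scaled) scores are
  used because library-wide scaling is undefined over a control subset.

## Leading-edge overlap genes and pathway consensus

The genes "driving" a connectivity score are read off the KS running
statistic: for each tag set, the tags at or before the position of the
dominant deviation (from the top of the ranking when $a > b$, from the
bottom otherwise). Pooled across the up and down lists, ordered by rank
extremity (distance to the nearer end of the drug ranking) and truncated to
a cap of 100, they form the per-condition overlap set. A simpler
"signature ∩ extreme-rank window" variant could be swapped in; the
leading-edge reading is the most faithful KS-based definition.

Conditions with |scaled score| < 0.5 (inclusive threshold on 0.5 itself) are
discarded; the rest are amalgamated per drug, each gene keeping its best
position across conditions, de-duplicated and truncated to the cap *after*
merging (truncating before merging is available as the per-condition cap).
Enrichment is a local one-sided hypergeometric test against a GMT
collection, restricted to a background universe (default: the drug-library
gene universe), BH-adjusted per query. Consensus across contrasts is the
mean of per-contrast ranks over the contrasts where a pathway was tested,
with lexicographic tie-breaks — a deliberately simple, deterministic
replacement for web-service consensus rankings.

## Hetnet treatment prediction

The knowledge graph is a typed multigraph; edges are traversable in both
directions and the metagraph is derived from the distinct
(type, relation, type) triples. Metapaths from DRUG to DISEASE are
enumerated over that schema up to `max_metapath_length` = 3 edges. The
degree-weighted path count of a pair along a metapath is

$$\mathrm{DWPC} = \sum_{\text{simple conforming paths}} \prod_{(u,v) \in \text{path}}
  \left(d_u\, d_v\right)^{-w}$$

where $d_u, d_v$ are the endpoint degrees restricted to that metaedge and
traversal direction. The damping exponent defaults to $w = 0.4$ with
node-disjoint (simple-path) semantics, the established convention for this
feature family; $w = 0$ recovers the raw path count and larger $w$
increasingly punishes hub-mediated paths. During featurisation the pair's
own DRUG–treats–DISEASE edge is removed from the graph (degrees included),
so known treatments never leak into their own features — this masking also
covers held-out positives, whose own edges likewise never inform them.

The classifier is a single-hidden-layer network (16 logistic hidden units,
logistic output, weight decay 1e-3) fitted with `nnet` on standardised
features under a fixed seed; the architecture is a free choice and weight
decay plays the regularising role that early stopping would otherwise play.
Negatives are sampled non-treat pairs at 4:1. Evaluation is stratified
k-fold cross-validation reporting AUC (rank form; ties count ½, so constant
scores give exactly 0.5) and F1 at the 0.5 probability threshold. When
scoring retrieval of held-out treatments, known (training) treatments are
excluded from the candidate list, as is standard for link-prediction
evaluation; candidates are restricted to drugs connected to the disease, and
all-zero feature rows are flagged rather than dropped.

## Multiscale-interactome diffusion

The interactome joins drugs, diseases, proteins and biological functions
through five admissible undirected edge classes. A biased random walk steps
from $u$ to neighbour $v$ with probability $w_{type(v)} / \sum_{v' \in N(u)}
w_{type(v')}$ and continues with probability $\alpha$; the diffusion profile
is the fixed point $r = (1-\alpha)\,e_{start} + \alpha\,T^{\top} r$. The
type weights (3.21 / 3.54 / 4.40 / 6.58) and $\alpha = 0.859$ are the
published optima of the multiscale-interactome method and are taken as
given, not re-fitted; only their ratios matter (a common rescaling leaves
the operator unchanged). The fixed point is computed by power iteration from
the uniform vector to max-norm tolerance 1e-10 (cap 10,000 iterations),
restricted to the start node's connected component so the profile's support
honours the walk's reachability exactly.

How to combine the drug and disease profiles into one relevance ranking is
not dictated by the method; the default is the geometric mean (a node must
be visited by *both* profiles to score at all), with arithmetic mean and
minimum as alternatives, and the top k = 10 proteins/functions are pooled
across the two types (a per-type flag exists). The mechanism subgraph is the
union of all simple drug→disease paths of at most 6 edges whose interior
stays inside the top-k set; 6 comfortably covers the short mechanism chains
such subgraphs are meant to display, and paths are not additionally filtered
by edge class (the typing constraints already restrict which chains exist).

## The synthetic benchmark

`simulation_spec()` fixes the study conditions; all generators are pure
functions of it (and restore the caller's RNG state).

* **DE tables**: per-gene two-group Gaussian model, 10 samples per arm,
  noise SD 0.5 on the log2 scale — array-typical values at which planted
  shifts of 1.5–3 log2 units are reliably detectable after BH; p-values come
  from the pooled t-test on the simulated groups, so BH behaves as it would
  on real data. 2,000 genes with 40 planted effects per direction.
* **Signature library**: 50 drugs × 3 concentrations over the same
  universe; background instances are uniform-score permutations; the 5
  planted therapeutics push each disease signature gene to the reversing end
  independently with probability ρ = 0.8, plus score jitter of SD 0.1
  across conditions. With ρ = 1 and no jitter the reversed tags occupy exact
  end blocks and the raw score hits its closed-form maximum. A
  `reversal_directions` switch plants one-sided reversal, the fixture that
  exercises configuration selection.
* **Hetnet**: ~500 nodes over 8 types. True treatments are planted by
  making the drug target 3–5 genes associated with the disease, so the
  signal lives in DRUG–GENE–DISEASE paths and the classifier must learn
  path features rather than memorise treat edges (which are masked anyway).
  5% treat-edge rate, 4:1 sampled negatives, 80/20 train/holdout split.
* **Interactome**: ~100 nodes; one planted drug→protein→…→disease path
  (proteins at the ends, functions in the middle) whose end proteins attach
  to both query nodes, on top of random scaffold biology.

These sizes keep the complete test suite and the acceptance script in the
tens of seconds on one CPU while leaving every statistic well away from
small-sample degeneracy.

What passing does **not** show: the generators plant clean, independent
effects — no correlated gene modules, batch effects, cell-context
heterogeneity, curation noise in graph edges, or degree distributions as
skewed as real knowledge graphs. Recovery of planted structure validates the
implementations and their contracts, not performance on any real library or
graph; in particular the hetnet metrics on synthetic data say nothing about
published performance numbers obtained on proprietary graphs.

## Numerical and degenerate-input conventions

* All orderings carry deterministic tie-breaks (gene id, drug id, node id,
  condition id), so every output is reproducible byte for byte.
* `scale_scores` on an all-zero result set returns zeros; a zero-score pair
  has an empty leading edge (warning); a drug whose conditions all fall
  below the amalgamation threshold yields an empty overlap set (warning,
  not an error); a no-path mechanism query returns an empty subgraph
  (warning).
* Hard errors name their context: a contrast with no significant genes in a
  required direction, a control drug missing from the library, a type
  mismatch between node and metapath, an isolated walk start.
* The pipeline validates that every referenced input exists before any
  computation, aborts with the failing stage's name, and keeps partial
  outputs. Its manifest records seeds, parameters and md5 hashes of every
  file; downstream triage of the combined DGEM+DWPC candidate table (an
  outer join with mean-of-available-ranks, flagging drugs seen by only one
  module) is deliberately left to the analyst.
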