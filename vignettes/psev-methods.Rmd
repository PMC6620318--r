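---
title: "Propagated entry-vector embeddings: model, parameters and design choices"
author: "psever authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagated entry-vector embeddings: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psever)
```

## The model

`psever` embeds structured EHR concepts — diagnosis, medication-order and lab
codes — onto a typed heterogeneous biomedical knowledge network. The subset of
network nodes that structured codes map onto are the *entry points* (SEPs):
the only places where information from patient records enters the graph.

The embedding of a concept or patient cohort is the stationary vector of a
topic-sensitive PageRank (random walk with restart). Let $A$ be the symmetric
adjacency of the network (every edge is treated as undirected; parallel typed
edges between the same pair sum, each typed assertion contributing weight 1,
with a binary option), and let $P$ be its column-normalised form,
$P_{ij} = A_{ij}/\mathrm{deg}(j)$. With restart probability $\beta$ and
restart distribution $v$, the walk iterates

$$ r \leftarrow (1-\beta)\,P\,r \;+\; \bigl(\beta + (1-\beta)\,m_d(r)\bigr)\,v $$

from $r_0 = v$ until the $L_1$ difference of successive iterates is at most
$\alpha$. Here $m_d(r)$ is the probability mass sitting on zero-degree
(dangling) nodes, which is re-routed to the restart distribution; this is
arithmetically identical to appending an extra restart row filled with
$\beta$ to the transition matrix, but keeps the operator sparse. The fixed
point is unique for $\beta > 0$, so the choice of start only affects the
iteration count. Each converged vector — one element per network node,
summing to 1 — is a *propagated entry vector* (PSEV).

### The restart distribution

Restart mass is not spread uniformly. Two constructions are provided:

* **Single concept.** A column-stochastic *SEP transition matrix* $S$ is
  accumulated from patient records: each patient's binary SEP incidence
  vector is divided by its sum and added to the rows of their SEPs; the
  accumulated matrix is transposed and column-normalised. Column $j$ of $S$
  is then the co-occurrence-weighted distribution with which a walker
  restarting "at" SEP $j$ re-enters the network, and is the restart vector of
  concept $j$'s PSEV.
* **Cohort.** For a cohort $C$, the weight of SEP $i$ is the proportion of
  cohort patients carrying it,
  $w_i = |\{p \in C : i \in \mathrm{SEPs}(p)\}| / |C|$. The default restart
  is $\tilde w = w / \lVert w \rVert_1$ placed directly on the SEP positions
  — equivalent to jumping to a random cohort patient and traversing to one of
  that patient's SEPs. Routing the weights through the co-occurrence matrix
  ($S\tilde w$) is available via `composed = TRUE`; the two readings are both
  defensible from the method's description, so both are implemented and the
  direct form is the documented default.

SEPs never observed in any patient are excluded from the SEP index.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.1 | probability per step of jumping back to the restart distribution (damping factor $1-\beta = 0.9$) |
| `alpha` | 1e-6 | $L_1$ threshold on the difference of successive rank vectors |
| `maxIter` | 1000 | iteration cap; non-convergence is an error carrying the last residual |
| tracing `beta` | 0.33 | stronger restart used for single-SEP, network-only walks in contribution tracing |
| `percentile` | 0.001 | share of SEPs kept as top contributors |

A note on `alpha`: a step-difference threshold does not bound the distance to
the exact fixed point by $\alpha$ itself but by roughly
$\alpha\,(1-\beta)/\beta$ (contraction-mapping bound; observed errors on
random graphs of a few dozen nodes are $10^{-8}$–$10^{-7}$ at
$\alpha = 10^{-6}$, $\beta = 0.1$). Agreement with a dense linear solve to
$10^{-8}$ or better therefore requires $\alpha \approx 10^{-9}$. Both the
norm ($L_1$, scale-free in vector length) and the threshold are configurable.

## Post-processing

Raw walk mass is dominated by hub degree: the same high-degree nodes head
every PSEV. The default normalisation is therefore a **per-node z-score**:
each column (node) of the PSEV matrix is standardised to mean 0, sd 1 across
PSEV rows, using the population (divisor $n$) standard deviation;
zero-variance columns are set to 0. The per-PSEV axis is available for
sensitivity checks and single-row matrices. Within each node type, elements
are then ranked in descending order (rank 1 = most important), with ties
broken deterministically by node key.

## The recovery benchmark

All edges of the chosen types (the package's study condition deletes
`ASSOCIATES_DaG`, `UPREGULATES_DuG` and `RESEMBLES_DrD`) are removed before
PSEV creation and kept as the gold standard. For each disease with a PSEV
row, its top $K$ ranked genes are selected, with $K$ equal to the disease's
held-out association degree; the candidate universe is either all genes or
only genes with at least one gold edge. Scoring:

* per-disease overlap with an upper-tail binomial p-value at $n = K$,
  $p_0 = K/G$ ($G$ = universe size) — the probability that a uniformly random
  ranking places a gold gene in the top $K$, chosen so the null expectation
  $K^2/G$ matches the permutation expectation exactly (a hypergeometric
  variant would condition on sampling without replacement; the binomial form
  is the package's documented choice);
* Fisher's combination $X = -2\sum\ln p_d \sim \chi^2_{2m}$ over the $m$
  diseases actually scored (diseases without a PSEV row are skipped and
  excluded from the degrees of freedom);
* fold change = observed total overlap / mean null total overlap.

Three nulls are implemented:

1. **Fisher–Yates PSEV permutation** — the node axis of every PSEV row is
   independently permuted and the full scoring pipeline re-applied.
2. **Shuffled network** — every edge type of the *full* network is rewired by
   degree-preserving double-edge swaps (10 attempted swaps per edge; a
   simpler endpoint-permutation null is available behind a flag) before PSEV
   recomputation. Held-out types are not deleted first, so true edges can
   survive by chance — a stricter null. Edge types with fewer than two edges
   are left unshuffled and reported.
3. **Shuffled patient–SEP links** — the network is untouched; the SEP
   endpoints of all patient–SEP incidence pairs are permuted once, then the
   whole pipeline is rerun.

### Add-back learning curves

At each fraction $f$, $f$ of each gold stratum (edge type) is restored
(uniform sampling within stratum), PSEVs are recomputed, and the inferred
top-$K$ network is scored against the **full** deleted gold standard of the
stratum. Scoring against only the still-held-out edges sounds natural but is
structurally non-monotone: restored direct edges pull walk mass onto their
own interaction partners, so the remaining held-out edges compete against the
network's new knowledge and their recovery rate *falls* as $f$ grows — we
measured mean Spearman correlations near $-0.5$ under that definition. The
full-gold curve is the learning-rate statement the benchmark is after: it
rises from the pure-inference level at $f = 0$ to the full-knowledge level at
$f = 1$, and a stratum whose edges are supported by redundant routes
(well-established associations) stays above a stratum with weak redundancy
(noisy regulation edges) at every fraction. `inferTopkNetwork()` retains a
training-edge exclusion option for conventional link-prediction evaluation.

### Block enrichment

For a cluster of diseases and a cluster of genes, the observed statistic is
the number of cluster genes associated with at least $t$ cluster diseases
($t = 1, 2, 3$); the expectation is the mean of the same statistic over
uniformly random, equally sized disease and gene sets, with the Monte-Carlo
standard deviation reported so the standard error of the expectation is
$\mathrm{sd}/\sqrt{n_\mathrm{perm}}$. A zero expectation yields an infinite
fold change with an explicit flag rather than a division.

## Tracing explanations

For a concept and a downstream target node, the contribution of SEP $j$ is

$$ c_j = S^z_{j,\mathrm{concept}} \times M^{\mathrm{net}}_{j,\mathrm{target}} $$

where $S^z$ is the SEP transition matrix z-scored per concept column
(row-wise scoring is available; the column axis is the default because the
product asks how unusual SEP $j$ is *for this concept*), and
$M^{\mathrm{net}}$ holds single-SEP, network-only PSEVs computed with
$\beta = 0.33$ on the benchmark (edge-deleted) graph. "Top 0.1 percentile of
contributors" is read as the top 0.1% of SEPs by contribution
(`percentile = 0.001`); ties at the threshold are all kept and at least one
SEP is always returned. Shortest paths from the top contributors to the
target are breadth-first on the deleted-edge graph — so an explanation can
never use a held-out edge type — with up to 10 equally short paths per SEP,
ordered deterministically by the node keys along the path.

## The synthetic generator

`generateGraph()`/`generatePatients()` build the fixture every test runs on:
a SPOKE-like multityped graph (Disease, Gene, Anatomy, Symptom, Compound,
Pathway) with planted disease–gene structure, at the package's study
conditions of 5 diseases, 200 genes, 60 other nodes and 1000 patients.
Each disease gets a private neighborhood (3 anatomies, 3 symptoms, 3 treating
compounds), a well-established association stratum (4–8 genes, each backed
with probability 0.9 by a compound-binding route, an anatomy-expression route
and a disease-specific shared pathway) and a noisy regulation stratum
(3–6 genes, the same routes at probability 0.25). Background noise comes from
random expression, binding, gene–gene interaction and pathway-membership
edges. Deleted direct edges therefore remain inferable through redundant
indirect routes — strongly for the well-established stratum, weakly for the
noisy one.

Patient records are built from slots (the diagnosis plus the disease's
symptom and compound neighborhood); each slot yields its true node with
probability $\theta$ (default 0.8) and a uniformly random SEP-eligible node
otherwise, plus Poisson(1) random extra codes. The diagnosis slot is
$\theta$-governed like the others, so at $\theta = 0$ records carry no
information about the assigned disease; benchmark cohorts are therefore taken
from the generator's manifest assignment rather than from the (noisy)
records. A BMI-like covariate (baseline 24 kg m$^{-2}$, sd 3, recorded to one
decimal) is shifted by +8 for carriers of the first disease, giving the
continuous-variable cohort machinery something real to select on.

What the generator does *not* emulate: realistic code frequency
distributions, longitudinal structure, terminology cross-walks, correlated
comorbidity beyond shared planted genes, and the scale of a real knowledge
network (hundreds of nodes instead of tens of thousands). Passing tests
demonstrate that the pipeline recovers planted structure under honest nulls
at desk scale; they do not certify effect sizes on real EHR corpora, whose
published fold changes depend on a proprietary patient population and the
full network.

### BMI class boundaries

The four weight-class cohorts use the printed boundaries <18, 18–24.5,
24.6–29.5, >29.6. Read literally these leave one-decimal gaps (24.5–24.6)
and exclude 29.6 itself, so they are encoded as the closed intervals
$[-\infty, 17.9]$, $[18, 24.5]$, $[24.6, 29.5]$, $[29.6, \infty]$ over BMI
values recorded to one decimal, which makes the four boxes an exact
partition. All interval cohorts are closed on both ends with $\pm\infty$
sentinels for open sides; repeated measurements reduce to the per-patient
median by default (robust to stray entries), with last-recorded available.

## Numerical and degenerate-input conventions

* Node ordering is lexicographic by (type, id) and inherited by every matrix.
* Double precision throughout; iteration counts and residuals are returned
  as attributes.
* Patients with no mappable concept are kept (empty SEP set) but skipped with
  a message when accumulating the SEP transition matrix.
* Zero-degree nodes: columns flagged, mass re-routed to the restart.
* Empty cohorts are an error for code-based selection (the SEP is named);
  interval selection may legitimately return an empty cohort.
* Ties: rank ties break by node key; contribution ties at the percentile
  threshold are all included; all-equal contributions return every SEP with
  a warning.

## Problem sizes used by the test suite

Unit tests run on graphs of 3–60 nodes and reduced fixtures (3 diseases,
60 genes, 300 patients). The end-to-end recovery checks sweep 20 generator
seeds at the full study conditions with 200-draw permutation nulls per seed;
null calibration uses 1000 permutations; block enrichment is verified against
its closed-form expectation at $10^5$ draws. The whole suite completes in
well under a minute of compute per end-to-end block.

## Known limitations

* The walk is undirected and unweighted; evidence-weighted or directed edges
  are out of scope.
* Multi-mapping concept codes are rejected rather than resolved.
* The binomial recovery p-value treats per-disease selections as independent
  draws; diseases sharing genes violate this mildly.
* At desk scale the z-score normalisation runs over few PSEV rows, so
  zero-variance columns (nodes untouched by every cohort) are common; they
  are set to 0 and logged.
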