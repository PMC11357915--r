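---
title: "Network-medicine methods in tcmnet: separation, proximity and random-walk prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-medicine methods in tcmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmnet)
```

## The scientific problem

Complex diseases and, in traditional medicine, their symptom-cluster
subtypes ("syndromes") can be represented as gene modules on a genome-wide
protein–protein interaction (PPI) network. Two topological questions then
become quantitative:

1. **Are two gene modules the same neighbourhood of the network?**
   Answered by the *separation score* between the module pair.
2. **Does a drug or a multi-herb formula act near a disease module?**
   Answered by the *closest-distance proximity* of its target set to the
   module, standardized against a degree-preserving permutation null.

A third, prioritization question — *which ingredient of a multi-herb
formula carries the signal?* — is answered by a random walk with restart
(RWR) over a heterogeneous formula–herb–ingredient–protein network.
`tcmnet` implements all three statistics plus the surrounding plumbing
(interactome assembly, gene-set and composition I/O, over-representation
analysis, a pipeline orchestrator) and a synthetic benchmark generator so
the whole chain can be validated with known ground truth and no external
downloads.

## The interactome and its distances

All distances are unweighted shortest-path hop counts on an undirected
simple graph. Edge lists from multiple sources are merged as unordered
pairs with self-loops removed; identifier remapping (e.g. onto Entrez
gene IDs) is treated as data curation and supplied as an input table, with
colliding nodes merged and unmapped nodes dropped and counted. Analyses
run on the largest connected component (LCC) so every distance is finite;
genes absent from the LCC are dropped with a warning and the retained set
sizes are reported with every result, keeping filtering auditable.

The computational primitive is a level-synchronous **multi-source BFS**:
one pass yields, for every node, the distance to the nearest member of a
source set. Both headline statistics are built from it, and the test suite
verifies bit-identical agreement with an exhaustive all-pairs BFS oracle
(via igraph) on hundreds of random graphs.

## Separation of two gene modules

For modules $A$ and $B$,

$$ s_{AB} \;=\; \langle d_{AB} \rangle \;-\;
   \frac{\langle d_{AA}\rangle + \langle d_{BB}\rangle}{2}, $$

where $\langle d_{AA}\rangle$ averages each member's distance to its
nearest *other* member (excluding self — otherwise the internal term is
identically zero) and $\langle d_{AB}\rangle$ averages, over the nodes of
*both* sets, the distance to the closest node of the other set. The
symmetric cross-term convention is required for the exchange symmetry of
the score; a gene shared by both modules contributes zero on both sides.
Negative or near-zero $s_{AB}$ means overlapping network neighbourhoods.
`separation_panel()` compares one focus module against a panel of sets,
reusing the focus internal distance, and reports the panel mean — the
related-versus-control contrast used to argue that syndrome modules are
topologically close to a disease module.

## Proximity with a degree-preserving null

The proximity of a target set $T$ to a disease module $H$ is

$$ d_c(H, T) \;=\; \frac{1}{\lVert T\rVert}\sum_{t \in T}
   \min_{h \in H} d(h, t), $$

the average distance from each target to its nearest disease protein
(note the direction: the average runs over targets). Because hubs are
close to everything, the raw value is standardized against a null built
by re-drawing **both** $H$ and $T$ as degree-matched random sets, 100
paired resamples by default:

$$ z = \frac{d_c^{obs} - \bar d_{null}}{\sigma_{null}}, \qquad
   P = \frac{\#\{d_{null} \le d_c^{obs}\} + 1}{n_{perm} + 1}. $$

The empirical P is one-sided (closer than random) and add-one smoothed,
so $P \ge 1/(n_{perm}+1)$. A pair is flagged significant by the dual
criterion $z < -1.5$ **and** $P < 0.05$. A degenerate null
($\sigma_{null}=0$) leaves $z$ undefined and the pair not significant,
with an explicit flag.

### Degree matching and bin resolution

Exact-degree matching is impossible for hubs in a finite network, so
nodes are sampled from log2 degree bins, merging low-occupancy bins
upward (a deficient top bin merges downward) until each bin holds at
least `min_bin_size` nodes. The default of 100 is calibrated to
interactome-scale networks (tens of thousands of nodes). **Bin resolution
must scale with the network**: on a 600-node benchmark, a 100-node
minimum collapses the degree spectrum into two or three bins, hubs are
"matched" against mid-degree nodes, and the null mis-calibrates. The
package's scaled-down studies therefore use `min_bin_size = 10` (about 2%
of nodes, the same ratio as 100 out of ~17k), under which degree-matched
random target sets are flagged significant in well under 5% of runs —
comfortably inside the 7.5% calibration bound the test suite enforces
over 400 runs.

### RNG discipline

`proximity_matrix()` derives each (disease, entity) cell's permutation
stream from a stable hash of the pair labels plus a base seed. Cells are
therefore independent: reordering the entity list permutes rows without
changing any value, and a fixed seed reproduces the matrix bit-for-bit.

## Random walk with restart

The heterogeneous network stacks four node kinds — formula, herb,
ingredient, protein — with formula–herb, herb–ingredient,
ingredient–protein (targets restricted to the interactome) and
protein–protein edges. The walk iterates

$$ p \leftarrow (1-r)\,W p + r\,e $$

with $W$ the column-stochastic adjacency of the flattened typed graph
(uniform edge weight 1), $e$ uniform over the on-network seed genes
(syndrome genes in the intended recipe) and restart probability
$r = 0.7$. The four-layer graph is flattened because no inter-layer jump
parameters are specified for the multiplex alternative; layer weights
would be straightforward config hooks but default to 1. Iteration stops
when the L1 change drops below `tolerance` (default 1e-10, cap 1000
iterations; with $r=0.7$ the map contracts by 0.3 per step, so
convergence takes ~25 iterations). Scores conserve probability mass at
every iteration, and the tests verify agreement with the direct dense
solve $p = r(I-(1-r)W)^{-1}e$ to 1e-8.

Ingredients are ranked by steady-state score (ties broken by identifier
so rankings are fully deterministic), annotated with their containing
formulae; ingredients with no on-network target stay in the network via
their herb edges but are flagged, since their score then reflects
composition only. Per-formula views truncate the global ranking to each
formula's members; the "top 1%" display rule is a reporting option, not
part of the ranking contract.

## Over-representation analysis

Pathway enrichment is the exact hypergeometric upper tail
$P(X \ge \text{overlap})$ with Benjamini–Hochberg adjustment across the
tested pathways. The cutoff pair (raw $P < 0.05$, adjusted $P < 0.2$)
follows the convention of applying the q-value-style cutoff 0.2 to BH
values, since BH is the only named adjustment; this is a documented
approximation. The default universe is the interactome node set, which
keeps enrichment consistent with the network statistics; any background
can be supplied instead.

## The synthetic benchmark and what it does (not) show

`generate_interactome()` grows a preferential-attachment graph: a seed
clique on $m+1$ nodes, then each new node attaches to $m$ distinct
existing nodes with probability proportional to degree, giving exactly
$m(m+1)/2 + m(n-m-1)$ edges, guaranteed connectivity (no LCC-loss
confound in recovery experiments; the LCC code path is exercised by
dedicated disconnected fixtures) and a heavy-tailed degree distribution.
Modules are planted by seeded BFS growth whose `cohesiveness` parameter
(default 0.8) biases the frontier choice toward nodes with many edges
into the module; overlap-controlled variants share an exact number of
genes with a base module and grow the remainder adjacent to the shared
core. Target profiles are drawn from exact distance strata, so placement
0/1 forces observed proximity 0/1. Formula fixtures plant one active
ingredient (all targets inside the module) among 20 decoys (random
targets), with drug-likeness scores separating actives (0.6–0.95) from
decoys (0.05–0.25) so a 0.3 screening threshold removes exactly the
decoys.

The default study conditions — 600 nodes, attachment 2, disease module
40, five syndrome modules of 35 sharing 12 genes with the disease module,
20 disjoint controls, 12-gene target profiles, 100 permutations, restart
0.7 — were chosen once as a realistic scaled-down analogue of an
interactome study and are used unchanged by the validation suite and the
acceptance script. Two geometric facts about this scale matter. First,
the bin-resolution point above. Second, on the attachment-2 graph every
node lies within 3 hops of a 40-gene module, so "distal" placement
experiments (4+ hops) are run on an attachment-1 graph of the same size,
whose tree-like sparsity leaves strata out to 7 hops.

What passing these experiments shows: the statistics respond to planted
topology in the right direction, at the right false-positive rate, under
a degree distribution with realistic hub structure. What it does not
show: behaviour under the real interactome's density (average degree ~36
versus ~4 here), its literature-curation biases correlating disease genes
with hubs, or identifier-mapping noise — those depend on real data the
generator deliberately does not imitate.

## Numerical and design choices

* Distances are integer hop counts; means of integers, so oracle
  comparisons can demand exact equality.
* LCC ties break toward the component containing the smallest node label
  (inert on real interactomes, which have a unique giant component).
* Sampling inside the permutation null is without replacement within a
  draw and independent across draws.
* All tabular outputs are TSV with fixed column order and 6 significant
  digits; JSON artifacts carry full precision.
* The pipeline fans one global seed out to stages by stable string
  hashing, so stages can be re-run in isolation and a manifest (inputs,
  parameters, checksums, child seeds) suffices to reproduce any number.

## Known limitations

* Real-interactome headline numbers (mean separation of a real disease
  versus syndrome panels, z-scores of named drugs) require curated
  gene/target/network data that are not redistributable here; the
  package validates the machinery on synthetic ground truth instead.
* Only the closest-distance proximity variant is implemented (no
  shortest/kernel/centre variants) and no multiple-testing correction is
  applied across a proximity matrix — the dual per-pair criterion is the
  published decision rule.
* The RWR is single-layer after flattening; true multiplex dynamics with
  per-layer restart would need jump parameters that are not specified.
* Edge confidence scores, direction and weights are out of scope; the
  interactome is strictly binary.
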