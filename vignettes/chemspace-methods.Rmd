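---
title: "From peptide sequences to mined similarity networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From peptide sequences to mined similarity networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepspace)
```

# The problem

Collections of bioactive peptides (antimicrobial, anticancer, antiviral, ...)
are most naturally compared in a *chemical space*: each sequence is mapped to
a point in an m-dimensional molecular-descriptor space, and pairwise
similarity in that space induces a network whose structure — communities,
hubs, bridges — can be mined for representative or novel compounds.
`pepspace` implements this workflow end to end: descriptor computation,
unsupervised selection of an informative low-redundancy descriptor subset,
similarity-network construction, and network mining. The package is written
in the classic modelling idiom: `chemspace()` fits the whole model and
returns a classed object; `predict()` embeds new sequences into the fitted
space.

# Molecular descriptors

A descriptor is a statistic of a per-residue property encoding. For a
sequence $s = s_1 \dots s_L$ and a property scale $p$ (one value per amino
acid), the encoding is the vector $(p(s_1), \dots, p(s_L))$. A
`descriptor_spec` composes, in order:

1. **encode** — look up the property per position;
2. **group restriction** (optional) — keep only residues of a named group
   (aromatic, charged, ...);
3. **neighborhood smoothing** (optional) — replace each position by the mean
   of the window of radius $k \in \{1,\dots,6\}$ around it, truncated at the
   ends;
4. **aggregate** — collapse with a statistic: mean, median, variance, sd,
   range, min, max, sum, or an ordered-weighted average (OWA, the dot
   product of a weight vector with the values sorted in descending order).

Two smaller families complete the set: group composition fractions, and
group-restricted sums. Columns are named deterministically as
`property.group.operator.kK` so a spec list defines a reproducible matrix.

**Design choices worth stating.**

* *Neighborhood semantics.* "Neighborhood aggregation at radius k" is
  implemented as a truncated sliding-window mean applied before the global
  operator. This is the simplest operator consistent with the idea of
  blending each residue with its sequence neighbors; other readings (e.g.
  windowed medians, center-excluded windows) would slot into the same
  pipeline step.
* *Group restriction and empty selections.* A random sequence may contain no
  aromatic residue at all. A location statistic (mean, min, ...) of an empty
  selection is undefined, and the matrix builder aborts naming the record
  and spec — silent imputation would corrupt the descriptor distribution.
  `sum` and `fraction` are naturally 0 on an empty selection, so the
  *default* spec set combines group restriction only with those two
  operators and is therefore total on arbitrary sequences.
* *The property table.* The bundled table ships six published scales
  (side-chain mass, Hellberg z1–z3, isoelectric point, Hopp–Woods
  hydrophilicity, Kyte–Doolittle hydropathy) and five groups (aliphatic,
  aromatic, uncharged polar, charged, helix-favoring). We deliberately ship
  only scales we could trace to standard published sources; a
  heat-of-formation scale is often mentioned in this descriptor tradition,
  but we found no per-residue reference table we could verify, so it is left
  to the user to add via `property_table()` rather than shipped with
  invented numbers. The table is a plain value and fully user-extensible.
* *Nonstandard letters.* B, J, O, U, Z and friends are rejected outright.
  With `strict = FALSE`, `X` alone is tolerated and encodes as the mean of
  each scale (an "average residue"); silent coercion of anything else is a
  data bug, not a convenience.
* *OWA weights.* Descriptor toolboxes often name OWA operators without
  fixing weights; we provide linearly decreasing weights plus the degenerate
  max/min vectors, selectable by name, and reject malformed user weights
  (negative, not summing to 1) instead of renormalizing.

# Unsupervised feature selection

Descriptor catalogues are large and highly redundant. Selection is
unsupervised — no activity labels — and proceeds in two stages.

**Information measures.** Each feature is discretized into $n_b$ equal-width
bins over its observed range (maximum assigned to the last bin; a constant
feature occupies one bin). Shannon entropy
$H(f) = -\sum_i p_i \log_2 p_i$ measures discriminative power
(bounded by $\log_2 n_b$); mutual information
$I(f_j, f_k) = \sum_{i,l} p_{il} \log_2 \frac{p_{il}}{p_i p_l}$
on the joint histogram (marginals taken from the joint margins, so
$I \ge 0$ and $I(f,f) = H(f)$ hold exactly) measures redundancy. All
quantities are in bits.

**Stage 1 — rank and filter** (`rank_and_filter()`): drop features with
$H < \theta_1$, rank the rest by descending entropy, then greedily keep a
feature iff its absolute correlation with every kept feature is below
$\theta_2$. Defaults: $n_b = n$ (one bin per instance), $\theta_1 = 0.1
\log_2 n_b$ (10% of the maximum), Spearman correlation, $\theta_2 = 0.8$.
Spearman is computed on rank-transformed copies cached once per matrix. A
constant feature has undefined correlation; the documented contract returns
0 with a warning (no redundancy signal), though in practice the entropy
cutoff removes constants first.

**Stage 2 — backward elimination** (`optimize_subset()`): maximize the merit
$$\Phi(F) = \frac{1}{|F|}\sum_{f_j \in F} H(f_j)
 - \frac{1}{|F|^2}\sum_{f_j, f_k \in F} I(f_j, f_k),$$
starting from the full candidate set and repeatedly applying the
single-feature deletion with the largest merit gain while one strictly
improves. The double sum runs over all ordered pairs *including* the
diagonal $I(f,f) = H(f)$ — the literal reading, under which a singleton
subset scores exactly 0; `exclude_diagonal = TRUE` exposes the alternative
convention. Binning here uses the square-root choice $n_b =
\lfloor\sqrt{n}\rfloor$. Entropies and the pairwise mutual-information
matrix are computed once and cached, so each deletion evaluation is pure
arithmetic — this caching is a contract, not an optimization detail, since
re-histogramming per deletion would make the procedure quadratically more
expensive in practice. Ties everywhere resolve to the lowest column index,
making the procedure deterministic.

**Procrustes assessment** (`procrustes_fit()`): to quantify how well a
reduced space preserves the structure of the original one, both matrices
are projected onto their leading principal components (50 by default) and
superimposed by symmetric Procrustes analysis (optimal translation,
scaling, rotation, reflection — computed via `vegan`); the normalized
residual sum of squares in $[0,1]$ is reported. Columns are centered and
unit-scaled before PCA by default, appropriate when descriptor columns have
incommensurable units. Note that column-wise scaling is *not* invariant to
a rotation applied to one configuration; `scale_columns = FALSE` restores
exact rotation/uniform-scaling invariance and is the right setting when
both matrices are coordinate configurations in a common unit.

# Similarity networks

The selected descriptors define a Euclidean metric space; coordinates are
z-score standardized by default (descriptor units are incommensurable, and
the stored parameters are reused verbatim when embedding new points; the
flag `standardize = FALSE` disables it). Distance becomes similarity via
$$sim(u,v) = 1 - \frac{d(u,v)}{\max_{p,q} d(p,q)} \in [0,1],$$
so coincident points have similarity 1 and the diameter pair similarity 0.

* **CSN** (`build_csn()`): edge $\{u,v\}$ iff $sim(u,v) \ge t$, weighted by
  the similarity. Density $2m/(n(n-1))$ is 1 at $t=0$ and non-increasing
  in $t$.
* **HSPN** (`build_hspn()`): for each point, the half-space proximal test
  repeatedly takes the nearest remaining candidate $v$, emits the edge, and
  discards every candidate strictly closer to $v$ than to $u$ (ties
  survive, so tied points are never silently disconnected; nearest-candidate
  ties resolve to the lowest index). The undirected union over all points
  is connected at $t=0$ and far sparser than the complete CSN; per-point
  computations are independent, so any evaluation order — including a
  parallel one — produces the identical graph. The HSPN edge set is a
  subset of the CSN edge set at the same threshold.
* **K-NN embedding** (`embed_knng()`, surfaced as `predict()`): new
  sequences are described with the fitted spec set, mapped with the stored
  standardization, and linked to their $k$ (default 3) nearest
  reference-or-new nodes. The reference diameter is reused for the
  similarity transform; a pair farther than it clamps at 0 with a warning,
  keeping the reference space immutable.

The full $n \times n$ similarity matrix is never materialized: the diameter
is computed in row blocks, HSP works from per-point distance vectors, and
CSN edges are generated block-wise. This is what makes the HSPN the
appropriate construction for datasets of tens of thousands of peptides.

# Mining the network

* **Communities**: Louvain modularity maximization on the weighted graph
  (via `igraph`), with an explicit seed for the randomized visiting order;
  the reported $Q$ is always recomputed from the final partition with the
  weighted modularity formula. Isolated nodes become singletons.
* **Harmonic centrality** $C_H(i) = \sum_{j \ne i} 1/d_g(i,j)$ with
  $1/\infty = 0$ for unreachable pairs. The edge length for weighted
  shortest paths is taken as $1 - sim$ — strong similarity means a short
  step, so central peptides have small similarity paths to everything —
  with a hop-count mode as the alternative, since graph tools differ on
  this convention.
* **Community hub-bridge centrality**
  $C_{HB}(i) = k^{int}_i \cdot card(c_i) + k^{ext}_i \cdot nnc(i)$, where
  the internal/external strengths split the weighted degree by community,
  $card$ is the community size and $nnc$ counts distinct *foreign*
  communities among the node's neighbors (not inter-community edges).
  Favors hubs of large communities and bridges spanning many communities.
* **Top-k and redundancy filtering**: the induced subgraph of the $k$
  highest-$C_{HB}$ nodes (ties by node id), and a greedy scan of records in
  decreasing centrality order keeping each iff its Smith–Waterman identity
  to every kept record is below 70%. Alignment uses BLOSUM62 with affine
  gaps (open 10, extend 0.5 — the BioJava/EMBOSS convention; both
  configurable), and identity is counted over the aligned columns of the
  optimal local alignment, gaps included, with the shorter-sequence
  denominator available by flag.

# The synthetic-data generators

`simulate_peptides()` draws sequences of uniform random length with
independent residues (uniform or user-weighted composition);
`simulate_points()` draws standard-normal point clouds; and
`simulate_redundant_matrix()` plants blocks of features that are noisy
copies of shared latent factors (default: 400 instances, 60 features, 6
blocks of 5 with noise sd 0.3, the rest independent noise). The planted
blocks emulate the dominant pathology of real descriptor catalogues — many
near-duplicate measurements of the same underlying property — which is the
regime where two-stage selection should beat plain entropy ranking.

What the generators do **not** emulate: residue autocorrelation along real
sequences, length/composition couplings, family structure (homologous
subgroups), or heavy-tailed descriptor marginals. Passing tests therefore
demonstrate algorithmic correctness and the qualitative behavior of the
machinery (sparsity, connectivity, monotone trends, selection dominance) on
controlled inputs — not biological validity of any particular descriptor
choice on curated peptide databases.

# Numerical and testing choices

* Binning: right-closed last bin; joint histograms reuse each feature's own
  edges; $0 \log 0 = 0$.
* Entropy/MI/merit oracles in the test suite are independent loop-based
  implementations; graph measures are checked against double-loop and
  Floyd–Warshall references; the HSP builder against a naive quadratic
  implementation; alignment scores against an independent Gotoh dynamic
  program.
* Problem sizes: property checks run on hundreds of seeded small instances;
  network-scale behavior (HSPN connectivity and sparsity versus the
  minimum-density connected CSN, found via the maximum MST edge) is
  exercised at $n \in \{200, 1557, 5000\}$ in 10–40 dimensions; selection
  dominance over top-k ranking on 20 seeded planted-redundancy matrices.
  These sizes were chosen to exercise the block-wise code paths while
  keeping the default suite quick to run.
* Determinism: every stochastic step (simulation, Louvain order) takes an
  explicit seed; the pipeline's artifacts are byte-identical across reruns
  with identical inputs, and each table artifact carries the configuration
  echo as comment lines (FASTA cannot carry comments; the sidecar
  `config.json` covers it).

# Known limitations

* The descriptor catalogue is a compact curated framework, not a
  reproduction of any specific historical descriptor list; numeric
  compatibility with other toolboxes is a non-goal.
* Only sequence-derived descriptors are computed — no 3D/structural or
  chemical-graph topological indices.
* Louvain is the only community method; betweenness/eigenvector
  centralities and approximate nearest-neighbor indices are out of scope.
* Redundancy filtering is exact and pairwise ($O(k^2)$ alignments over the
  kept set); it is meant for centrality-ranked shortlists, not for
  CD-HIT-scale dataset deduplication.

# A worked example

```{r example, eval = FALSE}
recs <- simulate_peptides(200, c(10, 40), seed = 1)
fit <- chemspace(recs, chemspace_config(network = "CSN", threshold = 0.6))
print(fit)
coef(fit)              # selected descriptors with their entropies
plot(fit)              # density vs threshold profile
new <- peptide_records(c("WLFKFLAWKKK", "FPKLLLKFLRLG"), ids = c("P1", "P2"))
g <- predict(fit, new) # 3-NN embedding into the fitted space
```
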