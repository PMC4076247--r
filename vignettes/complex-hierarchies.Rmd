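---
title: "Building hierarchies of protein complexes from association evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building hierarchies of protein complexes from association evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexHier)
```

## The problem

Affinity purification and co-fractionation experiments report protein
*associations*: sets of proteins retrieved together. A corpus of such
records is highly redundant (the same complex reported by many
publications, or repeatedly within one), contaminated by intrinsically
sticky proteins such as chaperones, and noisy at the level of individual
members (false negative drop-outs and false positive contaminants).
`complexHier` reconciles such a corpus into a directed acyclic graph in
which an edge X → Y states that complex X is, approximately, a part of
complex Y. A DAG rather than a tree is essential: a stable subassembly can
be a module of several unrelated larger machines.

This vignette explains the model and its assumptions, the tunable
parameters, the synthetic data used to validate the pipeline, and the
numerical and design choices made where the design was genuinely open.

## Evidence grouping and support weights

An *evidence* is one experimental observation: a protein set with a
publication, a detection-method annotation and an optional bait.
Records with fewer than `min_size = 4` distinct proteins are excluded up
front — three-or-fewer-member records carry more of the character of
binary interactions than of heteromeric complexes, and are exactly the
records most susceptible to accidental association. Evidences sharing
(publication, method, bait) are *equivalent* — near-copies arising from
database curation — and are grouped into one initial complex node, each
evidence weighted `u(e) = 1/k` inside a group of k, so every reported
complex contributes one unit of mass regardless of how redundantly it was
curated. Whether "experimental annotation" should mean the detection
method alone or method plus interaction type is ambiguous in general; this
package groups by the `method` column alone, which is the coarser and
therefore more conservative grouping.

The **support weight** of protein i in node C is the weighted fraction of
C's evidences containing i,

$$w_S(i) = \sum_{e \ni i} u(e) \Big/ \sum_e u(e),$$

equal to 1 exactly when every evidence of C contains i.

## Down-weighting sticky proteins

Let `n(i)` be the weighted number of evidences containing protein i over
the whole corpus, `N = Σᵢ n(i)`, and let `c` be the weighted median of the
occurrence counts: the largest attained value m such that proteins with
`n(i) ≥ m` still account for at least half of N. Proteins above the median
floor are down-weighted proportionally:

$$w_A(i) = w_S(i) \cdot \min(1,\; c / n(i)).$$

By construction fewer than half of the corpus mass is down-weighted. The
floor c also protects the opposite flank: in the flow weights below, a
protein seen in very few complexes is treated as if it belonged to at
least c, so incompleteness of the corpus does not inflate its weight. The
same weighted median serves both roles; a single per-corpus c is what
makes the zero-diffusion limit of the flow weights coincide *exactly* with
the adjusted weights.

## Information-flow weights

Direct binary interactions carry independent information: common proteins
that consistently interact with the rest of a complex are core members,
while sticky proteins attach in a haphazard way. The interaction network
enters through the substochastic transition operator

$$P(i,j) = \frac{A(i,j)}{\deg(i) + \kappa},$$

where A is the boolean adjacency of direct interactions (self-interactions
removed) and κ the median interaction degree, used as a pseudocount: at
each step a walker either moves to an interacting protein or, with the
remaining probability, leaves the protein layer and terminates. κ is taken
as the *lower* median (the element at position ⌈n/2⌉ of the sorted degree
list) so that it is always an attained integer degree.

For a node C, walkers are placed on its members proportionally to the
support weights — the only weight defined before any flow computation —
and the expected visit counts are

$$F_C = w_S^{\top} (I - \alpha P)^{-1},$$

computed by one sparse linear solve of the transposed system. Walkers may
traverse proteins outside C; only the final weights are masked to C's
member set:

$$w_N(i) = c\, F_C(i) / \max(n(i), c) \quad \text{for } i \in
\mathrm{Supp}(C).$$

The factor combines the termination-jump probability through the adjusted
complex count `max(n(i), c)` with the rescaling that puts `w_N` on the
same scale as `w_S`; it is the unique choice for which α → 0 reduces
`w_N` to `w_A` identically (at α = 0 the resolvent is the identity, so
`F_C = w_S`). Proteins absent from the interaction network have degree 0
and an all-zero operator row, so their flow weight reduces to their
adjusted weight with no special-casing.

The damping α ∈ [0, 1) controls how much the interaction network is
trusted. Rather than choosing it directly, it is calibrated from the mean
walk time

$$\bar T(\alpha) = \frac{1}{|V|} \sum_{i \in V} [(I-\alpha P)^{-1}
\mathbf 1]_i,$$

the expected number of protein visits of a walker starting uniformly on
the proteins V that appear in the interaction pair list (proteins indexed
only through complex evidence have no interactions to walk on and are not
averaged over). `T̄(0) = 1`, T̄ is increasing in α, and on a k-regular
network with κ = k it equals `1/(1 − α/2)`. `solve_alpha()` inverts
`T̄(α) = T*` (default `T* = 4` steps) by Newton's method — the derivative
`T̄'(α)` requires one extra linear solve per iteration — safeguarded by
bisection on the monotone bracket, to `|T̄(α) − T*| ≤ 1e-9`. Because P is
strictly substochastic, T̄ stays finite as α → 1; a target above
`sup T̄ = T̄(1)` is reported as unreachable together with that supremum
(e.g. any regular network has `sup T̄ < 2` and cannot support `T* = 4`).

## Similarity, distance and merging

Weight functions are compared by the weighted overlap
`σ(X,Y) = Σᵢ min(wX(i), wY(i))`, a generalization of intersection size,
and the relative distance

$$d(X \to Y) = 1 - \sigma(X,Y)/\sigma(X,X) \in [0,1],$$

the fraction of X's weight not covered by Y. `d(X→Y) = 0` exactly when Y
dominates X entrywise; d is asymmetric and does not satisfy the triangle
inequality. The relation `X→Y iff d(X→Y) ≤ ε` with ε = 0 is the dominance
partial order; ε = 0.15 (about one mismatching protein in seven)
tolerates experimental uncertainty at the cost of possible mutual
ε-closeness.

Mutually ε-close nodes are treated as evidence for the *same* biological
entity and merged, by a procedure resembling agglomerative clustering
under the symmetrized distance `d_sym = max(d(X→Y), d(Y→X))`:

1. **Step 0** merges all nodes with identical support weight vectors,
   yielding the non-redundant set (scheme `Z` stops here: support weights
   with ε = 0).
2. While any pair has `d_sym ≤ ε`, merge the closest pair into one node
   holding the union of their evidences, reset evidence weights to uniform
   `1/|E|`, recompute `n(i)` and all dependent weight vectors, and update
   distances.

Merging changes `n(i)` exactly for proteins in the merged union, so only
nodes sharing such proteins can see their adjusted or flow weights move;
the implementation recomputes precisely that affected set after each merge
(and a `recompute = "full"` mode exists to validate the bookkeeping, which
the test suite does). Ties on the minimal distance are broken by the
lexicographically smallest node-id pair, and node identifiers are assigned
from the sorted grouping keys, so the procedure is deterministic and
invariant under permutation of the input rows. One pair is merged per
iteration — the strictest reading of merging "the two closest" nodes —
since a single merge can change which pair is closest.

Both the merge condition and the edge condition use `≤ ε`. This makes the
two thresholds consistent: any pair tied at exactly ε in both directions
is merged, so no bidirectional edge can survive, and for every surviving
edge X → Y the two inequalities `σ(X,Y) ≥ (1−ε)σ(X,X)` and
`σ(X,Y) < (1−ε)σ(Y,Y)` force `σ(X,X) < σ(Y,Y)`: total weight strictly
increases along edges, which rules out cycles. `assert_acyclic()` verifies
the absence of bidirectional pairs, checks that constructive witness, and
produces a topological order; a violation would indicate a clustering bug,
not a property of the data. The floor c, κ and α are calibrated once from
the initial grouped corpus and held fixed during merging, while `n(i)` and
`u(e)` are recomputed dynamically — the calibration describes the corpus,
not the moving cluster state.

## Filtering and interpretation

A nominally large complex dominated by one regular-weight protein plus
heavily down-weighted common ones behaves like a binary interaction in
every distance computation. Effective size is measured by the
participation ratio `PR(w) = (Σw)²/Σw²` (n for n equal weights), and
nodes with `PR < 2.5` under the scheme's own weight vector are removed
after clustering, before classification — for the support schemes the
filter is near-vacuous by construction, since support weights of a single
evidence are all 1. Filtered nodes keep their merge history and are
reported separately.

Kept nodes are classified by their incident edges — *maximum* (only
incoming; the largest assemblies), *minimum* (only outgoing), *inner*
(both), *isolated* (neither) — and the undirected relation decomposes into
connected components, with isolated nodes reported as a class of their own
rather than as size-1 components. `protein_subgraph()` extracts the
induced subgraph of all nodes containing a given protein, the natural view
for asking "in which assemblies does this protein persist?".
`transitive_reduction()` removes edges implied by chains of others, for
display only; every analysis operates on the full edge set.

Hierarchies built under different schemes contain different merged nodes,
so `compare_dags()` first expands each hierarchy onto the shared
non-redundant set: a merged node of k constituents becomes k(k−1) ordered
within-node pairs, and each DAG edge becomes all between-constituent
pairs. Expansion is computed on the pre-filter graph with pairs incident
to filtered nodes labelled as such, so the provenance of every expanded
relation remains visible.

## The synthetic corpus generator

Real corpora come with no ground truth, so validation uses planted
universes (`generate_truth()`, `sample_evidence_corpus()`,
`sample_ppi()`): true complexes some of which are core subassemblies
embedded in one or two larger parents (a DAG, not a tree — mirroring a
stable core shared by several machines), redundant evidences per complex
with per-member false-negative drop-outs, uniform false-positive
contaminants, a designated pool of sticky proteins attaching independently
to any evidence (systematic noise, deliberately a separate channel from
the sporadic contaminants), and an interaction network much denser within
complexes than between them.

Default study conditions: a pool of 600 proteins, 16 complexes of 8–14
members (parents: core plus 8–14 extras), redundancy 3, within-complex
interaction density 0.95, sporadic background edge probability 2×10⁻⁴,
and every non-member protein carrying a single matched interaction
partner (`peripheral_fraction = 1`). The peripheral layer deserves
comment: it reproduces the degree skew of curated interactomes, where the
median degree is very small (so κ is 1 here, 3–4 in real corpora) while
complex cores are far denser. That skew is a genuine assumption of the
flow weighting — on a degree-homogeneous network the mean walk time is
bounded near 2 for every α and a target of 4 steps is unreachable, whereas
with the peripheral layer the supremum lies comfortably above it (5–8
across seeds at these conditions). Independent complexes draw disjoint
protein sets, so the planted subset relations are the only true
containments and recovery scoring is unambiguous; overlap between
complexes enters only through planted nesting, sticky attachment and
contaminants. This is deliberately not a fit to any real interactome's
degree distribution — the generator targets the method's assumptions, not
biological realism.

`score_recovery()` maps each final node to the true complex of maximal
support-weight overlap (ties to the smaller true id) and scores recovered
containment edges against the planted relations up to transitive closure
in both directions, plus *merge purity*, the fraction of final nodes whose
evidences originate from a single true complex.

What passing these tests shows — and does not. Perfect noise-free
recovery and the recall ordering flow ≥ adjusted ≥ support under noise
demonstrate the machinery and the intended effect of the weighting
schemes under controlled conditions with disjoint ground truth. Real
corpora have overlapping true complexes, correlated curation errors and
publication bias that the generator does not emulate; results on real data
depend on those factors in ways synthetic tests cannot certify.

## Numerical choices and limitations

- Linear systems are solved by sparse direct factorization (`Matrix`);
  at the problem sizes of interest (hundreds to a few tens of thousands of
  proteins) this is exact and fast. Expected visits satisfy a
  Neumann-series identity used as an independent test oracle.
- Distances are kept in a dense node×node matrix; corpora of up to a few
  thousand nodes are practical. The affected-set update after each merge
  keeps clustering near-quadratic rather than cubic.
- Support-weight equality in step 0 is exact equality of rational weights
  computed identically, implemented via a formatted signature at 15
  significant digits.
- Degenerate inputs: an empty interaction table leaves κ undefined and the
  flow scheme refuses to calibrate (the adjusted scheme remains
  available); evidence records listing the bait outside the member list
  are kept with a warning, membership being defined solely by the protein
  list; duplicate proteins within a record are collapsed with a warning.
- Test and acceptance runs use reduced problem sizes (pools of 300–600
  proteins, 8–16 complexes, up to 1000 corpora per property) chosen to
  exercise every code path at full statistical strength while keeping the
  whole suite fast.
- Limitations: evidence quality is modelled only through redundancy
  weighting; no probabilistic edges or confidence intervals on the DAG;
  binary (unweighted) interaction evidence only; identifier mapping
  between naming systems is out of scope and assumed done upstream.
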