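# complexHier

Organize protein-association evidence into a directed acyclic graph (DAG)
of part-of relationships between protein complexes.

Pull-down and co-fractionation experiments report *associations*: sets of
proteins retrieved together, each tied to a publication, a detection method
and (usually) a bait protein. Taken at face value these records are noisy —
the same complex is reported many times with slightly different member
lists, intrinsically sticky proteins (chaperones, cytoskeletal proteins)
show up in complexes they do not belong to, and individual members are
missed or spuriously added. `complexHier` reconciles such a corpus into a
hierarchy in which smaller complexes point to the larger assemblies they
are parts of, for anyone who wants to see how subcomplexes combine —
curators of complex databases, and analysts of AP-MS or co-fractionation
datasets.

## Model

Each complex node C carries a weight function over its member proteins,
under one of three schemes:

- **Support** `w_S(i)`: the fraction of C's (redundancy-weighted) evidences
  containing protein i. Evidences sharing (publication, method, bait) are
  grouped with weights u(e) = 1/k, so each reported complex contributes one
  unit of mass.
- **Adjusted** `w_A(i) = w_S(i) · min(1, c / n(i))`, where n(i) is the
  weighted number of complexes containing i and c is the weighted median of
  those counts: proteins occurring in more than c complexes — the globally
  "sticky" ones — are down-weighted proportionally.
- **Information flow** `w_N(i) = c · F_C(i) / max(n(i), c)`: walkers are
  placed on C's members proportionally to support and diffuse over the
  network of direct binary interactions under the substochastic operator
  `P(i,j) = A(i,j)/(deg(i)+κ)` (κ = median PPI degree) with damping α;
  `F_C = w_S (I − αP)^{-1}` counts expected visits, retained on C's member
  set. α is calibrated by Newton's method so the mean walk time
  `T̄(α) = mean[(I − αP)^{-1} 1]` equals a target (4 steps by default). At
  α = 0 the flow weights coincide exactly with the adjusted weights. Flow
  weighting amplifies interaction-connected complex cores, distinguishing
  consistently co-occurring members from randomly attached sticky proteins.

Complexes are compared by the weighted-overlap similarity
`σ(X,Y) = Σᵢ min(wX(i), wY(i))` (for indicator weights, the intersection
size) and the relative distance `d(X→Y) = 1 − σ(X,Y)/σ(X,X)`, which is 0
exactly when Y dominates X — "X is part of Y". Near-identical nodes
(mutual distance ≤ ε, default 0.15 ≈ one mismatching protein in seven) are
merged agglomeratively, which rescues false negatives and suppresses false
positives; the surviving relation `X→Y iff d(X→Y) ≤ ε` is then provably
acyclic, because total weight strictly increases along every edge. Nodes
with participation ratio `(Σw)²/Σw²` below 2.5 — effectively binary
interactions dressed up as complexes — are filtered, and the DAG is
classified (isolated / minimum / inner / maximum nodes), decomposed into
components, transitively reduced for display, and comparable across
schemes through expansion onto the non-redundant complex set.

## Worked example

The package ships a synthetic-corpus generator that plants nested
complexes, redundant noisy evidences, sticky proteins and a consistent PPI
network, so the whole pipeline can be exercised and scored against a known
ground truth:

```r
library(complexHier)
truth <- generate_truth(synth_params(fp_rate = 0.1, fn_rate = 0.1,
                                     sticky_count = 5), seed = 42)
ev  <- sample_evidence_corpus(truth, seed = 42)
ppi <- sample_ppi(truth, seed = 42)
h <- build_hierarchy(ev, ppi, scheme = "N4")
h
#> complex_hierarchy (scheme N4, epsilon 0.15)
#>   calibration: c = 5, kappa = 1, alpha = 0.943305 (mean walk time 4)
#>   nodes: 40 (filtered 0, isolated 2, minimum 15, inner 11, maximum 12)
#>   edges: 46 kept (46 before filtering); merges: 8
#>   connected components: 10
```

The calibration line reports the corpus floor c (proteins in more than c
complexes get down-weighted), the PPI median degree κ, and the damping α
solving for a mean walk time of 4 steps. Scoring against the planted truth:

```r
score_recovery(h, truth)[c("edge_precision", "edge_recall", "merge_purity")]
#> $edge_precision
#> [1] 1
#> $edge_recall
#> [1] 1
#> $merge_purity
#> [1] 1
```

Every planted core-inside-parent relation is recovered, no spurious
containment is asserted, and all merges united evidences of a single true
complex. `write_hierarchy(h, "out/")` exports node/edge/trace/weight
tables plus DOT and GraphML graphs; `protein_subgraph(h, "P0123")`,
`hierarchy_components(h)` and `compare_dags(hA, hB, baseline = hZ)` cover
the downstream analyses. A command-line front end with `build`,
`simulate`, `compare`, `subgraph` and `components` subcommands is installed
at `inst/scripts/complexhier.R`.

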