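---
title: "Methods: seed-chain-extend mapping to pangenome variation graphs"
author: "pgmap"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

pgmap maps long (and single-end short) reads to a *variation graph*: a
bidirected graph whose nodes carry DNA sequences, whose edges join node
*sides* (left or right), and in which a valid walk enters and leaves a node
on opposite sides — a reverse visit spells the node's reverse complement.
Haplotypes and reference sequences are embedded as named walks, and, as in
GBZ-style graphs, the edge set of a well-formed graph is exactly the set of
adjacencies supported by at least one walk; extra GFA links are retained but
flagged as non-haplotype.

The mapping pipeline is the seed–chain–extend scheme used by modern
long-read mappers, specialised to graphs:

1. **Snarl tree.** The graph is decomposed into nested *snarls* (sites of
   variation bounded by two separable, minimal node sides) and *chains*
   (maximal runs of nodes with snarls between them).
2. **Distance index.** Chain prefix coordinates and per-snarl boundary
   tables support minimum-distance queries between oriented base positions.
3. **Seeding.** A weighted-minimizer index over the haplotype spellings
   yields seeds pairing read offsets with oriented graph positions.
4. **Zip code tree.** Seeds are sorted by their snarl-tree address and
   bracketed by the boundaries containing them, giving ordered seed-to-seed
   graph distances.
5. **Chaining.** Two passes of dynamic programming select co-linear chains
   maximizing read coverage minus a minimap2-style gap cost.
6. **Extension.** Base-level alignment between consecutive seeds (wavefront
   alignment against haplotype spellings, with a banded global graph
   aligner as fallback) and outward from the terminal seeds (anchored tail
   alignment with an X-drop rule) produces the full-length alignment,
   scored, ranked and assigned a MAPQ, and emitted as GAF.

# Snarl decomposition

Two node sides are **separable** when cutting both their nodes into
disconnected half-vertices leaves the two tested faces in one component of
the side-adjacency graph; the snarl's **contents** are the nodes of that
component that cannot be reached from either boundary node's opposite face.
A candidate with empty contents is a *trivial* snarl and is represented
implicitly as chain adjacency.

Two operational rules had to be fixed where the definitions alone are
ambiguous:

* **Minimality / chain merging.** A separable pair is non-minimal when a
  single through-node splits it exactly: both sub-pairs separable, the
  contents partitioned exactly, and — crucially — every edge interior to
  the pair interior to one of the sub-pairs. Without the edge condition an
  indel bubble (whose deletion edge directly joins the two boundaries)
  would be wrongly flattened into a chain.
* **Canonical selection.** The decomposition is not unique: for example,
  the two allele sides of a bubble, facing outward, also form a separable
  pair enclosing everything on one side of the bubble. Candidates are
  therefore ordered by (min boundary id, max boundary id, contents size)
  and accepted greedily only if disjoint from, or properly nested within,
  everything already accepted. Chains are traversed so the lower node id
  comes first. The test-suite oracle applies the same canonicalization,
  independently implemented on igraph components.

Snarls containing directed cycles (tandem duplications) are flagged cyclic
and treated conservatively downstream. Decomposition is brute force over
candidate side pairs with reachability pruning — at desk scale
(hundreds of nodes) this takes seconds; output equivalence, not asymptotic
complexity, is the contract. Circular top-level chains are broken at the
lowest node id; the simulators never generate them.

# Distances

Distances are **base steps**: consecutive bases are at distance 1,
`d(A, A) = 0`, and unreachable pairs are `Inf` (never a magic number).
Queries are answered exactly by Dijkstra over the directed node-side graph,
which handles cycles and inversions without enumerating loops (a minimum
distance never benefits from an extra loop). The index also stores, per
chain, prefix coordinates of every item (snarl gaps contribute their
minimal through-distance) and, per snarl, the distances from each child
chain's two ends to the snarl boundaries in both traversal directions,
computed by Dijkstra restricted to the snarl interior. These structures are
what zip codes are made of.

# Zip codes and the zip code tree

A zip code is the root-to-leaf snarl-tree address of a position annotated
with those distances. Internally each seed carries, per level, four
quantities: distance from the level's start to the seed and from the seed
to the level's end, under forward and under reverse traversal of the
enclosing chain (`Inf` when infeasible). Climbing a level takes a minimum
over the two ways of entering a child chain (its canonical direction or
reversed), which is how inverted alleles join the same tree as their
flanks.

The forest splits seeds by connected component and by root-level heading;
within a tree, seeds are sorted by chain prefix coordinates (reversed for
the reverse-heading tree) with snarl children ordered by rank, and
bracketed by `chain`/`snarl` open and close items. The distance between two
seeds is resolved at the deepest level where their addresses diverge:
along a common chain it is the exact prefix-coordinate arithmetic; seeds in
sibling chains of one snarl are unreachable through the tree. Every finite
reported distance corresponds to a real walk, so on cyclic or inverted
regions the tree may over-report but never under-report a distance —
under-reporting would corrupt gap costs. On acyclic regions with no
reverse traversals the values are exact, and the test suite holds the tree
to 100% agreement with the distance index there.

# Chaining

The gap between consecutive seeds is `g = |read_gap - graph_gap|`; its
cost is `a*g + b*log2(g)` (0 when g = 0), with defaults `a = 0.01 k` and
`b = 0.5`, a transition cap `max_gap = 10000`, and up to `max_lookback =
64` predecessors per item in tree order. Pass 1 merges runs of
tree-order-consecutive seeds on a common diagonal (equal read and graph
gaps, read gap at most `fragment_max_gap = 200`) into fragments; pass 2
chains fragments under the full gap cost. Every seed also enters pass 2 as
a singleton item, so fragment boundaries can never hide the optimal chain —
the coverage-overlap penalty makes redundant representations score
identically, and the top score provably equals exhaustive enumeration
(checked on 500 random instances). Coverage counts read bases of an item
not already covered by its predecessor, so a chain's score is its covered
read bases minus its gap costs. Ties break toward longer read span, then
lower start offset.

Ranked chains are non-overlapping in the read by more than 50%; the best
chain excluded by that rule whose seeds are mostly disjoint from every
selected chain is remembered as the *competing placement* — it is the
ambiguity evidence for repeats, and the mapper extends it alongside the
selected chains so MAPQ compares alignment scores on the same scale.

# Base-level alignment

Scoring defaults are match +1, mismatch −4, gap open −6, gap extend −1 —
common long-read practice; the alignment layer is scale-free in these
parameters. Between consecutive anchors the read segment is aligned with a
gap-affine **wavefront** aligner against each haplotype spelling consistent
with both anchors (deduplicated, nearest lengths first). The wavefront
search runs in the penalty space `x = 2(M+|mm|), o = 2|go|, e = 2|ge|+M`,
in which minimum penalty over fixed endpoints is exactly maximum score
(`score = M(|q|+|t|)/2 - penalty/2`); the test suite checks score equality
with a full Gotoh matrix on a thousand random pairs. Exceeding the
configured cost budget is a declared failure, not an error.

On failure, when no consistent haplotype exists, or when the segment
exceeds `wfa_max_len`, a **banded global graph aligner** takes over: node
visits are unrolled into layers by graph offset (so cycles expand only as
far as the band allows), each layer runs an affine DP column over its node
bases with entry columns merging all predecessors, and cells outside
`|graph offset - read offset| <= band` are pruned. Its scores equal a
path-enumeration oracle on bubble graphs. `wfa_max_len` defaults to 8192:
the threshold is configuration, not a constant baked into the algorithm
(published descriptions of this fallback print an implausibly small
literal, apparently a typographic corruption of a power of two, so the
package simply exposes the knob).

Tails are aligned from the terminal anchors against haplotype
continuations. The full-length (whole-tail) reading is preferred whenever
it stays within the X-drop envelope of the best partial extension;
otherwise the remainder is soft-clipped. A graph X-drop extension exists
as the fallback when no haplotype passes through the anchor. Anchors
themselves are seeds verified to spell the read k-mer along a concrete
haplotype (endpoint agreement alone is not enough — a different allele of
a bubble inside the k-mer span can share both endpoints), and walk pieces
are joined with a merge rule that distinguishes a continued node visit
from a genuine second visit around a duplication loop. Every alignment is
re-scorable from its (walk, edits) pair alone, and the test suite does so.

# MAPQ

`mapq = clamp(0, 60, round(6 (primary - best_secondary) / match))`, where
the best secondary is the best competing alignment score, falling back to
the chain score of the best unextended chain, or 0. The formula is the
package's own; the tested contract is calibration — among reads reported
at MAPQ ≥ q, the empirical error rate stays within 3×10^(−q/10) for q in
{10, 30, 60} on the standard study — together with the cap of 60.

# Synthetic pangenomes and reads

The simulator lays SNV, insertion (1–50 bp, with a deletion edge),
inversion and tandem-duplication bubbles (3–20 bp segments) along a random
backbone at configurable per-base rates, assigns alleles to haplotypes at
a uniform random frequency per site, and derives the edge set from the
walks, so every graph satisfies the model invariants by construction.
Reads are drawn uniformly over haplotype positions on both strands with
independent per-base substitution, insertion and deletion errors.

What this does *not* emulate: correlated or homopolymer-biased error
profiles of real instruments, long repeats beyond the duplication
cassettes, structural variants larger than 50 bp, and graphs whose ids are
not in left-to-right creation order. Passing tests therefore demonstrate
algorithmic correctness under clean conditions, not benchmark performance
on real data.

A mapped read is judged **correct** when its reported walk shares at least
50% of its node-bases with the truth walk slice; this criterion is the
package's own choice and is applied symmetrically to every mapper output.

# Study sizes

The standard desk-scale study, used by the acceptance checks and
reproducible with `scripts/acceptance.R`:

* snarl decomposition against the exhaustive oracle on 200 random graphs
  of up to 120 nodes;
* distance queries against a base-level BFS oracle on 50 graphs (≤ 200
  nodes) over more than 10,000 sampled position pairs, including cyclic
  and inverted fixtures;
* zip-tree exactness on acyclic fixtures and zero under-reports across
  ≥ 10,000 pairs on cyclic ones;
* chain optimality on 500 random instances of up to 12 seeds;
* aligner optimality on 1000 random pairs (length ≤ 300, up to 15% edits)
  and on all bubble fixtures of ≤ 30 nodes;
* end-to-end: a 20 kb, 8-haplotype pangenome with 1000 error-free and
  1000 5%-error 1 kb reads, evaluated for accuracy and MAPQ calibration,
  plus byte-level determinism of GFA, FASTQ and GAF outputs under fixed
  seeds.

# Known limitations

* Chains of the snarl tree must be simple paths at every level; braided
  regions that give a node side two chain links raise an error rather than
  guessing (the simulators cannot produce them).
* Sibling alleles are unreachable through the zip tree even when a cyclic
  detour connects them; this is the conservative side of the
  over-approximation contract.
* Tail alignment against the graph (as opposed to haplotype continuations)
  reports a conservative head offset for left tails; it is only reached
  when no embedded haplotype passes the anchor.
* Paired-end rescue, reference-projection (SAM) output, haplotype
  sampling, and succinct index encodings are out of scope.
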