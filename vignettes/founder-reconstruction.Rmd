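---
title: "Founder set reconstruction under homologous recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder set reconstruction under homologous recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderset)
```

## The model

Complex, segmental-duplication-rich loci evolve largely through
homologous recombination between highly similar sequence segments.
`founderset` works at the level of *markers*: opaque symbols standing for
homologous DNA segments, produced upstream by any pangenome graph builder
that assigns homology (marker decomposition itself is out of scope). A
haplotype is a walk of oriented markers that starts with a forward source
marker `s` and ends with a forward sink marker `S`; interior markers may
appear any number of times in either orientation, which is how deletions,
duplications and inversions are representable. Reverse complementation
reverses a walk and flips every orientation.

Recombination is modeled as a crossover at a shared, identically oriented
marker: for walks $A$ and $B$ with $A[i] = B[j]$, the product is
$A[1..i] + B[j+1..]$. Because both allelic and non-allelic (positionally
displaced) crossovers are allowed, iterating the operator generates the
*span* of a haplotype set: all haplotypes reachable by any series of
crossovers among the set, its reverse complements, and previous products.

The span has a purely local characterization: a haplotype lies in the
span if and only if each of its consecutive oriented pairs occurs in the
input set or its reverse complements. Equivalently, the span is the set
of source-to-sink walks of the *variation graph*, an undirected
edge-colored multigraph whose nodes are marker extremities (tail/head),
with one marker edge per marker and one adjacency edge per observed
consecution. A consecution and its reverse-complement reading are one and
the same adjacency edge; this deduplication matters in practice — in the
bundled four-haplotype example, the pair "forward 3, forward 4" (from the
second haplotype) and "reverse 4, reverse 3" (from the first and third)
meet in the single edge joining the head of 3 to the tail of 4, giving 11
distinct adjacency edges.

```{r example-graph}
E2 <- example_haplotypes()
graph_stats(build_variation_graph(E2))[c("n_markers", "n_adjacency_edges")]
```

## Founder sets as a minimum network flow

A *founder set* is a generating set of the span with minimum total
length. Total length, not cardinality, is the objective: loci expand over
time through duplication, so ancestral configurations are expected to be
the compact ones, and a cardinality objective would admit absurdly long
founders. The package solves this as an integer network flow on the
variation graph:

* flow travels along adjacency edges, in either direction, in whole
  units; every adjacency edge and every marker must be covered at least
  once (so the founder set regenerates the whole graph, hence the whole
  span);
* at every extremity, incoming adjacency flow equals the marker
  traversals entering there and outgoing flow equals the traversals
  exiting there, with the source tail supplying path starts and the sink
  head absorbing path ends; terminals are traversed forward only, so no
  founder can start at the sink or end at the source;
* the objective is the total adjacency flow, which for any decomposition
  into walks equals total founder length minus the number of founders.

An optimal flow is decomposed by a seeded random walk that consumes flow
unit by unit; revisited extremities close alternating cycles, which are
excised on the spot, and exhausted source starts leave a circulation that
is swept into further cycles. Cycles are then integrated into the
source-to-sink walks through the *component graph*: each cycle points at
every component it shares a marker with, and is spliced in at a shared
marker occurrence — with its linearization reverse-complemented when the
marker is embedded in opposite orientation — preferring walks over cycles
and in-degree-zero cycles first.

Two outputs of this pipeline are canonical and stable under re-solving:
the optimal objective value and the founder count (the flow through the
source). The founder *strings* are one member of a typically large pool
of co-optimal solutions and depend on the decomposition seed; the
randomized-trials counter below exploits exactly this freedom.

## Counting recombinations

Given a sequence set and a query, the minimum number of crossovers needed
to produce the query is one less than the minimum number of *blocks* in a
segmentation of the query into segments that each occur contiguously in
some set member or its reverse complement, with consecutive blocks
overlapping by exactly one marker (the crossover site). The greedy rule —
always take the longest feasible prefix, then restart at its last
marker — is provably optimal, and a query is infeasible exactly when some
step's longest prefix has length at most one, which coincides with the
pair-support span criterion. The implementation matches prefixes against
the concatenation of the set and its reverse complements with separator
sentinels; the contract is the longest-prefix function, not any
particular index structure, and the iterative recursion touches each
query position at most once. An independent quadratic dynamic program
over cut positions is included as a verification oracle and is fuzzed
against the greedy segmentation in the tests (1000+ random cases).

```{r count}
H <- example_single_haplotype()
count_recombinations(H, ">s<1>2>3>4<3>S")
```

## Minimizing recombinations over founder sets

Jointly minimizing founder length and construction recombinations is
intractable to search directly. The package follows a two-stage
strategy: fix the consecutive-pair multiplicities (mu-hat) and marker
multiplicities (gamma-hat) from a Problem-1 founder set, then optimize
the arrangement of exactly those building blocks. The result is exact
*conditional on the multiplicities*; it is heuristic overall, since no
guarantee exists that a globally parsimonious founder set has optimal
flow. The package never claims more.

The search space is encoded as a *flow graph*: each extremity gets
gamma-hat in-copies and out-copies; each marker orientation contributes a
complete bipartite set of directed marker edges over its copies (copy
labels are therefore interchangeable, which is why a deterministic
sorted/sequential slot allocation is correctness-neutral); each oriented
pair realization contributes exactly mu-hat directed adjacency edges,
each out copy carrying at most one outgoing and each in copy at most one
incoming edge. Both directed realizations of a canonical pair are
materialized — a founder may spell an occurrence in either reading
direction, and with a single realization some out copies would be left
edgeless, breaking the degree structure the matching relies on.

The integer linear program selects a saturated half of the graph: a
perfect matching of marker edges on saturated nodes (per marker, exactly
half the copies), adjacency edges saturated exactly when both endpoints
are (so saturated components are maximal alternating walks), per-marker
and per-pair saturation pinned to gamma-hat and mu-hat, and an integer
rank flow bounded by the total marker multiplicity `T` that increases by
one across saturated marker edges and stays constant across saturated
adjacency edges, which rules out saturated cycles (their rank would be
unbounded); `T` also serves as the big-M in the linearization. Every
saturated node is assigned one occurrence position among the haplotypes
and their reverse complements, adjacency edges propagate assignments to
consecutive positions, and a marker edge scores one objective unit when
both of its endpoints carry the same occurrence — i.e., when that marker
traversal continues a haplotype block. Maximizing the score minimizes
recombinations: the reported count is `T` minus the score, and the
extracted founders carry a per-position annotation with their source
haplotype and starred recombination sites.

```{r minimize}
sol <- minimize_recombinations(E2, rng_seed = 1)
sol$recombinations
head(sol$annotation)
```

## The simulator

The bundled simulator emulates the benchmarking design used for this
method family: it builds a seed haplotype from the identity walk over `n`
markers by applying `ceiling(dup_ratio * n)` duplication events — each
copies a uniformly chosen segment of 1–3 markers to a uniformly chosen
position, inverted with probability `inv_ratio` — and then samples
haplotypes as uniform random source-to-sink walks of the seed's variation
graph, discarding walks that exceed `max_walk_factor` (default 4) times
the seed length before reaching the sink. The segment-length range,
uniform insertion position and uniform walk continuation are this
package's declared defaults where finer detail was unspecified; all are
recorded in the parameter object so runs are auditable. Duplication is
performed at sequence level; every copy insertion induces the
corresponding extra graph adjacencies, which is the declared reading of
duplications as "additional edges".

The simulator reports no true founder set, deliberately: the seed
generates the span but need not be a minimum-length generator, so
simulated instances probe feasibility, invariants and the
optimized-versus-randomized comparison rather than recovery accuracy.
What passing simulated tests cannot show: robustness to marker
misassignment (homology errors are upstream of this model), realistic
recombination-rate heterogeneity (every shared marker is equally
recombinogenic here), and scaling behavior at hundreds of thousands of
markers.

## Numerical and design choices

* **Solver backend.** All integer programs are passed to HiGHS through
  `scipy.optimize.milp` in a python subprocess, behind the
  `solver_config()` surface; problems are exchanged as sparse-triplet
  JSON. Integrality is demanded explicitly rather than relying on any
  relaxation. With a `time_limit`, best-effort solutions are returned and
  flagged; proven-optimal objective values are the canonical outputs.
* **Seeds.** Every random choice (decomposition neighbor selection, cycle
  integration order, simulator streams, trial streams) flows through an
  explicit integer seed, and trial seeds are derived deterministically
  from the stream seed, so any co-optimal variation is reproducible.
* **Tie-breaks.** Decomposition picks uniformly among positive-flow
  continuations; cycle integration picks uniformly among eligible
  cycles/edges after the walk-first, in-degree-zero-first rules.
* **Degenerate inputs.** Self-loop adjacencies (palindromic or
  tandem-duplication consecutions) are single edges and consume one flow
  unit per traversal; one-marker cycles are legal. Markers named in the
  table but absent from every walk are outside the universe: they get no
  marker edge and no coverage constraint (a simulation seed's table may
  name more markers than its sampled walks visit). Queries using unknown
  markers are infeasible, not errors.
* **Orientation canonicalization.** A pair and its reverse complement
  share one canonical key throughout (counts, edges, oracles), with the
  lexicographically smaller reading as representative.
* **Problem sizes.** The test suite verifies worked examples exactly,
  fuzzes the greedy/DP equivalence on over a thousand random queries,
  cross-checks founder minimality against exhaustive span-subset search
  on instances with up to three non-terminal markers, and runs the
  paired optimized-versus-randomized comparison on 50 simulated
  replicates with 8 markers and 4 haplotypes. The acceptance script uses
  20-marker, 10-haplotype replicates of the simulator's reference
  setting (10% duplications, 10% inversions). These sizes were chosen so
  the full pipeline, including exhaustive oracles, stays comfortably
  interactive; on larger instances the matching ILP becomes the
  bottleneck long before the flow stage does, and a solver time limit
  is the recommended control.

## Limitations

Exactness of the minimization is conditional on the multiplicity oracle;
results are reported as such. The matching ILP's size grows with the
product of marker multiplicities and haplotype length, and dense
duplication structure inflates it quickly — a solver time limit is the
intended safety valve, not an afterthought. Sequence-level phenomena
(NHEJ, mobile elements, rate heterogeneity, similarity thresholds) are
not modeled beyond what marker decomposition encodes. The walk format
treats markers as opaque; no nucleotide handling is provided anywhere.
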