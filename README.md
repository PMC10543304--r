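# founderset

Founder set reconstruction for marker-level haplotypes under a
homologous-recombination model that covers both allelic and non-allelic
(NAHR) crossovers — and therefore deletions, duplications and inversions.

Complex segmental-duplication loci (such as the human 1p36.13 region)
rearrange mainly through recombination between highly similar segments.
`founderset` represents haplotypes as walks of oriented markers
$A = s\,m_1 m_2 \ldots m_k\,S$ over a universe $\mathcal{M}$ with source
and sink terminals, where each marker can be traversed forward or reverse
($\overline{m}$). Recombination is a crossover at a shared, identically
oriented marker: $\chi(A, B, i, j) = A[..i] + B[j+1..]$ whenever
$A[i] = B[j]$. The package answers three questions for a haplotype set
$\mathcal{H}$:

1. **Founder set** — find a generating set $\mathcal{F}$ with
   $\mathrm{span}(\mathcal{F}) = \mathrm{span}(\mathcal{H})$ minimizing
   $\sum_{A \in \mathcal{F}} |A|$. Solved exactly as a minimum integer
   network flow on the bidirected variation graph $G_\mathcal{H}$ over
   marker extremities, followed by flow decomposition into alternating
   paths and cycles and cycle integration into source-to-sink walks.
2. **Recombination count** — the minimum number of crossovers needed to
   generate a query $Q$ from a sequence set $\mathcal{T}$, via the
   provably optimal greedy longest-block segmentation
   $R_\mathcal{T}(Q)$: repeatedly match the longest prefix of $Q$ that
   occurs in $\mathcal{T} \cup \overline{\mathcal{T}}$, overlapping
   consecutive blocks by one marker; $|$blocks$| - 1$ is the answer, and
   infeasibility coincides with span non-membership.
3. **Parsimonious founder set** — among founder sets with pair
   multiplicities $\hat\mu$ fixed from a Problem-1 solution, minimize
   total recombinations to build the founders from $\mathcal{H}$, via an
   integer linear program that selects a saturated perfect matching in a
   copy-expanded flow graph $G_{\mathcal{H},\hat\mu}$ (exact conditional
   on $\hat\mu$; heuristic overall).

A seeded simulator (duplication/inversion-decorated seed haplotype,
random-walk sampling of its variation graph) is included for
benchmarking, plus walk-format and GFA1 input/output and a command-line
interface (`inst/cli/founderset.R`).

## Worked example

The bundled four-haplotype set features a tandem duplication of marker 1,
an inverted repeat of markers 3/4, and a deletion:

```r
library(founderset)
E2 <- example_haplotypes()
graph_stats(build_variation_graph(E2))[c("n_markers", "n_adjacency_edges")]
#> $n_markers
#> [1] 6
#> $n_adjacency_edges
#> [1] 11

F2 <- founder_set(E2, rng_seed = 1)
F2
#> hap_set: 2 walk(s) over 6 markers (source=s, sink=S)
#>   founder1     >s>1>1>2>S
#>   founder2     >s<1>2>3>4<3>2>3>4<3>S
attr(F2, "objective")
#> [1] 14
```

Two founders of total length 16 (the flow objective 14 plus one per
founder) regenerate exactly the span of the four haplotypes. Minimizing
recombinations over founder sets with these pair multiplicities:

```r
sol <- minimize_recombinations(E2, rng_seed = 1)
sol$recombinations
#> [1] 2
subset(sol$annotation, is_recombination)
#>     founder position marker source_seq source_pos is_recombination
#> 7  founder2        3     >1         H2          4             TRUE
#> 11 founder2        7     <3         H3          6             TRUE
```

Both founders can be stitched from haplotype blocks with just two
crossovers, each starred at the marker where the source haplotype
switches. Counting recombinations directly: the single-haplotype example
`>s<1>2>3<4<3>S` spans exactly one further haplotype (an inversion
between the two reverse-oriented copies of marker 3), reachable with two
crossovers:

```r
H <- example_single_haplotype()
count_recombinations(H, ">s<1>2>3>4<3>S")
#> segmentation: 3 block(s), 2 recombination(s)
```

## Data formats

Walks are token strings, `>id` forward and `<id` reverse, one record per
line or `name<TAB>walk` (`read_walks()`/`write_walks()`). Inputs whose
terminals are ordinary ids — e.g. locus tables using markers 1 and 8 as
source and sink — are supported via `source`/`sink` arguments
(`load_locus_walks()`), and `write_gfa()` exports the variation graph as
GFA1 for rendering with the usual graph viewers.
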