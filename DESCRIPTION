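Package: founderset
Title: Founder Set Reconstruction for Haplotypes Under Homologous Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs minimal founder sets of marker-level haplotypes under a
    recombination model that covers both allelic and non-allelic homologous
    recombination (NAHR), and therefore deletions, duplications and inversions.
    Haplotypes are walks of oriented genomic markers bracketed by source and sink
    terminals. The package builds the bidirected variation graph of a haplotype
    set, solves the founder set problem as a minimum integer network flow,
    decomposes the flow into paths and cycles and integrates cycles into founder
    haplotypes; counts the minimum number of recombinations needed to generate a
    query from a sequence set by greedy longest-block segmentation; and minimizes
    the total number of recombinations over founder sets with fixed pair
    multiplicities via an integer linear program on a copy-expanded flow graph.
    A haplotype simulator with tunable duplication and inversion rates is
    included for benchmarking, along with walk-format and GFA1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: python3 with scipy (>= 1.9) for the integer linear
    programming backend
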