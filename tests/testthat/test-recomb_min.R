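test_that("the multiplicity oracle counts pairs and marker copies", {
  H <- example_single_haplotype()
  o <- estimate_mu_hat(H)
  expect_true(all(o$mu == 1L))
  expect_length(o$mu, 6L)              # six distinct pairs in A
  expect_equal(unname(o$gamma[H$markers == "3"]), 2L)  # marker 3 occurs twice
  expect_equal(o$n_founders, 1L)
  E2 <- example_haplotypes()
  F2 <- founder_set(E2, rng_seed = 1)
  o2 <- estimate_mu_hat(F2)
  expect_equal(unname(o2$gamma[E2$source]), 2L)  # gamma(s) = number of founders
  expect_equal(unname(o2$gamma[E2$sink]), 2L)
  # round trip: recounting pairs of F reproduces mu exactly
  expect_identical(o2$mu, founderset:::pair_count_table(F2))
  # symmetry: the canonical key of a pair and its reverse complement agree
  for (k in names(o2$mu)) {
    p <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    expect_equal(founderset:::pair_key(p[1], p[2]),
                 founderset:::pair_key(-p[2], -p[1]))
  }
})

test_that("the copy-expanded flow graph has the postulated shape", {
  H <- hap_set(list(w = ">s>1>S"))
  fg <- build_flow_graph(H, estimate_mu_hat(H))
  # 3 markers with gamma 1 each: 4 nodes per marker
  expect_equal(nrow(fg$nodes), 12L)
  # forward marker edges for terminals, forward + reverse for marker 1
  expect_equal(nrow(fg$marker_edges), 4L)
  # each of the two canonical pairs has two directed realizations
  expect_equal(nrow(fg$adjacency_edges), 4L)
  expect_equal(nrow(fg$adjacency_edges), sum(2L * fg$mu))
  expect_equal(fg$total_flow, 3L)

  E2 <- example_haplotypes()
  F2 <- founder_set(E2, rng_seed = 1)
  o2 <- estimate_mu_hat(F2)
  fg2 <- build_flow_graph(E2, o2)
  # 4 * gamma(m) nodes per marker
  expect_equal(nrow(fg2$nodes), sum(4L * o2$gamma))
  # every out copy except sink-head carries at most one outgoing adjacency
  # edge, every in copy except source-tail at most one incoming
  expect_false(anyDuplicated(fg2$adjacency_edges$from) > 0)
  expect_false(anyDuplicated(fg2$adjacency_edges$to) > 0)
  # total directed adjacency edges = sum of mu over oriented pairs
  n_oriented <- sum(vapply(names(o2$mu), function(k) {
    p <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    o2$mu[[k]] * (if (p[2] == -p[1]) 1L else 2L)
  }, integer(1)))
  expect_equal(nrow(fg2$adjacency_edges), n_oriented)
  # an inconsistent oracle is rejected
  bad <- o2
  bad$mu[1] <- bad$mu[1] + 5L
  expect_error(build_flow_graph(E2, bad), "inconsistent")
})

test_that("the matching ILP finds two recombinations on the worked example", {
  E2 <- example_haplotypes()
  sol <- minimize_recombinations(E2, rng_seed = 1)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$recombinations, 2L)
  FF <- extract_annotated_founders(sol)
  expect_length(FF$walks, 2L)
  expect_equal(sum(sol$annotation$is_recombination), 2L)
  # extracted founders realize exactly the oracle pair multiset
  F1 <- attr(sol, "flow_founders")
  expect_identical(founderset:::pair_count_table(FF),
                   founderset:::pair_count_table(F1))
  # consistency with the greedy counter at proven optimality
  expect_equal(founder_recombination_total(E2, FF), sol$recombinations)
})

test_that("a founder multiset equal to the haplotypes needs no recombination", {
  E2 <- example_haplotypes()
  oracle <- estimate_mu_hat(E2)        # pretend H itself is the founder set
  fg <- build_flow_graph(E2, oracle)
  sol <- solve_min_recombinations(fg, E2)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$recombinations, 0L)
  expect_false(any(sol$annotation$is_recombination))
  expect_equal(walk_strings(sol$founders$walks, E2),
               walk_strings(E2$walks, E2))
})

test_that("the saturated subgraph satisfies the structural invariants", {
  E2 <- example_haplotypes()
  sol <- minimize_recombinations(E2, rng_seed = 1)
  FF <- sol$founders
  F1 <- attr(sol, "flow_founders")
  oracle <- estimate_mu_hat(F1)
  # saturated marker edges = sum over markers of gamma: one per position
  expect_equal(sum(lengths(FF$walks)), sum(oracle$gamma))
  # founder count equals gamma(s): node-disjoint source-to-sink paths
  expect_length(FF$walks, oracle$n_founders)
  # "exactly half" property: per marker, saturated node count would be
  # 2 * gamma(m) of the 4 * gamma(m) copies; equivalent per-position check
  occ <- table(abs(unlist(FF$walks)))
  expect_equal(as.integer(occ[as.character(seq_along(oracle$gamma))]),
               as.integer(oracle$gamma))
})

test_that("the ILP never beats the conditional optimum of the greedy counter", {
  # per-founder greedy counts are individually minimal, so their sum over
  # any mu-consistent founder set bounds the ILP objective from below
  for (seed in c(3, 11)) {
    H <- simulate_haplotypes(sim_params(n_markers = 8, dup_ratio = 0.25,
                                        inv_ratio = 0.25, n_haplotypes = 4,
                                        rng_seed = seed))
    sol <- minimize_recombinations(H, rng_seed = seed)
    expect_equal(sol$status, "optimal")
    expect_equal(founder_recombination_total(H, sol$founders),
                 sol$recombinations)
    rt <- random_trials(H, n_trials = 3, rng_seed = seed)
    expect_lte(sol$recombinations, rt$best)
  }
})
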