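test_that("the minimum flow on the worked example forces two founders", {
  E2 <- example_haplotypes()
  G <- build_variation_graph(E2)
  fl <- solve_min_flow(G)
  expect_equal(fl$status, "optimal")
  expect_equal(fl$n_founders, 2L)     # two adjacency edges leave s^h
  expect_equal(fl$objective, sum(fl$arcs$flow))
  # coverage invariants
  per_edge <- tapply(fl$arcs$flow, fl$arcs$edge, sum)
  expect_true(all(per_edge >= 1L))
  expect_true(all(fl$fwd + fl$rev >= 1L))
  expect_equal(unname(fl$rev[c(G$source, G$sink)]), c(0L, 0L))
})

test_that("a single haplotype with distinct adjacencies is its own founder set", {
  H <- example_single_haplotype()
  G <- build_variation_graph(H)
  fl <- solve_min_flow(G)
  expect_equal(fl$objective, length(H$walks$A) - 1L)
  expect_true(all(fl$arcs$flow %in% 0:1))
  F1 <- founder_set(H)
  # the founder is a single walk of the same length and pair set as A
  # (the span holds a co-optimal alternative differing by one inversion)
  expect_length(F1$walks, 1L)
  expect_length(F1$walks[[1]], length(H$walks$A))
  expect_setequal(canonical_pairs(F1), canonical_pairs(H))
  expect_true(span_contains(H, F1$walks[[1]]))
})

test_that("flow decomposition consumes the flow exactly and yields valid parts", {
  E2 <- example_haplotypes()
  G <- build_variation_graph(E2)
  fl <- solve_min_flow(G)
  for (seed in 1:10) {
    comps <- decompose_flow(fl, G, rng_seed = seed)
    kinds <- vapply(comps, `[[`, "", "kind")
    expect_equal(sum(kinds == "path"), fl$n_founders)
    # paths are haplotypes; cycles contain no terminals
    for (cm in comps) {
      if (cm$kind == "path") expect_true(is_haplotype(cm$walk, E2))
      else expect_false(any(abs(cm$walk) %in% c(E2$source, E2$sink)))
    }
    # arc traversal counts over all components reproduce phi exactly
    consumed <- integer(nrow(fl$arcs))
    for (cm in comps) {
      w <- cm$walk
      steps <- if (cm$kind == "path") seq_len(length(w) - 1L)
      else seq_along(w)
      for (i in steps) {
        a <- w[i]
        b <- w[if (i == length(w)) 1L else i + 1L]
        u <- founderset:::exit_ext(a); v <- founderset:::entry_ext(b)
        k <- which(fl$arcs$from == u & fl$arcs$to == v)
        if (length(k) == 0L) k <- which(fl$arcs$from == v & fl$arcs$to == u &
                                          fl$arcs$from == fl$arcs$to)
        expect_length(k, 1L)
        consumed[k] <- consumed[k] + 1L
      }
    }
    expect_identical(consumed, fl$arcs$flow)
  }
})

test_that("an all-ones flow on a simple path decomposes into a single path", {
  H <- hap_set(list(w = ">s>1>2>3>S"))
  G <- build_variation_graph(H)
  fl <- solve_min_flow(G)
  comps <- decompose_flow(fl, G, 4)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$kind, "path")
  expect_identical(comps[[1]]$walk, H$walks$w)
})

test_that("the component graph links cycles to components sharing markers", {
  E2 <- example_haplotypes()
  G <- build_variation_graph(E2)
  fl <- solve_min_flow(G)
  comps <- decompose_flow(fl, G, rng_seed = 1)
  cg <- build_component_graph(comps)
  kinds <- vapply(comps, `[[`, "", "kind")
  cyc <- which(kinds == "cycle")
  expect_true(all(cyc %in% cg$edges$from))      # every cycle has out-degree >= 1
  expect_false(any(kinds[cg$edges$from] == "path"))
  for (r in seq_len(nrow(cg$edges))) {
    ci <- cg$edges$from[r]; cj <- cg$edges$to[r]
    expect_true(abs(cg$edges$label[r]) %in% abs(comps[[ci]]$walk))
    expect_true(abs(cg$edges$label[r]) %in% abs(comps[[cj]]$walk))
  }
  # edgeless case: no cycles
  H <- hap_set(list(w = ">s>1>S"))
  Gh <- build_variation_graph(H)
  cg0 <- build_component_graph(decompose_flow(solve_min_flow(Gh), Gh, 1))
  expect_equal(nrow(cg0$edges), 0L)
})

test_that("cycle splicing preserves the pair multiset plus the junction copy", {
  # walk >s>1>2>S with cycle (>2>3) shared at marker 2
  w <- c(1L, 3L, 4L, 2L)
  cyc <- c(4L, 5L)
  out <- founderset:::splice_cycle(w, cyc, 4L)
  expect_identical(out, c(1L, 3L, 4L, 5L, 4L, 2L))
  # opposite embedding: the reversed linearization is inserted
  w2 <- c(1L, -4L, 2L)
  out2 <- founderset:::splice_cycle(w2, cyc, 4L)
  expect_identical(out2, c(1L, -4L, -5L, -4L, 2L))
  # pair multiset: union of both components' pairs plus the junction pair
  p_before <- founderset:::pair_count_table(list(w))
  p_cycle <- founderset:::pair_count_table(list(c(cyc, cyc[1])))
  p_after <- founderset:::pair_count_table(list(out))
  joint <- table(c(rep(names(p_before), p_before), rep(names(p_cycle), p_cycle)))
  expect_equal(sum(p_after), sum(joint))
  expect_setequal(names(p_after), names(joint))
})

test_that("the founder pipeline preserves the span and minimizes total length", {
  E2 <- example_haplotypes()
  F2 <- founder_set(E2, rng_seed = 1)
  expect_length(F2$walks, 2L)
  expect_setequal(canonical_pairs(F2), canonical_pairs(E2))
  expect_equal(sum(lengths(F2$walks)), attr(F2, "objective") + 2L)
  # mu of the founder set is itself a feasible flow achieving the optimum
  expect_equal(sum(founderset:::pair_count_table(F2)),
               attr(F2, "objective"))
  # all founders are haplotypes (never start at the sink or end at the source)
  for (w in F2$walks) expect_true(is_haplotype(w, E2))
})

test_that("founder total length matches the exhaustive oracle on tiny instances", {
  instances <- list(
    example_single_haplotype(),
    hap_set(list(H1 = ">s>1>2>S", H2 = ">s>2>1>S")),
    hap_set(list(H1 = ">s>1>1>2>S", H2 = ">s>1>2>S")),
    hap_set(list(H1 = ">s>1<2>3>S", H2 = ">s>1>2>3>S", H3 = ">s>3>S")),
    simulate_haplotypes(sim_params(n_markers = 3, dup_ratio = 0.4,
                                   inv_ratio = 0.5, n_haplotypes = 3,
                                   rng_seed = 2)),
    simulate_haplotypes(sim_params(n_markers = 3, dup_ratio = 0.34,
                                   inv_ratio = 0, n_haplotypes = 2,
                                   rng_seed = 4))
  )
  for (H in instances) {
    F1 <- founder_set(H, rng_seed = 3)
    oracle <- min_founder_total_length_oracle(
      H, max_len = attr(F1, "objective") + 1L,
      max_size = length(F1$walks) + 1L)
    expect_equal(sum(lengths(F1$walks)), oracle)
  }
})

test_that("founder sets are reproducible under a fixed seed", {
  H <- simulate_haplotypes(sim_params(n_markers = 8, dup_ratio = 0.3,
                                      inv_ratio = 0.3, n_haplotypes = 4,
                                      rng_seed = 31))
  F1 <- founder_set(H, rng_seed = 17)
  F2 <- founder_set(H, rng_seed = 17)
  expect_identical(F1$walks, F2$walks)
})
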