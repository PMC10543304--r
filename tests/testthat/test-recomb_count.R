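test_that("the longest block prefix is found with a witness", {
  H <- example_single_haplotype()
  B <- walk_of(H, ">s<1>2>3>4<3>S")
  r <- longest_block_prefix(H, B)
  expect_equal(r$length, 4L)           # ">s<1>2>3"; length 5 occurs nowhere
  expect_equal(r$witness$id, "A")
  expect_equal(r$witness$offset, 1L)
  full <- longest_block_prefix(H, H$walks$A)
  expect_equal(full$length, length(H$walks$A))
  # a segment of the reverse complement is witnessed with orientation -1
  rc_seg <- reverse_complement(H$walks$A)[2:4]
  rr <- longest_block_prefix(H, rc_seg)
  expect_equal(rr$length, 3L)
  expect_equal(rr$witness$orientation, -1L)
  expect_equal(longest_block_prefix(H, walk_of(H, ">4>4"))$length, 1L)
  none <- longest_block_prefix(list(walk_of(H, ">s>S")), c(5L))
  expect_equal(none$length, 0L)
  expect_null(none$witness)
})

test_that("greedy segmentation reproduces the worked inversion example", {
  H <- example_single_haplotype()
  seg <- count_recombinations(H, ">s<1>2>3>4<3>S")
  expect_equal(seg$recombinations, 2L)
  expect_equal(seg$blocks$start, c(1L, 4L, 6L))
  expect_equal(seg$blocks$end, c(4L, 6L, 7L))
  # consecutive blocks overlap by exactly one position and cover the query
  expect_equal(seg$blocks$start[-1], seg$blocks$end[-nrow(seg$blocks)])
  # every block is a verified substring of the set or its reverse complements
  Q <- walk_of(H, ">s<1>2>3>4<3>S")
  pool <- c(H$walks, lapply(H$walks, reverse_complement))
  for (i in seq_len(nrow(seg$blocks))) {
    blk <- Q[seg$blocks$start[i]:seg$blocks$end[i]]
    hit <- any(vapply(pool, function(A) {
      any(vapply(seq_len(length(A) - length(blk) + 1L), function(o)
        identical(A[o:(o + length(blk) - 1L)], blk), logical(1)))
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("membership, feasibility and the span criterion coincide", {
  H <- example_single_haplotype()
  expect_equal(count_recombinations(H, H$walks$A)$recombinations, 0L)
  bad <- ">s>1>2>3>S"
  seg <- count_recombinations(H, bad)
  expect_false(seg$feasible)
  expect_equal(seg$recombinations, Inf)
  expect_false(span_contains(H, bad))
  # fuzz: feasibility of the segmentation <=> pair-support span criterion
  set.seed(71)
  for (r in 1:100) {
    T <- random_tiny_hapset(3L, 2L, 5L)
    Q <- random_tiny_hapset(3L, 1L, 5L)$walks[[1]]
    expect_equal(count_recombinations(T, Q)$feasible, span_contains(T, Q))
  }
})

test_that("greedy equals the exact dynamic-programming oracle on fuzz cases", {
  set.seed(97)
  n_cases <- 0L
  for (r in 1:250) {
    T <- random_tiny_hapset(3L, sample(1:3, 1), sample(3:7, 1))
    bi <- block_index(T)
    for (q in 1:4) {
      Q <- c(1L, sample(c(-(3:5), 3:5), sample(2:10, 1), replace = TRUE), 2L)
      greedy <- count_recombinations(bi, Q)$recombinations
      expect_identical(greedy, min_segmentation_oracle(bi, Q))
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 1000L)
})

test_that("the number of greedy steps is bounded by the query length", {
  # queries sampled from a seed haplotype's graph are always feasible
  # against the seed, and the block count never exceeds |Q| - 1
  for (r in 1:10) {
    p <- sim_params(n_markers = 6, dup_ratio = 0.5, inv_ratio = 0.5,
                    n_haplotypes = 5, rng_seed = 100 + r)
    H <- simulate_haplotypes(p)
    seed_set <- attr(H, "seed_set")
    bi <- block_index(seed_set)
    for (w in H$walks) {
      seg <- count_recombinations(bi, w)
      expect_true(seg$feasible)
      expect_lte(nrow(seg$blocks), length(w) - 1L)
    }
  }
})

test_that("founder recombination totals behave and reduce to zero for F = H", {
  E2 <- example_haplotypes()
  expect_equal(founder_recombination_total(E2, E2), 0)
  F2 <- founder_set(E2, rng_seed = 1)
  tot <- founder_recombination_total(E2, F2)
  expect_gte(tot, 0)
  blocks <- sum(vapply(F2$walks, function(w)
    nrow(count_recombinations(E2, w)$blocks), integer(1)))
  expect_equal(tot, blocks - length(F2$walks))
})

test_that("randomized trials are monotone and seeded", {
  E2 <- example_haplotypes()
  r1 <- random_trials(E2, n_trials = 1, rng_seed = 5)
  expect_equal(r1$best, r1$scores[1])
  r4 <- random_trials(E2, n_trials = 4, rng_seed = 5)
  r8 <- random_trials(E2, n_trials = 8, rng_seed = 5)
  expect_identical(r4$scores, r8$scores[1:4])   # same seed stream
  expect_lte(r8$best, r4$best)                  # monotone in trials
  expect_lte(min(r8$scores), r1$best)
  # the best founder set is feasible and scores its reported best
  expect_equal(founder_recombination_total(E2, r8$founders), r8$best)
})

test_that("co-optimal flow resampling keeps the objective and varies the flow", {
  E2 <- example_haplotypes()
  G <- build_variation_graph(E2)
  fl <- solve_min_flow(G)
  fl2 <- founderset:::resample_cooptimal_flow(G, fl, rng_seed = 2,
                                              solver_cfg = NULL)
  expect_equal(fl2$objective, fl$objective)
  expect_equal(fl2$n_founders, fl$n_founders)
  rt <- random_trials(E2, n_trials = 3, rng_seed = 2, resample_flow = TRUE)
  expect_true(is.finite(rt$best))
})
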