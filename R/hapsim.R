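# Haplotype simulator: a random seed haplotype with duplications and
# inversions, then haplotypes sampled as random source-to-sink walks in
# the seed's variation graph.

#' Simulation parameters
#'
#' @param n_markers number of distinct (non-terminal) markers; the size of
#'   the variation graph.
#' @param dup_ratio fraction in \[0, 1\]: `ceiling(dup_ratio * n_markers)`
#'   duplication events are applied to the seed, each copying a random
#'   segment of 1-3 markers to a random interior position.
#' @param inv_ratio fraction in \[0, 1\]: probability that a duplicated
#'   copy is inserted in inverted orientation.
#' @param n_haplotypes number of haplotypes sampled from the seed's
#'   variation graph.
#' @param rng_seed integer seed; the whole simulation is deterministic
#'   given the parameter set.
#' @param max_walk_factor sampled walks longer than
#'   `max_walk_factor * length(seed)` are discarded and retried.
#' @param max_retries retry budget per haplotype before giving up.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_markers = 100L, dup_ratio = 0.1, inv_ratio = 0.1,
                       n_haplotypes = 10L, rng_seed = 1L,
                       max_walk_factor = 4, max_retries = 1000L) {
  stopifnot(n_markers >= 1L, n_haplotypes >= 1L,
            dup_ratio >= 0, dup_ratio <= 1, inv_ratio >= 0, inv_ratio <= 1,
            max_walk_factor >= 1)
  structure(list(n_markers = as.integer(n_markers), dup_ratio = dup_ratio,
                 inv_ratio = inv_ratio,
                 n_haplotypes = as.integer(n_haplotypes),
                 rng_seed = as.integer(rng_seed),
                 max_walk_factor = max_walk_factor,
                 max_retries = as.integer(max_retries)),
            class = "sim_params")
}

with_sim_seed <- function(seed, code) {
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, code)
  } else {
    set.seed(seed); code
  }
}

#' Generate a seed haplotype with duplications and inversions
#'
#' Starts from the identity walk `s, 1, .., n, S` and applies
#' `ceiling(dup_ratio * n)` duplication events: each copies a random
#' segment of 1-3 consecutive markers to a random interior position, and
#' each copy is independently inverted (reverse-complemented) with
#' probability `inv_ratio`.
#'
#' @param p a [sim_params()].
#' @return a `hap_set` with the single seed haplotype over markers
#'   `1..n_markers` plus terminals.
#' @export
generate_seed <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  n <- p$n_markers
  markers <- c("s", "S", as.character(seq_len(n)))
  src <- 1L; snk <- 2L
  body <- seq_len(n) + 2L          # identity walk in marker-table indices
  n_dup <- ceiling(p$dup_ratio * n)
  body <- with_sim_seed(p$rng_seed, {
    for (k in seq_len(n_dup)) {
      seg_len <- sample(1:3, 1L)
      start <- sample(length(body) - seg_len + 1L, 1L)
      seg <- body[start:(start + seg_len - 1L)]
      if (stats::runif(1) < p$inv_ratio) seg <- reverse_complement(seg)
      at <- sample(0:length(body), 1L)      # insert after position `at`
      body <- append(body, seg, after = at)
    }
    body
  })
  hap_set(list(seed = c(src, body, snk)), markers = markers,
          source = "s", sink = "S")
}

#' Sample haplotypes as random walks of the seed's variation graph
#'
#' Performs uniform random walks from the source tail of the seed's
#' variation graph, choosing uniformly among adjacency continuations, and
#' retains walks that reach the sink within the length bound. Every
#' sampled haplotype lies in the span of the seed (it uses only seed
#' adjacencies).
#'
#' @param seed_set a single-haplotype `hap_set` (from [generate_seed()]).
#' @param p a [sim_params()].
#' @return a `hap_set` of `n_haplotypes` walks named `sim1..simK`.
#' @export
sample_haplotypes <- function(seed_set, p) {
  stopifnot(inherits(seed_set, "hap_set"), length(seed_set$walks) == 1L)
  seed <- seed_set$walks[[1L]]
  tab <- pair_count_table(seed_set)
  succ <- pair_successors(names(tab))
  max_len <- ceiling(p$max_walk_factor * length(seed))
  draw_walk <- function() {
    for (r in seq_len(p$max_retries)) {
      w <- seed_set$source
      repeat {
        cand <- succ[[as.character(w[length(w)])]]
        cand <- cand[abs(cand) != seed_set$source & cand != -seed_set$sink]
        if (length(cand) == 0L) break        # dead end: retry
        b <- if (length(cand) == 1L) cand else sample(cand, 1L)
        w <- c(w, b)
        if (b == seed_set$sink) return(w)
        if (length(w) > max_len) break
      }
    }
    stop("walk sampling starved: no source-to-sink walk within bounds ",
         "after ", p$max_retries, " retries")
  }
  walks <- with_sim_seed(p$rng_seed + 1L, {
    lapply(seq_len(p$n_haplotypes), function(i) draw_walk())
  })
  names(walks) <- paste0("sim", seq_along(walks))
  hap_set(walks, markers = seed_set$markers, source = "s", sink = "S")
}

#' Simulate a haplotype set
#'
#' Composition of [generate_seed()] and [sample_haplotypes()]. The
#' simulator reports the seed and parameters as provenance but — like the
#' benchmarking design it emulates — no "true" founder set: the seed is a
#' generator of the span the haplotypes are drawn from, not necessarily a
#' minimum one.
#'
#' @param p a [sim_params()].
#' @return a `hap_set` with attributes `seed_set` (the seed `hap_set`)
#'   and `params`.
#' @examples
#' H <- simulate_haplotypes(sim_params(n_markers = 10, n_haplotypes = 4))
#' length(H$walks)
#' @export
simulate_haplotypes <- function(p = sim_params()) {
  seed_set <- generate_seed(p)
  H <- sample_haplotypes(seed_set, p)
  structure(H, seed_set = seed_set, params = p)
}
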