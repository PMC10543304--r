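# Shared helpers: tiny instances, oracles, and convenience accessors.

walk_of <- function(H, s) founderset:::as_walk(s, H)

# render a set of walks as a sorted character vector for set comparison
walk_strings <- function(ws, H) {
  unname(sort(vapply(ws, render_walk, "", markers = H)))
}

canonical_pairs <- function(H) sort(names(founderset:::pair_count_table(H)))

# marker-name-based canonical pair strings, comparable across hap_sets
# whose marker tables are ordered differently
canonical_pairs_named <- function(H) {
  keys <- names(founderset:::pair_count_table(H))
  sort(vapply(keys, function(k) {
    p <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    fwd <- paste0(render_walk(p[1], H$markers), render_walk(p[2], H$markers))
    rc <- paste0(render_walk(-p[2], H$markers), render_walk(-p[1], H$markers))
    min(fwd, rc)
  }, "", USE.NAMES = FALSE))
}

# independent minimality oracle for the founder-set problem on tiny
# instances: exhaustive search over subsets of the enumerated span for the
# minimum total length with the same canonical pair set as H
min_founder_total_length_oracle <- function(H, max_len, max_size = 3L) {
  span <- enumerate_span(H, max_len)
  target <- canonical_pairs(H)
  best <- Inf
  n <- length(span)
  idx_sets <- unlist(lapply(seq_len(min(max_size, n)), function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (is in idx_sets) {
    F <- span[is]
    if (setequal(names(founderset:::pair_count_table(F)), target))
      best <- min(best, sum(lengths(F)))
  }
  best
}

# random terminal-bracketed walk sets for fuzzing (not necessarily
# realistic; arbitrary adjacency structure)
random_tiny_hapset <- function(n_markers = 3L, n_haps = 2L, len = 6L) {
  markers <- c("s", "S", as.character(seq_len(n_markers)))
  walks <- lapply(seq_len(n_haps), function(i) {
    body <- sample(c(-(3:(2 + n_markers)), 3:(2 + n_markers)),
                   len, replace = TRUE)
    c(1L, body, 2L)
  })
  names(walks) <- paste0("H", seq_len(n_haps))
  hap_set(walks, markers = markers)
}

fast_cfg <- function() solver_config()
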