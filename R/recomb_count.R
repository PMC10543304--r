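# Problem 2 (Recombination Count): greedy longest-block segmentation of a
# query against a set of terminal sequences, with an exact DP oracle and a
# randomized-trials counter for founder sets.

#' Build a block index over a sequence set
#'
#' Concatenates the sequences and their reverse complements with unique
#' separators into one array supporting longest-prefix match queries. A
#' query segment is a block iff it occurs inside a single sequence of the
#' set or its reverse complements (matches never span separators).
#'
#' @param T a `hap_set` or list of signed integer walks.
#' @return a `block_index`.
#' @export
block_index <- function(T) {
  walks <- if (inherits(T, "hap_set")) T$walks else T
  if (is.null(names(walks))) names(walks) <- paste0("seq", seq_along(walks))
  seqs <- c(walks, stats::setNames(lapply(walks, reverse_complement),
                                   paste0(names(walks), "'")))
  orient <- rep(c(1L, -1L), each = length(walks))
  lens <- lengths(seqs)
  # separator NA between sequences; offsets locate each sequence
  concat <- unlist(lapply(seqs, function(w) c(w, NA_integer_)), use.names = FALSE)
  starts <- cumsum(c(1L, lens[-length(lens)] + 1L))
  structure(list(concat = concat, starts = starts, lens = lens,
                 ids = names(seqs), orient = orient,
                 n_fwd = length(walks)),
            class = "block_index")
}

# map a concatenation position to (sequence id, 1-based offset, orientation)
index_witness <- function(bi, pos) {
  k <- findInterval(pos, bi$starts)
  list(id = unname(bi$ids[k]), offset = unname(pos - bi$starts[k] + 1L),
       orientation = unname(bi$orient[k]))
}

#' Longest block prefix of a query
#'
#' Returns the largest `k` such that `Q[..k]` occurs as a segment of some
#' sequence of the indexed set or its reverse complements, with one
#' witness occurrence; 0 if even `Q[1]` is absent.
#'
#' @param T a `hap_set`, list of walks, or a prebuilt [block_index()].
#' @param Q query walk (signed integer vector).
#' @return list with `length` and `witness` (`id`, `offset`,
#'   `orientation`; `NULL` when length is 0).
#' @export
longest_block_prefix <- function(T, Q) {
  bi <- if (inherits(T, "block_index")) T else block_index(T)
  Q <- as.integer(Q)
  if (length(Q) == 0L) return(list(length = 0L, witness = NULL))
  hits <- which(bi$concat == Q[1])
  if (length(hits) == 0L) return(list(length = 0L, witness = NULL))
  L <- 1L
  wit <- hits[1]
  k <- 2L
  while (k <= length(Q) && length(hits) > 0L) {
    nxt <- bi$concat[hits + k - 1L]          # NA at separators/end kills the hit
    hits <- hits[!is.na(nxt) & nxt == Q[k]]
    if (length(hits) > 0L) {
      L <- k
      wit <- hits[1]
      k <- k + 1L
    }
  }
  list(length = L, witness = index_witness(bi, wit))
}

#' Minimum recombinations to generate a query (greedy segmentation)
#'
#' Implements the greedy recursion: take the longest prefix of the query
#' that is a block of the sequence set, then recurse on the suffix
#' starting at the prefix's last position (consecutive blocks overlap by
#' exactly one marker). The greedy segmentation is provably minimal. A
#' query whose longest block prefix has length <= 1 at any step cannot be
#' generated and yields `Inf` recombinations.
#'
#' @param T a `hap_set`, list of walks, or [block_index()].
#' @param Q query walk: signed integer vector, or token string resolved
#'   against `T`'s marker table when `T` is a `hap_set`.
#' @return an object of class `segmentation`: list with `recombinations`
#'   (integer, or `Inf` if infeasible), `feasible`, and `blocks` (data
#'   frame `start`, `end`, `witness_id`, `witness_offset`, `orientation`).
#' @examples
#' H <- example_single_haplotype()
#' B <- ">s<1>2>3>4<3>S"
#' count_recombinations(H, B)$recombinations  # 2
#' @export
count_recombinations <- function(T, Q) {
  if (is.character(Q)) {
    stopifnot(inherits(T, "hap_set"))
    Q <- as_walk(Q, T)
    if (is.null(Q))
      return(structure(list(recombinations = Inf, feasible = FALSE,
                            blocks = NULL), class = "segmentation"))
  }
  bi <- if (inherits(T, "block_index")) T else block_index(T)
  Q <- as.integer(Q)
  pos <- 1L
  blocks <- data.frame(start = integer(0), end = integer(0),
                       witness_id = character(0),
                       witness_offset = integer(0), orientation = integer(0))
  feasible <- TRUE
  repeat {
    rest <- Q[pos:length(Q)]
    r <- longest_block_prefix(bi, rest)
    if (r$length <= 1L && r$length < length(rest)) { feasible <- FALSE; break }
    blocks[nrow(blocks) + 1L, ] <-
      list(pos, pos + r$length - 1L, r$witness$id, r$witness$offset,
           r$witness$orientation)
    if (r$length == length(rest)) break
    pos <- pos + r$length - 1L              # overlap by one marker
  }
  structure(list(
    recombinations = if (feasible) nrow(blocks) - 1L else Inf,
    feasible = feasible,
    blocks = if (feasible) blocks else NULL
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  if (!x$feasible) cat("segmentation: infeasible (Inf recombinations)\n")
  else cat(sprintf("segmentation: %d block(s), %d recombination(s)\n",
                   nrow(x$blocks), x$recombinations))
  invisible(x)
}

#' Exact minimum-segmentation oracle (dynamic program)
#'
#' Independent quadratic-time dynamic program over cut positions that
#' minimizes the number of overlapping blocks covering the query. Used to
#' validate the greedy segmentation; intended for small queries only.
#'
#' @param T a `hap_set`, list of walks, or [block_index()].
#' @param Q query walk.
#' @return minimum number of recombinations (`Inf` if infeasible).
#' @export
min_segmentation_oracle <- function(T, Q) {
  bi <- if (inherits(T, "block_index")) T else block_index(T)
  Q <- as.integer(Q)
  n <- length(Q)
  if (n == 0L) return(Inf)
  # is_block[i, j]: Q[i..j] occurs in the indexed set
  is_block <- function(i, j) {
    longest_block_prefix(bi, Q[i:j])$length == j - i + 1L
  }
  f <- rep(Inf, n)                          # f[j]: min blocks covering Q[..j]
  for (j in seq_len(n)) {
    if (is_block(1L, j)) { f[j] <- 1; next }
    for (k in seq_len(j - 1L)[-1L]) {       # cut at k in 2..j-1, overlap by one
      if (is.finite(f[k]) && is_block(k, j)) f[j] <- min(f[j], f[k] + 1)
    }
  }
  if (is.finite(f[n])) as.integer(f[n]) - 1L else Inf
}

#' Total recombinations to build a founder set from haplotypes
#'
#' Sum of [count_recombinations()] over founders, against the haplotype
#' set; `Inf` if any founder is infeasible.
#'
#' @param H a `hap_set` of haplotypes.
#' @param F a `hap_set` of founders (sharing `H`'s marker table).
#' @return total recombination count.
#' @export
founder_recombination_total <- function(H, F) {
  bi <- block_index(H)
  sum(vapply(F$walks, function(w) {
    count_recombinations(bi, w)$recombinations
  }, numeric(1)))
}

#' Randomized founder-assignment trials
#'
#' Fixes one optimal flow and repeatedly re-runs the randomized flow
#' decomposition and cycle integration with fresh seeds, scoring each
#' candidate founder set by its total recombination count against `H` and
#' keeping the best. With `resample_flow = TRUE`, each trial additionally
#' draws a different co-optimal flow (the total-flow optimum is fixed as a
#' constraint and a random objective selects among co-optimal solutions).
#' The best score is monotonically non-increasing in the number of trials
#' for a fixed seed stream.
#'
#' @param H a `hap_set`.
#' @param n_trials number of trials (>= 1).
#' @param rng_seed integer seed for the trial seed stream.
#' @param solver_cfg a [solver_config()].
#' @param resample_flow also randomize over co-optimal flows.
#' @return list with `best` (minimum total recombinations), `founders`
#'   (best founder `hap_set`), and `scores` (per-trial totals).
#' @export
random_trials <- function(H, n_trials = 10L, rng_seed = 1L,
                          solver_cfg = NULL, resample_flow = FALSE) {
  stopifnot(n_trials >= 1L)
  G <- build_variation_graph(H)
  flow <- solve_min_flow(G, solver_cfg)
  bi <- block_index(H)
  scores <- numeric(n_trials)
  best <- Inf
  best_F <- NULL
  for (i in seq_len(n_trials)) {
    seed_i <- (rng_seed + 7919L * i) %% .Machine$integer.max
    fl <- if (resample_flow && i > 1L)
      resample_cooptimal_flow(G, flow, seed_i, solver_cfg) else flow
    Fi <- founders_from_flow(fl, G, seed_i)
    scores[i] <- sum(vapply(Fi$walks, function(w)
      count_recombinations(bi, w)$recombinations, numeric(1)))
    if (scores[i] < best) { best <- scores[i]; best_F <- Fi }
  }
  list(best = best, founders = best_F, scores = scores)
}

# draw a co-optimal flow: constrain total adjacency flow to the known
# optimum and optimize a random objective over arc flows
resample_cooptimal_flow <- function(G, flow, rng_seed, solver_cfg) {
  arcs <- flow_arcs(G)
  M <- length(G$markers)
  n_arc <- nrow(arcs)
  v_arc <- seq_len(n_arc)
  v_fwd <- n_arc + seq_len(M)
  v_rev <- n_arc + M + seq_len(M)
  nvar <- n_arc + 2L * M
  tb <- triplet_builder()
  for (e in seq_len(nrow(G$adjacency))) {
    idx <- v_arc[arcs$edge == e]
    tb$add_row(idx, rep(1, length(idx)), 1, Inf)
  }
  for (m in G$present)
    tb$add_row(c(v_fwd[m], v_rev[m]), c(1, 1), 1, Inf)
  for (m in seq_len(M)) {
    for (side in c("t", "h")) {
      e <- if (side == "t") ext_tail(m) else ext_head(m)
      if (e == ext_tail(G$source) || e == ext_head(G$sink)) next
      into <- v_arc[arcs$to == e]
      outof <- v_arc[arcs$from == e]
      v_in <- if (side == "t") v_fwd[m] else v_rev[m]
      v_out <- if (side == "t") v_rev[m] else v_fwd[m]
      tb$add_row(c(into, v_in), c(rep(1, length(into)), -1), 0, 0)
      tb$add_row(c(outof, v_out), c(rep(1, length(outof)), -1), 0, 0)
    }
  }
  tb$add_row(v_arc, rep(1, n_arc), flow$objective, flow$objective)
  con <- tb$collect()
  rnd <- if (requireNamespace("withr", quietly = TRUE))
    withr::with_seed(rng_seed, stats::runif(n_arc))
  else { set.seed(rng_seed); stats::runif(n_arc) }
  obj <- c(rnd, rep(0, 2L * M))
  ub <- rep(Inf, nvar)
  ub[c(v_rev[G$source], v_rev[G$sink])] <- 0
  res <- milp_solve(obj, con$triplets, con$lhs, con$rhs,
                    lb = rep(0, nvar), ub = ub, cfg = solver_cfg)
  x <- res$x
  arcs$flow <- as.integer(x[v_arc])
  structure(list(
    arcs = arcs,
    fwd = stats::setNames(as.integer(x[v_fwd]), G$markers),
    rev = stats::setNames(as.integer(x[v_rev]), G$markers),
    objective = sum(arcs$flow),
    n_founders = as.integer(x[v_fwd[G$source]]),
    status = res$status
  ), class = "flow_solution")
}
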