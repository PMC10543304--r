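# Problem 3 (Parsimonious Founder Set): with pair multiplicities fixed from
# a Problem 1 solution, build the copy-expanded flow graph and solve a
# matching ILP that minimizes the number of recombinations needed to build
# the founders from the haplotypes.

#' Estimate the pair-multiplicity oracle from a founder set
#'
#' Counts canonical consecutive-pair multiplicities (mu-hat) of a founder
#' set and derives per-marker multiplicities (gamma-hat: the number of
#' occurrences of each marker in either orientation; for the terminals,
#' the number of founders). Fixing these multiplicities is what makes the
#' downstream minimization exact *conditional on the oracle*: the pipeline
#' is heuristic overall because an optimal parsimonious founder set need
#' not have optimal flow.
#'
#' @param F a `hap_set` of founders (any haplotype multiset).
#' @return a `mu_oracle`: list with `mu` (named canonical pair counts),
#'   `gamma` (per-marker occurrence counts), `n_founders`, and the marker
#'   table with terminals.
#' @export
estimate_mu_hat <- function(F) {
  stopifnot(inherits(F, "hap_set"))
  mu <- pair_count_table(F)
  occ <- abs(unlist(F$walks, use.names = FALSE))
  gamma <- tabulate(occ, nbins = length(F$markers))
  names(gamma) <- F$markers
  structure(list(mu = mu, gamma = gamma, n_founders = length(F$walks),
                 markers = F$markers, source = F$source, sink = F$sink),
            class = "mu_oracle")
}

# the two directed realizations of a canonical pair key; palindromic pairs
# (b == -a) have a single realization
pair_realizations <- function(key) {
  p <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
  a <- p[1]; b <- p[2]
  if (b == -a) list(c(a, b)) else list(c(a, b), c(-b, -a))
}

#' Build the copy-expanded flow graph
#'
#' Directed edge-colored multigraph over node triples (side, extremity,
#' copy): each marker extremity contributes gamma-hat(m) *in* and
#' gamma-hat(m) *out* copies. Each forward (and, for non-terminals,
#' reverse) orientation of a marker contributes a complete bipartite set
#' of gamma-hat(m)^2 directed marker edges from entry-side in copies to
#' exit-side out copies. Every oriented pair realization with positive
#' multiplicity contributes exactly mu-hat directed adjacency edges from
#' out copies of its exit extremity to in copies of its entry extremity;
#' each out copy carries at most one outgoing and each in copy at most one
#' incoming adjacency edge, allocated deterministically (sorted pairs,
#' sequential slots). No adjacency edge leaves an out copy of the sink
#' head and none enters an in copy of the source tail.
#'
#' @param H a `hap_set` (supplies the universe; occurrence assignment is
#'   done at solve time).
#' @param oracle a `mu_oracle`.
#' @return a `flow_graph`: list of node and edge tables plus the total
#'   flow constant `T = sum(gamma)`.
#' @export
build_flow_graph <- function(H, oracle) {
  stopifnot(inherits(H, "hap_set"), inherits(oracle, "mu_oracle"))
  if (!identical(H$markers, oracle$markers))
    stop("haplotype set and oracle use different marker tables")
  M <- length(H$markers)
  gamma <- oracle$gamma
  occurring <- sort(unique(abs(unlist(H$walks, use.names = FALSE))))
  if (any(gamma[occurring] < 1L))
    stop("gamma-hat must be >= 1 for every marker occurring in the haplotypes")

  # nodes: one row per (io, extremity, copy)
  nodes <- do.call(rbind, lapply(seq_len(M), function(m) {
    g <- gamma[m]
    expand.grid(io = c("i", "o"), ext = c(ext_tail(m), ext_head(m)),
                copy = seq_len(g), stringsAsFactors = FALSE)
  }))
  nodes$id <- seq_len(nrow(nodes))
  node_lookup <- new.env(parent = emptyenv())
  assign_key <- function(io, ext, copy) paste(io, ext, copy, sep = ":")
  for (r in seq_len(nrow(nodes)))
    assign(assign_key(nodes$io[r], nodes$ext[r], nodes$copy[r]),
           nodes$id[r], envir = node_lookup)
  node_id <- function(io, ext, copy)
    get(assign_key(io, ext, copy), envir = node_lookup)

  # marker edges: per orientation, complete bipartite over copies;
  # terminals are traversed forward only
  me <- list()
  for (m in seq_len(M)) {
    g <- gamma[m]
    orients <- if (m %in% c(H$source, H$sink)) 1L else c(1L, -1L)
    for (o in orients) {
      a <- m * o
      for (xi in seq_len(g)) for (yi in seq_len(g)) {
        me[[length(me) + 1L]] <- data.frame(
          from = node_id("i", entry_ext(a), xi),
          to = node_id("o", exit_ext(a), yi),
          marker = m, traversal = a)
      }
    }
  }
  marker_edges <- do.call(rbind, me)

  # adjacency edges: deterministic slot allocation per extremity
  realizations <- list()
  for (key in sort(names(oracle$mu))) {
    for (re in pair_realizations(key)) {
      realizations[[length(realizations) + 1L]] <-
        data.frame(a = re[1], b = re[2], key = key,
                   count = oracle$mu[[key]])
    }
  }
  realizations <- do.call(rbind, realizations)
  realizations <- realizations[order(realizations$a, realizations$b), ,
                               drop = FALSE]
  out_used <- integer(2L * M)   # slots consumed per extremity, out side
  in_used <- integer(2L * M)
  ae <- list()
  for (r in seq_len(nrow(realizations))) {
    a <- realizations$a[r]; b <- realizations$b[r]
    e_out <- exit_ext(a); e_in <- entry_ext(b)
    for (k in seq_len(realizations$count[r])) {
      out_used[e_out] <- out_used[e_out] + 1L
      in_used[e_in] <- in_used[e_in] + 1L
      if (out_used[e_out] > gamma[ext_marker(e_out)] ||
          in_used[e_in] > gamma[ext_marker(e_in)])
        stop("mu-hat row sums exceed gamma-hat at extremity ",
             ext_label(e_out, H$markers), "/", ext_label(e_in, H$markers),
             ": oracle inconsistent")
      ae[[length(ae) + 1L]] <- data.frame(
        from = node_id("o", e_out, out_used[e_out]),
        to = node_id("i", e_in, in_used[e_in]),
        a = a, b = b, key = realizations$key[r])
    }
  }
  adjacency_edges <- do.call(rbind, ae)
  # the sink head out copies and source tail in copies must carry none
  stopifnot(out_used[ext_head(H$sink)] == 0L,
            in_used[ext_tail(H$source)] == 0L)

  structure(list(nodes = nodes, marker_edges = marker_edges,
                 adjacency_edges = adjacency_edges,
                 gamma = gamma, mu = oracle$mu,
                 total_flow = sum(gamma),
                 markers = H$markers, source = H$source, sink = H$sink),
            class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf(
    "flow_graph: %d nodes, %d marker edges, %d adjacency edges, T = %d\n",
    nrow(x$nodes), nrow(x$marker_edges), nrow(x$adjacency_edges),
    x$total_flow))
  invisible(x)
}

# occurrence table of H and its reverse complements: one row per position,
# keyed by the oriented marker at that position
occurrence_table <- function(H) {
  walks <- c(H$walks, stats::setNames(lapply(H$walks, reverse_complement),
                                      paste0(names(H$walks), "'")))
  do.call(rbind, lapply(names(walks), function(nm) {
    w <- walks[[nm]]
    data.frame(seq = nm, j = seq_along(w), a = w)
  }))
}

#' Minimize recombinations over founder sets with fixed multiplicities
#'
#' Solves the matching integer linear program on the copy-expanded flow
#' graph: binary saturation variables for edges and nodes select a
#' perfect matching of marker edges on exactly half the nodes per marker,
#' adjacency saturation follows node saturation, per-marker and per-pair
#' saturation totals are pinned to gamma-hat and mu-hat, an integer rank
#' flow (increasing by one across saturated marker edges, constant across
#' saturated adjacency edges) rules out cycles, each saturated node is
#' assigned one haplotype occurrence, adjacency edges propagate
#' occurrences to consecutive positions, and a marker edge scores one
#' objective unit when both endpoints carry the same occurrence. The
#' maximized score is the number of marker traversals that continue a
#' haplotype block; the reported recombination count is
#' `sum(gamma-hat) - score`.
#'
#' @param fg a `flow_graph`.
#' @param H the `hap_set` of haplotypes.
#' @param solver_cfg a [solver_config()]; set its `time_limit` to cap the
#'   solve (a best-effort solution is then returned with
#'   `status = "time_limit"`).
#' @return a `matching_solution`: list with `recombinations`, `score`,
#'   `status`, `founders` (annotated founder `hap_set`), `annotation`
#'   (per-position data frame with source haplotype, position, orientation
#'   and recombination stars), and `gap` (MIP gap if not proven optimal).
#' @export
solve_min_recombinations <- function(fg, H, solver_cfg = NULL) {
  stopifnot(inherits(fg, "flow_graph"), inherits(H, "hap_set"))
  nodes <- fg$nodes
  me <- fg$marker_edges
  ae <- fg$adjacency_edges
  Tt <- fg$total_flow
  occ <- occurrence_table(H)
  occ_by_a <- split(seq_len(nrow(occ)), occ$a)

  n_me <- nrow(me); n_ae <- nrow(ae); n_nd <- nrow(nodes)
  v_xm <- seq_len(n_me)
  v_xa <- n_me + seq_len(n_ae)
  v_y <- n_me + n_ae + seq_len(n_nd)
  v_f <- n_me + n_ae + n_nd + seq_len(n_nd)
  base <- n_me + n_ae + 2L * n_nd

  # node traversal: the oriented marker a node represents.
  # in node at entry(a) and out node at exit(a) both carry traversal a.
  node_trav <- integer(n_nd)
  for (r in seq_len(n_nd)) {
    m <- ext_marker(nodes$ext[r])
    tail <- !ext_is_head(nodes$ext[r])
    node_trav[r] <- if (nodes$io[r] == "i") {
      if (tail) m else -m
    } else {
      if (tail) -m else m
    }
  }

  # c variables: per node, one per matching occurrence
  c_node <- integer(0); c_occ <- integer(0)
  for (v in seq_len(n_nd)) {
    os <- occ_by_a[[as.character(node_trav[v])]]
    if (length(os)) {
      c_node <- c(c_node, rep.int(v, length(os)))
      c_occ <- c(c_occ, os)
    }
  }
  n_c <- length(c_node)
  v_c <- base + seq_len(n_c)
  c_index <- split(seq_len(n_c), c_node)            # node -> c var rows
  c_of <- function(v, o) {                          # (node, occ row) -> var
    idx <- c_index[[as.character(v)]]
    idx[match(o, c_occ[idx])]
  }

  # t variables: per marker edge, one per occurrence matching its traversal
  t_edge <- integer(0); t_occ <- integer(0)
  for (ei in seq_len(n_me)) {
    os <- occ_by_a[[as.character(me$traversal[ei])]]
    if (length(os)) {
      t_edge <- c(t_edge, rep.int(ei, length(os)))
      t_occ <- c(t_occ, os)
    }
  }
  n_t <- length(t_edge)
  v_t <- base + n_c + seq_len(n_t)
  nvar <- base + n_c + n_t

  tb <- triplet_builder()
  # C.02: per node, saturated marker edges incident = y (perfect matching)
  me_by_node <- split(rep(seq_len(n_me), 2L), c(me$from, me$to))
  for (v in seq_len(n_nd)) {
    inc <- me_by_node[[as.character(v)]]
    if (is.null(inc)) next
    tb$add_row(c(v_xm[inc], v_y[v]), c(rep(1, length(inc)), -1), 0, 0)
  }
  # C.03 + C.08: adjacency saturation equals saturation of both endpoints;
  # paths can only start at source-tail in copies / end at sink-head out
  # copies because those carry no adjacency edges by construction
  for (ei in seq_len(n_ae)) {
    tb$add_row(c(v_xa[ei], v_y[ae$from[ei]]), c(1, -1), 0, 0)
    tb$add_row(c(v_xa[ei], v_y[ae$to[ei]]), c(1, -1), 0, 0)
  }
  # C.04: per marker, saturated marker edges (both orientations) = gamma
  for (m in seq_len(length(fg$markers))) {
    idx <- which(me$marker == m)
    tb$add_row(v_xm[idx], rep(1, length(idx)), fg$gamma[m], fg$gamma[m])
  }
  # C.05: per canonical pair, saturated adjacency edges over both
  # realizations = mu
  for (key in names(fg$mu)) {
    idx <- which(ae$key == key)
    tb$add_row(v_xa[idx], rep(1, length(idx)), fg$mu[[key]], fg$mu[[key]])
  }
  # C.06: rank flow increases by exactly 1 across saturated marker edges
  for (ei in seq_len(n_me)) {
    u <- me$from[ei]; v <- me$to[ei]
    tb$add_row(c(v_f[v], v_f[u], v_xm[ei]), c(1, -1, Tt), -Inf, Tt + 1)
    tb$add_row(c(v_f[v], v_f[u], v_xm[ei]), c(1, -1, -Tt), 1 - Tt, Inf)
  }
  # C.07: rank flow constant across saturated adjacency edges
  for (ei in seq_len(n_ae)) {
    u <- ae$from[ei]; v <- ae$to[ei]
    tb$add_row(c(v_f[v], v_f[u], v_xa[ei]), c(1, -1, Tt), -Inf, Tt)
    tb$add_row(c(v_f[v], v_f[u], v_xa[ei]), c(1, -1, -Tt), -Tt, Inf)
  }
  # C.09: each saturated node carries exactly one occurrence
  for (v in seq_len(n_nd)) {
    idx <- c_index[[as.character(v)]]
    tb$add_row(c(if (length(idx)) v_c[idx], v_y[v]),
               c(rep(1, length(idx)), -1), 0, 0)
  }
  # C.10: saturated adjacency edges propagate occurrences to the
  # consecutive position of the same (possibly reverse-complemented)
  # haplotype
  occ_key <- paste(occ$seq, occ$j, sep = "#")
  occ_next <- match(paste(occ$seq, occ$j + 1L, sep = "#"), occ_key)
  for (ei in seq_len(n_ae)) {
    u <- ae$from[ei]; v <- ae$to[ei]
    for (o in c_occ[c_index[[as.character(u)]]]) {
      nx <- occ_next[o]
      if (!is.na(nx) && occ$a[nx] == ae$b[ei]) {
        tb$add_row(c(v_c[c_of(u, o)], v_c[c_of(v, nx)], v_xa[ei]),
                   c(1, -1, 1), -Inf, 1)
      } else {
        tb$add_row(c(v_c[c_of(u, o)], v_xa[ei]), c(1, 1), -Inf, 1)
      }
    }
  }
  # C.11: a marker edge scores only if saturated and both endpoints carry
  # the same occurrence
  for (k in seq_len(n_t)) {
    ei <- t_edge[k]; o <- t_occ[k]
    tb$add_row(c(v_t[k], v_xm[ei]), c(1, -1), -Inf, 0)
    tb$add_row(c(v_t[k], v_c[c_of(me$from[ei], o)]), c(1, -1), -Inf, 0)
    tb$add_row(c(v_t[k], v_c[c_of(me$to[ei], o)]), c(1, -1), -Inf, 0)
  }

  con <- tb$collect()
  obj <- numeric(nvar)
  obj[v_t] <- 1
  lb <- numeric(nvar)
  ub <- c(rep(1, n_me + n_ae + n_nd), rep(Tt, n_nd), rep(1, n_c + n_t))
  # nodes without marker edges (reverse copies of terminals) stay
  # unsaturated
  no_me <- setdiff(seq_len(n_nd), unique(c(me$from, me$to)))
  ub[v_y[no_me]] <- 0
  res <- milp_solve(obj, con$triplets, con$lhs, con$rhs, lb, ub,
                    maximize = TRUE, cfg = solver_cfg)
  if (res$status == "infeasible")
    return(structure(list(recombinations = Inf, score = NA_integer_,
                          status = "infeasible", founders = NULL,
                          annotation = NULL, gap = NA_real_),
                     class = "matching_solution"))
  x <- res$x
  score <- as.integer(round(sum(x[v_t])))
  sol <- list(x_marker = x[v_xm], x_adj = x[v_xa], y = x[v_y],
              f = x[v_f], c_val = x[v_c],
              c_node = c_node, c_occ = c_occ, occ = occ)
  founders <- trace_saturated_founders(fg, sol, H)
  structure(list(
    recombinations = Tt - score,
    score = score,
    status = res$status,
    founders = founders$hap_set,
    annotation = founders$annotation,
    gap = res$gap
  ), class = "matching_solution")
}

#' @export
print.matching_solution <- function(x, ...) {
  cat(sprintf("matching_solution: %s, %s recombination(s)\n",
              x$status, format(x$recombinations)))
  invisible(x)
}

# walk the saturated subgraph from each saturated source-tail in copy and
# spell out founders with their haplotype-occurrence annotation
trace_saturated_founders <- function(fg, sol, H) {
  nodes <- fg$nodes
  me <- fg$marker_edges
  ae <- fg$adjacency_edges
  sat_me <- which(sol$x_marker > 0.5)
  sat_ae <- which(sol$x_adj > 0.5)
  me_from <- function(v) sat_me[match(v, me$from[sat_me])]  # in node -> edge
  ae_from <- function(v) sat_ae[match(v, ae$from[sat_ae])]  # out node -> edge
  occ_of_node <- function(v) {
    idx <- which(sol$c_node == v & sol$c_val > 0.5)
    if (length(idx) != 1L) return(c(NA_character_, NA_integer_))
    o <- sol$c_occ[idx]
    c(sol$occ$seq[o], sol$occ$j[o])
  }
  starts <- nodes$id[nodes$io == "i" & nodes$ext == ext_tail(fg$source) &
                       sol$y[nodes$id] > 0.5]
  walks <- list(); ann <- list()
  for (sidx in seq_along(starts)) {
    v <- starts[sidx]
    walk <- integer(0)
    rows <- list()
    prev_occ <- NULL
    repeat {
      eidx <- me_from(v)
      stopifnot(!is.na(eidx))
      a <- me$traversal[eidx]
      w <- me$to[eidx]
      o_in <- occ_of_node(v); o_out <- occ_of_node(w)
      walk <- c(walk, a)
      rows[[length(rows) + 1L]] <- data.frame(
        position = length(walk),
        marker = paste0(ifelse(a > 0, ">", "<"), fg$markers[abs(a)]),
        source_seq = o_out[1], source_pos = as.integer(o_out[2]),
        entry_seq = o_in[1], entry_pos = as.integer(o_in[2]),
        is_recombination = !identical(o_in, o_out))
      nxt <- ae_from(w)
      if (is.na(nxt)) break                   # sink head out copy
      v <- ae$to[nxt]
    }
    stopifnot(abs(walk[length(walk)]) == fg$sink)
    walks[[paste0("founder", sidx)]] <- walk
    a <- do.call(rbind, rows)
    a$founder <- paste0("founder", sidx)
    ann[[sidx]] <- a
  }
  FH <- hap_set(walks, markers = fg$markers,
                source = fg$markers[fg$source], sink = fg$markers[fg$sink])
  annotation <- do.call(rbind, ann)
  annotation <- annotation[, c("founder", "position", "marker", "source_seq",
                               "source_pos", "is_recombination")]
  list(hap_set = FH, annotation = annotation)
}

#' Annotated founders of a matching solution
#'
#' Returns the founder walks of a [solve_min_recombinations()] solution as
#' a `hap_set` with the per-position block annotation (source haplotype,
#' source position, orientation via the reverse-complement naming
#' convention `name'`, and recombination stars) attached as attribute
#' `annotation`.
#'
#' @param sol a `matching_solution`.
#' @return a `hap_set` with attribute `annotation`.
#' @export
extract_annotated_founders <- function(sol) {
  stopifnot(inherits(sol, "matching_solution"))
  if (is.null(sol$founders)) stop("solution is infeasible; no founders")
  structure(sol$founders, annotation = sol$annotation)
}

#' End-to-end parsimonious founder reconstruction
#'
#' Runs the full pipeline: founder-set flow (Problem 1), multiplicity
#' oracle from its solution, copy-expanded flow graph, and the
#' recombination-minimizing matching ILP (Problem 3). Exact conditional on
#' the oracle multiplicities; heuristic overall.
#'
#' @param H a `hap_set`.
#' @param rng_seed seed for the flow decomposition used to derive the
#'   oracle.
#' @param solver_cfg a [solver_config()].
#' @return the `matching_solution`, with the Problem 1 founder set in
#'   attribute `flow_founders`.
#' @examples
#' \donttest{
#' sol <- minimize_recombinations(example_haplotypes())
#' sol$recombinations  # 2
#' }
#' @export
minimize_recombinations <- function(H, rng_seed = 1L, solver_cfg = NULL) {
  F1 <- founder_set(H, rng_seed, solver_cfg)
  oracle <- estimate_mu_hat(F1)
  fg <- build_flow_graph(H, oracle)
  sol <- solve_min_recombinations(fg, H, solver_cfg)
  attr(sol, "flow_founders") <- F1
  sol
}
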