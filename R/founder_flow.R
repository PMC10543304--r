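# Problem 1 (Founder Set): minimum integer network flow on the variation
# graph, flow decomposition into alternating paths/cycles, and integration
# of cycles into source-to-sink walks.

# directed adjacency arc table of a variation graph: one row per direction
# of every adjacency edge (self-loops get a single row)
flow_arcs <- function(G) {
  rows <- list()
  for (r in seq_len(nrow(G$adjacency))) {
    u <- G$adjacency[r, 1]; v <- G$adjacency[r, 2]
    rows[[length(rows) + 1L]] <- c(u, v)
    if (u != v) rows[[length(rows) + 1L]] <- c(v, u)
  }
  arcs <- do.call(rbind, rows)
  data.frame(from = arcs[, 1], to = arcs[, 2],
             edge = rep(seq_len(nrow(G$adjacency)),
                        ifelse(G$adjacency[, 1] == G$adjacency[, 2], 1L, 2L)))
}

#' Solve the founder-set flow problem on a variation graph
#'
#' Finds an integral flow of minimum total adjacency flow such that every
#' marker is traversed at least once (in forward or reverse direction),
#' every adjacency edge carries at least one unit of flow in some
#' direction, and flow is conserved at every extremity: adjacency flow
#' into an extremity equals the number of marker traversals entering
#' there, and adjacency flow out equals the traversals exiting there. The
#' source tail supplies path starts and the sink head absorbs path ends;
#' terminals are traversed forward only. By the flow decomposition
#' argument, the optimal objective equals the total founder length minus
#' the number of founders of a minimum founder set.
#'
#' @param G a `variation_graph`.
#' @param solver_cfg a [solver_config()].
#' @return an object of class `flow_solution`: list with `arcs` (data
#'   frame `from`, `to`, `edge`, `flow`), `fwd`/`rev` (per-marker
#'   traversal counts), `objective`, `n_founders` (forward traversals of
#'   the source), and `status`.
#' @export
solve_min_flow <- function(G, solver_cfg = NULL) {
  stopifnot(inherits(G, "variation_graph"))
  arcs <- flow_arcs(G)
  M <- length(G$markers)
  n_arc <- nrow(arcs)
  # variable layout: [arc flows | fwd(m) | rev(m)]
  v_arc <- seq_len(n_arc)
  v_fwd <- n_arc + seq_len(M)
  v_rev <- n_arc + M + seq_len(M)
  nvar <- n_arc + 2L * M
  tb <- triplet_builder()

  # per-edge coverage
  for (e in seq_len(nrow(G$adjacency))) {
    idx <- v_arc[arcs$edge == e]
    tb$add_row(idx, rep(1, length(idx)), 1, Inf)
  }
  # per-marker coverage, over the universe of occurring markers
  for (m in G$present)
    tb$add_row(c(v_fwd[m], v_rev[m]), c(1, 1), 1, Inf)

  # conservation at every extremity; the source tail and sink head rows
  # are omitted (path starts/ends balance them by definition)
  for (m in seq_len(M)) {
    for (side in c("t", "h")) {
      e <- if (side == "t") ext_tail(m) else ext_head(m)
      if (e == ext_tail(G$source) || e == ext_head(G$sink)) next
      into <- v_arc[arcs$to == e]
      outof <- v_arc[arcs$from == e]
      v_in <- if (side == "t") v_fwd[m] else v_rev[m]   # traversals entering at e
      v_out <- if (side == "t") v_rev[m] else v_fwd[m]  # traversals exiting at e
      tb$add_row(c(into, v_in), c(rep(1, length(into)), -1), 0, 0)
      tb$add_row(c(outof, v_out), c(rep(1, length(outof)), -1), 0, 0)
    }
  }
  con <- tb$collect()
  obj <- c(rep(1, n_arc), rep(0, 2L * M))
  ub <- rep(Inf, nvar)
  ub[c(v_rev[G$source], v_rev[G$sink])] <- 0   # terminals forward-only
  res <- milp_solve(obj, con$triplets, con$lhs, con$rhs,
                    lb = rep(0, nvar), ub = ub, cfg = solver_cfg)
  if (res$status == "infeasible")
    stop("internal error: flow problem infeasible on a valid variation graph")
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

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: objective %d, %d founder path(s)\n",
              x$objective, x$n_founders))
  invisible(x)
}

# traversal implied by entering marker at extremity e
traversal_at <- function(e) {
  m <- ext_marker(e)
  if (ext_is_head(e)) -m else m
}

#' Decompose a flow into alternating paths and cycles
#'
#' Random-walk flow decomposition: starting at the source tail, repeatedly
#' cross the marker edge and follow an adjacency arc with positive
#' remaining flow (chosen uniformly at random among continuations),
#' decrementing as it goes. A revisited extremity closes an alternating
#' cycle, which is excised and reported; reaching the sink ends a path.
#' Once all source paths are extracted, remaining flow (a circulation) is
#' swept into further cycles. The multiset of arc traversals over all
#' components reproduces the flow exactly.
#'
#' @param flow a `flow_solution`.
#' @param G the `variation_graph` the flow was computed on.
#' @param rng_seed integer seed for the random neighbor choice.
#' @return list of components, each a list with `kind` (`"path"` or
#'   `"cycle"`) and `walk` (signed marker vector; paths run source to
#'   sink, cycles are rotation-invariant).
#' @export
decompose_flow <- function(flow, G, rng_seed = 1L) {
  stopifnot(inherits(flow, "flow_solution"))
  arcs <- flow$arcs
  remaining <- arcs$flow
  out_idx <- split(seq_len(nrow(arcs)), arcs$from)  # arc rows by source extremity

  pick_arc <- function(e) {
    idx <- out_idx[[as.character(e)]]
    idx <- idx[remaining[idx] > 0L]
    if (length(idx) == 0L) return(NA_integer_)
    if (length(idx) == 1L) idx else sample(idx, 1L)
  }
  comps <- list()

  walk_from <- function(u, as_path) {
    rec_markers <- integer(0)
    rec_nodes <- u                       # rec_nodes[k] = node before marker k
    repeat {
      a <- traversal_at(u)
      rec_markers <- c(rec_markers, a)
      if (as_path && abs(a) == G$sink) {
        comps[[length(comps) + 1L]] <<- list(kind = "path", walk = rec_markers)
        return(invisible())
      }
      e <- exit_ext(a)
      k <- pick_arc(e)
      if (is.na(k))
        stop("flow conservation violated at extremity ",
             ext_label(e, G$markers))
      remaining[k] <<- remaining[k] - 1L
      u <- arcs$to[k]
      j <- match(u, rec_nodes)
      if (!is.na(j)) {                   # closed an alternating cycle
        cyc <- rec_markers[j:length(rec_markers)]
        comps[[length(comps) + 1L]] <<- list(kind = "cycle", walk = cyc)
        rec_markers <- rec_markers[seq_len(j - 1L)]
        rec_nodes <- rec_nodes[seq_len(j)]
        if (!as_path && length(rec_markers) == 0L) return(invisible())
      } else {
        rec_nodes <- c(rec_nodes, u)
      }
    }
  }

  run <- function() {
    for (p in seq_len(flow$n_founders)) walk_from(ext_tail(G$source), TRUE)
    while (any(remaining > 0L)) {
      e <- arcs$from[which(remaining > 0L)[1L]]   # an extremity with outflow
      m <- ext_marker(e)
      u <- if (ext_is_head(e)) ext_tail(m) else ext_head(m)
      walk_from(u, FALSE)
    }
  }
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(rng_seed, run())
  } else {
    set.seed(rng_seed); run()
  }
  stopifnot(all(remaining == 0L))
  # conservation check: component traversals reproduce fwd/rev
  trav <- unlist(lapply(comps, `[[`, "walk"))
  fwd <- tabulate(trav[trav > 0L], nbins = length(G$markers))
  rv <- tabulate(-trav[trav < 0L], nbins = length(G$markers))
  stopifnot(identical(fwd, as.integer(unname(flow$fwd))),
            identical(rv, as.integer(unname(flow$rev))))
  comps
}

#' Component graph of a flow decomposition
#'
#' Directed edge-labeled multigraph with one node per decomposition
#' component. Each cycle points at every other component it shares one or
#' more markers with, one edge per distinct shared marker, labeled with
#' the marker oriented as it first occurs in the cycle.
#'
#' @param components output of [decompose_flow()].
#' @return a `component_graph`: list with `components` and `edges` (data
#'   frame `from`, `to`, `label`).
#' @export
build_component_graph <- function(components) {
  n <- length(components)
  edges <- list()
  for (i in seq_len(n)) {
    if (components[[i]]$kind != "cycle") next
    ci <- components[[i]]$walk
    linked <- FALSE
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- intersect(abs(ci), abs(components[[j]]$walk))
      for (m in shared) {
        lab <- ci[match(m, abs(ci))]     # oriented as it occurs in the cycle
        edges[[length(edges) + 1L]] <- data.frame(from = i, to = j, label = lab)
        linked <- TRUE
      }
    }
    if (!linked && n > 1L)
      stop("cycle component shares no marker with any other component; ",
           "variation graph construction violated")
    if (!linked && n == 1L)
      stop("flow decomposes into a single cycle with no source-to-sink path; ",
           "variation graph construction violated")
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(from = integer(0), to = integer(0), label = integer(0))
  structure(list(components = components, edges = edges),
            class = "component_graph")
}

# splice cycle `cyc` into walk `w` at an occurrence of oriented marker
# `lab` (lab occurs in cyc). If w contains lab at position p in the same
# orientation, the rotated cycle body is inserted after p; otherwise the
# reverse complement is inserted at an occurrence of -lab.
splice_cycle <- function(w, cyc, lab) {
  r <- match(lab, cyc)
  stopifnot(!is.na(r))
  rot <- c(cyc[r:length(cyc)], if (r > 1L) cyc[seq_len(r - 1L)])  # starts with lab
  p <- match(lab, w)
  if (!is.na(p)) {
    insert <- c(rot[-1L], lab)
  } else {
    p <- match(-lab, w)
    stopifnot(!is.na(p))
    rc <- reverse_complement(rot)                 # ends with -lab
    insert <- rc
  }
  c(w[seq_len(p)], insert, if (p < length(w)) w[(p + 1L):length(w)])
}

#' Integrate cycles of a component graph into founder walks
#'
#' Successively deconstructs the component graph: singleton source-to-sink
#' walks are emitted; an in-degree-0 cycle (or, failing that, any cycle)
#' is spliced into a neighboring component at a shared marker, preferring
#' walks over cycles, with the linearization reversed when the marker is
#' embedded in opposite orientation. Incoming edges of an absorbed cycle
#' are re-targeted at the absorbing component.
#'
#' @param cg a `component_graph`.
#' @param markers marker name table (character vector or `hap_set`);
#'   used to assemble the returned `hap_set`.
#' @param source,sink marker indices of the terminals.
#' @param rng_seed integer seed for arbitrary choices among candidates.
#' @return a `hap_set` of founder walks.
#' @export
integrate_cycles <- function(cg, markers, source, sink, rng_seed = 1L) {
  stopifnot(inherits(cg, "component_graph"))
  if (inherits(markers, "hap_set")) {
    source <- markers$source; sink <- markers$sink
    markers <- markers$markers
  }
  comps <- cg$components
  edges <- cg$edges
  alive <- rep(TRUE, length(comps))
  out <- list()

  run <- function() {
    repeat {
      kinds <- vapply(comps, `[[`, "", "kind")
      live_paths <- which(alive & kinds == "path")
      indeg <- vapply(seq_along(comps), function(i)
        sum(alive[edges$from] & edges$to == i & edges$from != i), integer(1))
      for (i in live_paths[indeg[live_paths] == 0L]) {
        out[[length(out) + 1L]] <<- comps[[i]]$walk
        alive[i] <<- FALSE
      }
      live_cycles <- which(alive & kinds == "cycle")
      if (length(live_cycles) == 0L) {
        if (any(alive)) stop("unintegrable components remain")
        return(invisible())
      }
      cand <- live_cycles[indeg[live_cycles] == 0L]
      if (length(cand) == 0L) cand <- live_cycles
      ci <- if (length(cand) == 1L) cand else sample(cand, 1L)
      ei <- which(alive[edges$to] & edges$from == ci & edges$to != ci)
      stopifnot(length(ei) > 0L)
      to_paths <- ei[kinds[edges$to[ei]] == "path"]
      pool <- if (length(to_paths)) to_paths else ei
      e <- if (length(pool) == 1L) pool else sample(pool, 1L)
      tgt <- edges$to[e]
      comps[[tgt]]$walk <<- splice_cycle(comps[[tgt]]$walk,
                                         comps[[ci]]$walk, edges$label[e])
      # drop the cycle; re-target its incoming edges at the absorber
      alive[ci] <<- FALSE
      inc <- edges$to == ci
      edges$to[inc] <<- tgt
      edges <<- unique(edges[edges$from != ci & edges$from != edges$to, ,
                             drop = FALSE])
    }
  }
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(rng_seed, run())
  } else {
    set.seed(rng_seed); run()
  }
  walks <- stats::setNames(out, paste0("founder", seq_along(out)))
  hap_set(walks, markers = markers, source = markers[source],
          sink = markers[sink])
}

#' Compute a founder set for a haplotype set
#'
#' End-to-end Problem 1 pipeline: build the variation graph, solve the
#' minimum flow, decompose it into paths and cycles, and integrate cycles
#' into founder haplotypes. The returned founder set generates exactly the
#' span of `H`: its canonical pair set (and marker set) equals that of
#' `H`, and its total length equals the flow objective plus the number of
#' founders. The founder count and total length are canonical; the
#' individual founder strings depend on `rng_seed` through the
#' decomposition's random choices among co-optimal alternatives.
#'
#' @param H a `hap_set`.
#' @param rng_seed integer seed.
#' @param solver_cfg a [solver_config()].
#' @return a `hap_set` of founders with attributes `objective` (flow
#'   objective), `flow` (the `flow_solution`) and `graph`.
#' @examples
#' \donttest{
#' F <- founder_set(example_haplotypes())
#' length(F$walks)  # 2
#' }
#' @export
founder_set <- function(H, rng_seed = 1L, solver_cfg = NULL) {
  G <- build_variation_graph(H)
  flow <- solve_min_flow(G, solver_cfg)
  founders_from_flow(flow, G, rng_seed)
}

# decomposition + integration of a fixed flow (shared by founder_set and
# the randomized trials)
founders_from_flow <- function(flow, G, rng_seed) {
  comps <- decompose_flow(flow, G, rng_seed)
  cg <- build_component_graph(comps)
  FH <- integrate_cycles(cg, G$markers, G$source, G$sink,
                         rng_seed = rng_seed + 1L)
  stopifnot(setequal(names(pair_count_table(FH)), names(G$pair_counts)))
  tot <- sum(lengths(FH$walks))
  stopifnot(tot == flow$objective + length(FH$walks))
  structure(FH, objective = flow$objective, flow = flow, graph = G)
}
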