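# Extremity encoding: marker index m has tail 2m-1 and head 2m. Walking a
# marker forward enters the tail and exits the head; reverse traversal is
# the opposite. An adjacency edge joins the exit extremity of one oriented
# marker to the entry extremity of the next.

ext_tail <- function(m) 2L * m - 1L
ext_head <- function(m) 2L * m
ext_marker <- function(e) (e + 1L) %/% 2L
ext_is_head <- function(e) e %% 2L == 0L

entry_ext <- function(a) ifelse(a > 0L, ext_tail(abs(a)), ext_head(abs(a)))
exit_ext <- function(a) ifelse(a > 0L, ext_head(abs(a)), ext_tail(abs(a)))

ext_label <- function(e, markers) {
  paste0(markers[ext_marker(e)], ifelse(ext_is_head(e), "^h", "^t"))
}

# canonical undirected extremity pair (u <= v)
canon_edge <- function(u, v) cbind(pmin(u, v), pmax(u, v))
edge_key <- function(u, v) {
  e <- canon_edge(u, v)
  paste(e[, 1], e[, 2], sep = "-")
}

#' Build the variation graph of a haplotype set
#'
#' The variation graph is an undirected edge-colored multigraph over marker
#' extremities (tail/head per marker). Each marker contributes one *marker
#' edge* joining its two extremities; each consecutive oriented pair
#' observed in a haplotype (or its reverse complement) contributes one
#' *adjacency edge* joining the exit extremity of the first marker to the
#' entry extremity of the second. A pair and its reverse-complement reading
#' map to the same undirected edge; self-pairs are legal. The source tail
#' and sink head carry no adjacency edges.
#'
#' @param H a `hap_set`.
#' @return an object of class `variation_graph`: list with `markers`,
#'   `adjacency` (2-column matrix of extremity codes, canonically
#'   ordered and sorted), `pair_counts` (canonical pair multiset of `H`),
#'   `source`, `sink`, and the attached `walks`.
#' @export
build_variation_graph <- function(H) {
  stopifnot(inherits(H, "hap_set"))
  if (length(H$walks) == 0L) stop("haplotype set is empty")
  validate_hap_set(H)
  tab <- pair_count_table(H)
  adj <- unique(do.call(rbind, lapply(names(tab), function(k) {
    p <- as.integer(strsplit(k, "|", fixed = TRUE)[[1]])
    canon_edge(exit_ext(p[1]), entry_ext(p[2]))
  })))
  adj <- adj[order(adj[, 1], adj[, 2]), , drop = FALSE]
  stopifnot(!any(adj == ext_tail(H$source)), !any(adj == ext_head(H$sink)))
  # the universe is the set of markers occurring in the walks: the marker
  # table may name more (e.g. a simulation seed's full table)
  present <- sort(unique(abs(unlist(H$walks, use.names = FALSE))))
  structure(list(markers = H$markers, present = present, adjacency = adj,
                 pair_counts = tab, source = H$source, sink = H$sink,
                 walks = H$walks),
            class = "variation_graph")
}

#' @export
print.variation_graph <- function(x, ...) {
  cat(sprintf("variation_graph: %d markers, %d adjacency edges\n",
              length(x$markers), nrow(x$adjacency)))
  invisible(x)
}

#' Summary statistics of a variation graph
#'
#' @param G a `variation_graph`.
#' @return list with `n_markers`, `n_marker_edges`, `n_adjacency_edges`,
#'   `n_edges_total`, per-extremity adjacency `degree` (self-loop edges
#'   counted once), and the attached-walk length summary
#'   (`length_min`/`length_median`/`length_max`, `NA` when no walks are
#'   attached).
#' @export
graph_stats <- function(G) {
  stopifnot(inherits(G, "variation_graph"))
  loop <- G$adjacency[, 1] == G$adjacency[, 2]
  exts <- c(G$adjacency[, 1], G$adjacency[!loop, 2])  # self-loops once
  present_exts <- sort(c(ext_tail(G$present), ext_head(G$present)))
  deg <- table(factor(ext_label(exts, G$markers),
                      levels = ext_label(present_exts, G$markers)))
  lens <- lengths(G$walks)
  list(
    n_markers = length(G$present),
    n_marker_edges = length(G$present),
    n_adjacency_edges = nrow(G$adjacency),
    n_edges_total = length(G$present) + nrow(G$adjacency),
    degree = stats::setNames(as.integer(deg), names(deg)),
    n_walks = length(lens),
    length_min = if (length(lens)) min(lens) else NA_integer_,
    length_median = if (length(lens)) stats::median(lens) else NA_real_,
    length_max = if (length(lens)) max(lens) else NA_integer_
  )
}

#' Trace a walk as an alternating edge path of a variation graph
#'
#' Expresses a terminal sequence as the alternating sequence of marker and
#' adjacency edges it traverses, starting and ending with a marker edge.
#' Fails with an informative error if a consecutive pair of the walk has no
#' adjacency edge in the graph (the walk is then not in the span).
#'
#' @param G a `variation_graph`.
#' @param A walk: signed integer vector or token string.
#' @return a data frame with columns `kind` ("marker" or "adjacency"),
#'   `from`, `to` (extremity labels) and `marker` (oriented token for
#'   marker edges, `NA` otherwise).
#' @export
walk_to_edge_path <- function(G, A) {
  H <- structure(list(walks = list(), markers = G$markers,
                      source = G$source, sink = G$sink), class = "hap_set")
  A <- as_walk(A, H)
  if (is.null(A)) stop("walk refers to markers absent from the graph")
  keys <- edge_key(G$adjacency[, 1], G$adjacency[, 2])
  rows <- list()
  for (i in seq_along(A)) {
    a <- A[i]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "marker",
      from = ext_label(entry_ext(a), G$markers),
      to = ext_label(exit_ext(a), G$markers),
      marker = paste0(ifelse(a > 0, ">", "<"), G$markers[abs(a)]),
      stringsAsFactors = FALSE)
    if (i < length(A)) {
      b <- A[i + 1L]
      k <- edge_key(exit_ext(a), entry_ext(b))
      if (!(k %in% keys))
        stop(sprintf("not in span: pair (%s, %s) at position %d has no adjacency edge",
                     render_walk(a, G$markers), render_walk(b, G$markers), i))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "adjacency",
        from = ext_label(exit_ext(a), G$markers),
        to = ext_label(entry_ext(b), G$markers),
        marker = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
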