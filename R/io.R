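#' Read and write walk files
#'
#' The walk format stores one record per line, either a bare walk string or
#' `name<TAB>walk`. A walk string concatenates oriented marker tokens,
#' `>id` for forward and `<id` for reverse, e.g. `">1>2>3<7>5"`. Lines
#' starting with `#` are comments. When the input's terminals are ordinary
#' marker ids, name them via `source`/`sink`; when walks lack terminal
#' markers entirely, set `add_terminals = TRUE` to wrap them.
#'
#' @param path file path.
#' @param source,sink terminal marker names expected in the input.
#' @param add_terminals wrap walks with terminals when missing.
#' @return a `hap_set`.
#' @export
read_walks <- function(path, source = "s", sink = "S", add_terminals = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no walk records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  named <- lengths(parts) >= 2L
  nms <- ifelse(named, vapply(parts, `[`, "", 1L), paste0("walk", seq_along(parts)))
  ws <- ifelse(named, vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  walks <- stats::setNames(as.list(ws), nms)
  ok <- try(hap_set(walks, source = source, sink = sink,
                    add_terminals = add_terminals), silent = TRUE)
  if (inherits(ok, "try-error")) {
    # re-parse line by line for an error message with a line number
    for (i in seq_along(walks)) {
      e <- try(hap_set(walks[i], source = source, sink = sink,
                       add_terminals = add_terminals), silent = TRUE)
      if (inherits(e, "try-error"))
        stop("parse error at walk record ", i, " ('", nms[i], "'): ",
             conditionMessage(attr(e, "condition")))
    }
    stop(conditionMessage(attr(ok, "condition")))
  }
  ok
}

#' @rdname read_walks
#' @param H a `hap_set` to write.
#' @param header optional character vector of provenance lines, written as
#'   `#`-prefixed comments.
#' @export
write_walks <- function(H, path, header = NULL) {
  stopifnot(inherits(H, "hap_set"))
  lines <- c(
    if (length(header)) paste0("# ", header),
    vapply(names(H$walks),
           function(nm) paste(nm, render_walk(H$walks[[nm]], H$markers), sep = "\t"),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export a variation graph as GFA1
#'
#' Writes one S-line per marker (sequence `*`, tag `LN:i:1`), one L-line
#' per adjacency edge (orientations derived from the extremity sides,
#' overlap `0M`) and one P-line per attached walk. Line ordering is sorted
#' and deterministic so output is bit-reproducible.
#'
#' @param G a `variation_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gfa <- function(G, path) {
  stopifnot(inherits(G, "variation_graph"))
  s_lines <- sort(paste0("S\t", G$markers, "\t*\tLN:i:1"))
  # An adjacency edge {u, v} is an observed consecution: exiting through u,
  # entering through v. Exit at a head means forward ('+') traversal of the
  # first marker; entry at a tail means forward traversal of the second.
  l_lines <- sort(apply(G$adjacency, 1L, function(e) {
    u <- e[1]; v <- e[2]
    paste("L", G$markers[ext_marker(u)], if (ext_is_head(u)) "+" else "-",
          G$markers[ext_marker(v)], if (ext_is_head(v)) "-" else "+",
          "0M", sep = "\t")
  }))
  p_lines <- sort(vapply(names(G$walks), function(nm) {
    w <- G$walks[[nm]]
    paste("P", nm,
          paste0(G$markers[abs(w)], ifelse(w > 0, "+", "-"), collapse = ","),
          "*", sep = "\t")
  }, character(1)))
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines, p_lines), path)
  invisible(path)
}
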