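#' Haplotype sets of oriented marker walks
#'
#' A `hap_set` holds a collection of named walks over a common universe of
#' genomic markers. Each walk is stored as a signed integer vector: the
#' absolute value indexes into the marker table and the sign encodes
#' orientation (positive = forward, negative = reverse). Two designated
#' markers act as *terminals*: every haplotype starts with the forward
#' source marker and ends with the forward sink marker, and terminals never
#' occur at interior positions.
#'
#' @param walks a named list of walks. Each walk may be a signed integer
#'   vector (referring to `markers`), or a character scalar in token
#'   notation, e.g. `">s<1>2>3<4<3>S"` where `>` denotes forward and `<`
#'   reverse orientation.
#' @param markers character vector of marker names; required when walks are
#'   given as integer vectors, otherwise derived from the tokens.
#' @param source,sink names of the source and sink terminal markers.
#' @param add_terminals if `TRUE`, walks lacking the terminal markers are
#'   wrapped with a leading forward source and trailing forward sink.
#'   Useful for inputs whose terminals are ordinary ids (e.g. `1` and `8`).
#' @return an object of class `hap_set` with elements `walks` (named list
#'   of signed integer vectors), `markers` (character), `source` and `sink`
#'   (marker indices).
#' @examples
#' H <- hap_set(list(A = ">s<1>2>3<4<3>S"))
#' H$walks$A
#' @export
hap_set <- function(walks, markers = NULL, source = "s", sink = "S",
                    add_terminals = FALSE) {
  if (!is.list(walks)) walks <- as.list(walks)
  if (is.null(names(walks)) || anyNA(names(walks)) || any(names(walks) == "")) {
    names(walks) <- paste0("walk", seq_along(walks))
  }
  if (anyDuplicated(names(walks)))
    stop("walk names must be unique")
  chr <- vapply(walks, is.character, logical(1))
  if (any(chr)) {
    toks <- lapply(walks, function(w) if (is.character(w)) tokenize_walk(w) else NULL)
    used <- unique(unlist(lapply(toks, function(t) t$id)))
    markers <- unique(c(markers, source, sink, used))
    walks <- mapply(function(w, t) {
      if (is.character(w)) {
        idx <- match(t$id, markers)
        idx * t$orient
      } else as.integer(w)
    }, walks, toks, SIMPLIFY = FALSE)
  } else {
    if (is.null(markers)) stop("`markers` is required for integer walks")
    walks <- lapply(walks, as.integer)
  }
  markers <- unique(c(markers, source, sink))
  src <- match(source, markers)
  snk <- match(sink, markers)
  if (src == snk) stop("source and sink markers must be distinct")
  if (add_terminals) {
    walks <- lapply(walks, function(w) {
      if (length(w) == 0L || w[1] != src) w <- c(src, w)
      if (w[length(w)] != snk) w <- c(w, snk)
      w
    })
  }
  H <- structure(list(walks = walks, markers = markers,
                      source = src, sink = snk),
                 class = "hap_set")
  validate_hap_set(H)
  H
}

tokenize_walk <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) stop("empty walk string")
  toks <- regmatches(s, gregexpr("[><][^><]+", s))[[1]]
  if (sum(nchar(toks)) != nchar(s))
    stop("malformed walk string: ", s)
  list(id = substring(toks, 2L),
       orient = ifelse(substring(toks, 1L, 1L) == ">", 1L, -1L))
}

validate_hap_set <- function(H) {
  stopifnot(inherits(H, "hap_set"))
  for (nm in names(H$walks)) {
    w <- H$walks[[nm]]
    err <- walk_problem(w, H)
    if (!is.null(err)) stop("walk '", nm, "': ", err)
  }
  invisible(H)
}

# NULL if `w` is a valid haplotype of H, else a message
walk_problem <- function(w, H) {
  if (length(w) < 2L) return("haplotype must contain at least source and sink")
  if (any(w == 0L) || any(abs(w) > length(H$markers)) || anyNA(w))
    return("marker index out of range")
  if (w[1] != H$source) return("must start with the forward source marker")
  if (w[length(w)] != H$sink) return("must end with the forward sink marker")
  inner <- w[-c(1L, length(w))]
  if (any(abs(inner) %in% c(H$source, H$sink)))
    return("terminal marker at interior position")
  NULL
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("hap_set: %d walk(s) over %d markers (source=%s, sink=%s)\n",
              length(x$walks), length(x$markers),
              x$markers[x$source], x$markers[x$sink]))
  for (nm in names(x$walks))
    cat(sprintf("  %-12s %s\n", nm, render_walk(x$walks[[nm]], x$markers)))
  invisible(x)
}

#' Render a walk in token notation
#'
#' @param w signed integer walk vector.
#' @param markers marker name table (a character vector, or a `hap_set`
#'   whose marker table is used).
#' @return a single string such as `">s<1>2>S"`.
#' @export
render_walk <- function(w, markers) {
  if (inherits(markers, "hap_set")) markers <- markers$markers
  paste0(ifelse(w > 0, ">", "<"), markers[abs(w)], collapse = "")
}

#' Is a terminal sequence / haplotype structurally valid?
#'
#' A terminal sequence starts with the forward source or reverse sink,
#' ends with the forward sink or reverse source, and has no interior
#' terminal markers. A haplotype is the source-to-sink special case.
#'
#' @param w signed integer walk vector.
#' @param H a `hap_set` supplying the marker table and terminal ids.
#' @return logical scalar.
#' @export
is_terminal_sequence <- function(w, H) {
  if (length(w) < 2L) return(FALSE)
  n <- length(w)
  if (!(w[1] == H$source || w[1] == -H$sink)) return(FALSE)
  if (!(w[n] == H$sink || w[n] == -H$source)) return(FALSE)
  !any(abs(w[-c(1L, n)]) %in% c(H$source, H$sink))
}

#' @rdname is_terminal_sequence
#' @export
is_haplotype <- function(w, H) {
  is.null(walk_problem(w, H))
}

# replace the walk list, keeping marker table / terminals
set_walks <- function(H, walks) {
  H$walks <- walks
  validate_hap_set(H)
}
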