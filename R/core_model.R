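#' Reverse complementation of a marker walk
#'
#' Reverses the order of the walk and flips every marker's orientation.
#' Applied to a terminal sequence it yields a terminal sequence; it is an
#' involution.
#'
#' @param w signed integer walk vector.
#' @return the reverse-complemented walk.
#' @examples
#' H <- hap_set(list(A = ">s<1>2>3<4<3>S"))
#' render_walk(reverse_complement(H$walks$A), H)
#' @export
reverse_complement <- function(w) {
  rev(-as.integer(w))
}

#' Recombination (crossover) of two terminal sequences
#'
#' Models (non-)allelic homologous recombination as a crossover at a shared,
#' identically oriented marker: given `A[i] == B[j]`, the product is
#' `A[..i] + B[j+1..]`. Positions are 1-based and inclusive.
#'
#' @param A,B signed integer walk vectors.
#' @param i,j crossover positions into `A` and `B`.
#' @return the recombinant walk, of length `i + length(B) - j`.
#' @examples
#' H <- hap_set(list(A = ">s<1>2>3<4<3>S"))
#' A <- H$walks$A
#' X <- recombine(A, reverse_complement(A), 4, 2)
#' render_walk(X, H)
#' @export
recombine <- function(A, B, i, j) {
  if (i < 1L || i > length(A) || j < 1L || j > length(B))
    stop("crossover position out of range")
  if (A[i] != B[j])
    stop("A[i] and B[j] must be the same marker in the same orientation")
  c(A[seq_len(i)], if (j < length(B)) B[(j + 1L):length(B)] else integer(0))
}

# consecutive pairs of a walk as a 2-column matrix
walk_pairs <- function(w) {
  n <- length(w)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(w[-n], w[-1L])
}

# canonical representative of the pair (a, b) ~ (-b, -a), vectorized.
# The canonical form is the lexicographically smaller of the two readings.
canon_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  swap <- (-b < a) | (-b == a & -a < b)
  cbind(ifelse(swap, -b, a), ifelse(swap, -a, b))
}

pair_key <- function(a, b) {
  p <- canon_pair(a, b)
  paste(p[, 1], p[, 2], sep = "|")
}

# multiset of canonical consecutive pairs over a list of walks
pair_count_table <- function(walks) {
  if (inherits(walks, "hap_set")) walks <- walks$walks
  keys <- unlist(lapply(walks, function(w) {
    p <- walk_pairs(w)
    pair_key(p[, 1], p[, 2])
  }), use.names = FALSE)
  if (length(keys) == 0L) return(integer(0))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

#' Multiplicity of a consecutive oriented marker pair
#'
#' Counts positions `(A, i)` across the sequence set where `A[i..i+1]`
#' equals the pair `(m1, m2)` or its reverse-complement reading
#' `(-m2, -m1)`. By construction the count is symmetric:
#' `pair_multiplicity(X, m1, m2) == pair_multiplicity(X, -m2, -m1)`.
#'
#' @param X a `hap_set` or a list of signed integer walks.
#' @param m1,m2 the oriented markers of the pair: signed indices into the
#'   marker table, or (when `X` is a `hap_set`) oriented tokens such as
#'   `">3"` / `"<4"`.
#' @return integer count.
#' @examples
#' pair_multiplicity(example_haplotypes(), ">3", "<4")
#' @export
pair_multiplicity <- function(X, m1, m2) {
  if (is.character(m1) || is.character(m2)) {
    stopifnot(inherits(X, "hap_set"))
    m1 <- oriented_id(m1, X)
    m2 <- oriented_id(m2, X)
  }
  tab <- pair_count_table(X)
  k <- pair_key(m1, m2)
  if (k %in% names(tab)) tab[[k]] else 0L
}

# ">name"/"<name" token (or plain name = forward) to signed marker index
oriented_id <- function(tok, H) {
  if (is.numeric(tok)) return(as.integer(tok))
  orient <- 1L
  if (startsWith(tok, ">")) tok <- substring(tok, 2L)
  else if (startsWith(tok, "<")) { orient <- -1L; tok <- substring(tok, 2L) }
  idx <- match(tok, H$markers)
  if (is.na(idx)) stop("unknown marker: ", tok)
  idx * orient
}

# successor map: for oriented marker a, which oriented markers b may follow
# so that the pair (a, b) is supported by the pair set
pair_successors <- function(pair_keys) {
  mat <- do.call(rbind, lapply(strsplit(pair_keys, "|", fixed = TRUE), as.integer))
  succ <- list()
  add <- function(a, b) {
    k <- as.character(a)
    succ[[k]] <<- c(succ[[k]], b)
  }
  for (r in seq_len(nrow(mat))) {
    a <- mat[r, 1]; b <- mat[r, 2]
    add(a, b)
    if (!(a == -b && b == -a)) add(-b, -a)   # reverse reading, skip palindromic
  }
  lapply(succ, unique)
}

#' Span membership via the pair criterion
#'
#' A haplotype `Q` lies in the span of `H` (the set of all haplotypes
#' generable from `H` by iterated recombination) if and only if every
#' consecutive oriented pair of `Q` occurs in `H` or its reverse
#' complements — equivalently, `Q` is an alternating source-to-sink walk of
#' the variation graph of `H`.
#'
#' @param H a `hap_set`.
#' @param Q a candidate walk: signed integer vector over `H`'s marker
#'   table, or a token string.
#' @return logical scalar; `FALSE` also when `Q` is not a structurally
#'   valid haplotype over `H`'s universe.
#' @export
span_contains <- function(H, Q) {
  Q <- as_walk(Q, H)
  if (is.null(Q) || !is_haplotype(Q, H)) return(FALSE)
  tab <- pair_count_table(H)
  p <- walk_pairs(Q)
  all(pair_key(p[, 1], p[, 2]) %in% names(tab))
}

# coerce token strings to signed walks over H's existing marker table;
# NULL if a token refers to an unknown marker
as_walk <- function(Q, H) {
  if (is.character(Q)) {
    t <- tokenize_walk(Q)
    idx <- match(t$id, H$markers)
    if (anyNA(idx)) return(NULL)
    as.integer(idx * t$orient)
  } else as.integer(Q)
}

#' Exhaustively enumerate the span of a haplotype set
#'
#' Breadth-first enumeration of all alternating source-to-sink walks of the
#' variation graph, up to a maximum walk length. Intended as a test oracle
#' on small instances; the frontier guard aborts on combinatorial
#' explosion.
#'
#' @param H a `hap_set`.
#' @param max_len maximum haplotype length (number of markers, terminals
#'   included).
#' @param max_frontier abort when the BFS frontier exceeds this size.
#' @return list of signed integer walks, lexicographically ordered.
#' @export
enumerate_span <- function(H, max_len, max_frontier = 1e5) {
  tab <- pair_count_table(H)
  succ <- pair_successors(names(tab))
  out <- list()
  frontier <- list(c(H$source))
  len <- 1L
  while (length(frontier) > 0L && len < max_len) {
    nxt <- list()
    for (w in frontier) {
      last <- w[length(w)]
      for (b in succ[[as.character(last)]]) {
        if (abs(b) == H$source) next          # interior/reverse terminal: dead end
        if (b == -H$sink) next
        w2 <- c(w, b)
        if (b == H$sink) out[[length(out) + 1L]] <- w2
        else nxt[[length(nxt) + 1L]] <- w2
      }
    }
    if (length(nxt) > max_frontier)
      stop("span enumeration frontier exceeded ", max_frontier)
    frontier <- nxt
    len <- len + 1L
  }
  keys <- vapply(out, function(w) paste(w, collapse = ","), character(1))
  out[order(keys)]
}
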