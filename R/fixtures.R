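#' Bundled worked examples
#'
#' `example_single_haplotype()` returns the single-haplotype set
#' \{A = >s<1>2>3<4<3>S\}, whose span consists of exactly two haplotypes
#' (the second arises by an inversion between the two inverted copies of
#' marker 3). `example_haplotypes()` returns the four-haplotype set H1-H4
#' over markers 1-4 featuring a tandem duplication of marker 1, an
#' inverted repeat of markers 3/4, and a deletion; its variation graph has
#' 6 marker edges and 12 adjacency edges and admits a founder set of two
#' sequences.
#'
#' @return a `hap_set`.
#' @export
example_single_haplotype <- function() {
  hap_set(list(A = ">s<1>2>3<4<3>S"))
}

#' @rdname example_single_haplotype
#' @export
example_haplotypes <- function() {
  hap_set(list(
    H1 = ">s<1>2>3<4<3>S",
    H2 = ">s>1>1>1>2>3>4<3>S",
    H3 = ">s<1>2>3<4<3<2>3<4<3>S",
    H4 = ">s<1>2>S"
  ))
}

#' Load locus-style walk data with ordinary terminal ids
#'
#' Loader for marker-walk tables such as the 68-haplotype data of the
#' human 1p36.13 locus, where the source and sink are ordinary marker ids
#' (1 and 8). The table itself is not redistributed with the package; pass
#' the path to a local copy (TSV with columns name and walk, or one walk
#' per line).
#'
#' @param path path to a walk file.
#' @param source_id,sink_id marker ids acting as source and sink.
#' @return a `hap_set`.
#' @export
load_locus_walks <- function(path, source_id = "1", sink_id = "8") {
  if (!file.exists(path))
    stop("walk file not found: '", path, "'.\n",
         "This data set is not bundled; supply a local copy as a TSV of ",
         "name<TAB>walk records (walks in '>id'/'<id' token notation).")
  read_walks(path, source = source_id, sink = sink_id)
}
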