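#' Levenshtein edit distance between DNA strings
#'
#' Unit-cost edit distance (minimum number of substitutions, insertions and
#' deletions transforming `a` into `b`), the metric governing barcode
#' distinguishability: a set with minimum pairwise distance d detects up to
#' d-1 edits and uniquely corrects up to floor((d-1)/2).
#'
#' @param a,b character vectors over `{A,C,G,T,N}` (recycled to the longer
#'   length).
#' @return integer vector of distances.
#' @examples
#' levenshtein("ACGT", "ACGT")  # 0
#' levenshtein("ACGT", "AGT")   # 1
#' @export
levenshtein <- function(a, b) {
  assert_dna(a, "a"); assert_dna(b, "b")
  cpp_levenshtein(toupper(a), toupper(b))
}

#' All pairwise Levenshtein distances within a set
#'
#' @param x character vector of DNA strings.
#' @return symmetric integer matrix of distances.
#' @export
levenshtein_matrix <- function(x) {
  assert_dna(x, "x")
  m <- cpp_lev_pairwise(toupper(x))
  dimnames(m) <- list(names(x), names(x))
  m
}
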