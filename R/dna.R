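#' DNA string utilities
#'
#' Small helpers shared across the package: reverse complement with full
#' IUPAC-degeneracy support, base composition, homopolymer runs, and random
#' sequence generation used by the barcode designers and the simulator.
#'
#' @name dna-utils
NULL

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"
IUPAC_COMP <- "TGCAYRSWMKVHDBN"

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC degeneracy alphabet (so degenerate primers such as
#' 806R `GGACTACNVGGGTWTCTAAT` complement correctly). Case-insensitive;
#' output is upper case.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("GGACTACNVGGGTWTCTAAT")
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  bad <- grepl(paste0("[^", IUPAC_CHARS, "]"), x)
  if (any(bad))
    stop("non-DNA characters in sequence(s): ", paste(x[bad], collapse = ", "))
  comp <- chartr(IUPAC_CHARS, IUPAC_COMP, x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' @rdname dna-utils
#' @param x character vector of DNA strings.
#' @return `gc_fraction`: fraction of G/C bases per string.
#' @export
gc_fraction <- function(x) {
  x <- toupper(x)
  (nchar(gsub("[^GC]", "", x))) / nchar(x)
}

#' @rdname dna-utils
#' @return `max_homopolymer`: length of the longest single-base run.
#' @export
max_homopolymer <- function(x) {
  vapply(strsplit(toupper(x), ""), function(ch) {
    if (length(ch) == 0) return(0L)
    max(rle(ch)$lengths)
  }, integer(1))
}

# Random ACGT strings of the given lengths (vectorized over `lengths`).
random_dna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
}

assert_dna <- function(x, what = "sequence", allow_iupac = FALSE) {
  alpha <- if (allow_iupac) IUPAC_CHARS else "ACGTN"
  bad <- !grepl(paste0("^[", alpha, "]*$"), toupper(x))
  if (any(bad))
    stop(what, " contains non-DNA characters: ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(toupper(x))
}
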