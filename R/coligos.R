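#' Cross-contamination checking oligonucleotides (coligos)
#'
#' A coligo is a short synthetic tracer added one-per-well before (or
#' during) DNA extraction: a unique 13-nt identifier bookended by sequence
#' complementary to the locus PCR primers, so it amplifies and sequences
#' alongside real amplicons. Reading the 13 bases after the forward primer
#' reveals which well each coligo read originated from; coligo reads found
#' in the wrong well quantify cross-contamination.
#'
#' Identifiers are designed at pairwise Levenshtein distance >= 3, the
#' minimum that both detects and uniquely corrects any single substitution,
#' insertion or deletion.
#'
#' @name coligos
NULL

coligo_constraints <- function(x = list()) {
  defaults <- list(min_distance = 3L, gc_bounds = c(0.4, 0.6),
                   max_homopolymer = 3L)
  defaults[names(x)] <- x
  defaults
}

#' Design a set of error-correcting coligo identifiers
#'
#' Seeded rejection sampling: random candidates of the target length are
#' kept when their GC content and homopolymer runs are within bounds and
#' they sit at Levenshtein distance >= `min_distance` from every accepted
#' identifier.
#'
#' @param n number of identifiers.
#' @param length identifier length in nt (default 13).
#' @param constraints list with `min_distance` (default 3), `gc_bounds`
#'   (default `c(0.4, 0.6)`), `max_homopolymer` (default 3).
#' @param seed integer seed (required).
#' @param max_attempts candidate budget.
#' @return data.frame with columns `id`, `sequence`.
#' @export
generate_coligo_identifiers <- function(n, length = 13L, constraints = list(),
                                        seed, max_attempts = 1e6) {
  if (missing(seed)) stop("seed is required for reproducible design")
  cons <- coligo_constraints(constraints)
  if (n > 4^length)
    stop("infeasible request: ", n, " identifiers of length ", length,
         " exceed the 4^", length, " possible sequences")
  set.seed(seed)
  acc <- character(0)
  attempts <- 0L
  while (length(acc) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("coligo generation budget of ", max_attempts,
           " candidates exhausted: obtained ", length(acc), " of ", n)
    cand <- random_dna(length)
    if (max_homopolymer(cand) > cons$max_homopolymer) next
    gc <- gc_fraction(cand)
    if (gc < cons$gc_bounds[1] || gc > cons$gc_bounds[2]) next
    if (length(acc) &&
        min(cpp_levenshtein(rep(cand, length(acc)), acc)) < cons$min_distance)
      next
    acc <- c(acc, cand)
  }
  out <- data.frame(id = sprintf("coligo%02d", seq_len(n)), sequence = acc,
                    stringsAsFactors = FALSE)
  rep <- validate_coligo_set(out, constraints = cons)
  stopifnot(rep$pass)
  out
}

#' Validate a coligo identifier set
#'
#' Reports every identifier pair closer than the minimum Levenshtein
#' distance (3 is required for single-edit detection *and* correction) and
#' any composition violations. Violations are reported, not raised.
#'
#' @param identifiers data.frame with `id`, `sequence`, or a character
#'   vector of sequences.
#' @param constraints see [generate_coligo_identifiers()].
#' @return list with `pass` and `violations` (data.frame `check`, `detail`).
#' @export
validate_coligo_set <- function(identifiers, constraints = list()) {
  cons <- coligo_constraints(constraints)
  seqs <- if (is.data.frame(identifiers)) identifiers$sequence else identifiers
  if (length(seqs) == 0L) stop("empty identifier set")
  assert_dna(seqs, "coligo identifier")
  viol <- list()
  add <- function(check, detail)
    viol[[length(viol) + 1L]] <<- data.frame(check = check, detail = detail,
                                             stringsAsFactors = FALSE)
  bad <- max_homopolymer(seqs) > cons$max_homopolymer
  for (s in seqs[bad]) add("homopolymer", s)
  gc <- gc_fraction(seqs)
  bad <- gc < cons$gc_bounds[1] | gc > cons$gc_bounds[2]
  for (s in seqs[bad]) add("gc", s)
  if (length(seqs) > 1L) {
    d <- cpp_lev_pairwise(seqs)
    idx <- which(d < cons$min_distance & upper.tri(d), arr.ind = TRUE)
    for (k in seq_len(nrow(idx)))
      add("min_distance",
          sprintf("%s/%s (distance %d)", seqs[idx[k, 1]], seqs[idx[k, 2]],
                  d[idx[k, 1], idx[k, 2]]))
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), detail = character(),
               stringsAsFactors = FALSE)
  list(pass = nrow(viol) == 0L, violations = viol)
}

#' Assemble a full coligo sequence
#'
#' The synthesized molecule is forward primer + identifier + reverse
#' complement of the reverse primer, so that both locus primers anneal to
#' it and the identifier is read immediately after the forward primer.
#' IUPAC degeneracy codes are honoured in the primers.
#'
#' @param identifier one row of a coligo identifier table (or a list with
#'   `id` and `sequence`).
#' @param fwd_primer,rev_primer locus primer sequences (IUPAC allowed).
#' @return object of class `coligo` with fields `identifier`, `fwd_primer`,
#'   `rev_primer`, `full_sequence`.
#' @export
build_coligo <- function(identifier, fwd_primer, rev_primer) {
  if (is.data.frame(identifier)) identifier <- as.list(identifier[1, ])
  if (is.null(identifier$sequence) || !nzchar(identifier$sequence))
    stop("coligo identifier sequence is empty")
  assert_dna(identifier$sequence, "identifier")
  if (!nzchar(fwd_primer) || !nzchar(rev_primer))
    stop("primers must be nonempty")
  assert_dna(fwd_primer, "fwd_primer", allow_iupac = TRUE)
  assert_dna(rev_primer, "rev_primer", allow_iupac = TRUE)
  full <- paste0(toupper(fwd_primer), toupper(identifier$sequence),
                 reverse_complement(rev_primer))
  structure(list(identifier = identifier, fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer), full_sequence = full),
            class = "coligo")
}

#' @export
print.coligo <- function(x, ...) {
  cat(sprintf("coligo %s: %d nt (%d primer + %d id + %d primer-rc)\n",
              x$identifier$id %||% "?", nchar(x$full_sequence),
              nchar(x$fwd_primer), nchar(x$identifier$sequence),
              nchar(x$rev_primer)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
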