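#' Molecular identifier (MID) sets for dual indexing
#'
#' MIDs are short sample-identifying oligonucleotides sequenced inline at
#' the start of both mates of a read pair. Variable lengths (8-10 nt by
#' default) inject base diversity into the first sequencing cycles, and a
#' minimum same-length Levenshtein distance of 2 lets single errors be
#' detected without risking silent mis-assignment. Dual indexing with n
#' forward and n reverse MIDs distinguishes n^2 sample replicates.
#'
#' `mid_set()` assembles forward/reverse MID tables into a validated set;
#' `generate_mid_set()` designs one de novo by seeded rejection sampling.
#'
#' @param forward,reverse data.frames with columns `id`, `sequence` (an
#'   optional `length` column is recomputed).
#' @param constraints list with elements `min_same_length_distance`
#'   (default 2), `min_cross_length_distance` (default 3: MIDs of
#'   different lengths must sit at Levenshtein distance >= 3, which keeps a
#'   single indel in one MID from mimicking a MID of a neighbouring
#'   length), `max_homopolymer` (default 3), `gc_bounds` (default
#'   `c(0.3, 0.7)`), `length_range` (default `c(8, 10)`), `forbid_prefix`
#'   (default `TRUE`: within an orientation no MID may be a prefix of a
#'   longer one, which keeps variable-length matching unambiguous).
#' @return an object of class `mid_set`.
#' @export
mid_set <- function(forward, reverse, constraints = list()) {
  cons <- mid_constraints(constraints)
  tidy <- function(df, orientation) {
    stopifnot(all(c("id", "sequence") %in% names(df)))
    df <- data.frame(id = as.character(df$id),
                     sequence = assert_dna(df$sequence, "MID sequence"),
                     stringsAsFactors = FALSE)
    df$length <- nchar(df$sequence)
    df$orientation <- orientation
    if (anyDuplicated(df$id)) stop("duplicate MID ids (", orientation, ")")
    df
  }
  structure(list(forward = tidy(forward, "forward"),
                 reverse = tidy(reverse, "reverse"),
                 constraints = cons),
            class = "mid_set")
}

mid_constraints <- function(x = list()) {
  defaults <- list(min_same_length_distance = 2L,
                   min_cross_length_distance = 3L, max_homopolymer = 3L,
                   gc_bounds = c(0.3, 0.7), length_range = c(8L, 10L),
                   forbid_prefix = TRUE)
  defaults[names(x)] <- x
  defaults
}

#' @export
print.mid_set <- function(x, ...) {
  cat(sprintf("mid_set: %d forward + %d reverse MIDs (lengths %s)\n",
              nrow(x$forward), nrow(x$reverse),
              paste(sort(unique(c(x$forward$length, x$reverse$length))),
                    collapse = "/")))
  cat(sprintf("  dual-index capacity: %d\n",
              dual_index_capacity(nrow(x$forward), nrow(x$reverse))))
  invisible(x)
}

#' Validate a MID set against its design constraints
#'
#' Checks, within each orientation: sequence lengths inside the configured
#' range, homopolymer cap, GC bounds, pairwise Levenshtein distance of
#' same-length MIDs at or above the minimum, and (optionally) absence of
#' prefix relations between MIDs of different lengths. Violations are
#' reported, not raised.
#'
#' @param set a [mid_set()].
#' @return list with `pass` (logical) and `violations` (data.frame with
#'   columns `orientation`, `check`, `detail`).
#' @export
validate_mid_set <- function(set) {
  stopifnot(inherits(set, "mid_set"))
  cons <- set$constraints
  viol <- list()
  add <- function(orientation, check, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      orientation = orientation, check = check, detail = detail,
      stringsAsFactors = FALSE)
  for (ori in c("forward", "reverse")) {
    df <- set[[ori]]
    if (nrow(df) == 0L) { add(ori, "empty", "no MIDs"); next }
    bad <- df$length < cons$length_range[1] | df$length > cons$length_range[2]
    for (s in df$sequence[bad]) add(ori, "length", s)
    bad <- max_homopolymer(df$sequence) > cons$max_homopolymer
    for (s in df$sequence[bad]) add(ori, "homopolymer", s)
    gc <- gc_fraction(df$sequence)
    bad <- gc < cons$gc_bounds[1] | gc > cons$gc_bounds[2]
    for (s in df$sequence[bad]) add(ori, "gc", s)
    for (L in unique(df$length)) {
      seqs <- df$sequence[df$length == L]
      if (length(seqs) < 2L) next
      d <- cpp_lev_pairwise(seqs)
      idx <- which(d < cons$min_same_length_distance & upper.tri(d),
                   arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        add(ori, "min_distance",
            paste(seqs[idx[k, 1]], seqs[idx[k, 2]], sep = "/"))
    }
    if (length(unique(df$length)) > 1L) {
      M <- cpp_lev_pairwise(df$sequence)
      cross <- outer(df$length, df$length, "!=") & upper.tri(M)
      idx <- which(M < cons$min_cross_length_distance & cross,
                   arr.ind = TRUE)
      for (k in seq_len(nrow(idx)))
        add(ori, "cross_length_distance",
            paste(df$sequence[idx[k, 1]], df$sequence[idx[k, 2]],
                  sep = "/"))
    }
    if (isTRUE(cons$forbid_prefix)) {
      n <- nrow(df)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || df$length[i] >= df$length[j]) next
        if (startsWith(df$sequence[j], df$sequence[i]))
          add(ori, "prefix",
              paste(df$sequence[i], df$sequence[j], sep = "/"))
      }
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(orientation = character(), check = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(pass = nrow(viol) == 0L, violations = viol)
}

#' Design a variable-length MID set by seeded rejection sampling
#'
#' Draws random candidates length by length (shortest first) and keeps each
#' candidate only if it satisfies the composition constraints, sits at
#' Levenshtein distance at or above the same-length minimum from every
#' accepted MID of the same length and orientation and at or above the
#' cross-length minimum from accepted MIDs of other lengths, and creates
#' no prefix relation with them. Deterministic given `seed`.
#'
#' @param n_per_length named vector, MID length -> count, per orientation
#'   (default `c("8" = 32, "9" = 32, "10" = 32)`, i.e. 96 MIDs each way).
#' @param constraints see [mid_set()].
#' @param seed integer seed (required).
#' @param max_attempts total candidate budget per orientation.
#' @return a validated [mid_set()].
#' @export
generate_mid_set <- function(n_per_length = c("8" = 32, "9" = 32, "10" = 32),
                             constraints = list(), seed,
                             max_attempts = 1e6) {
  if (missing(seed)) stop("seed is required for reproducible design")
  cons <- mid_constraints(constraints)
  cons$length_range <- range(as.integer(names(n_per_length)))
  set.seed(seed)
  gen_one <- function(orientation, offset) {
    acc <- character(0); acc_len <- integer(0)
    attempts <- 0L
    for (L in sort(as.integer(names(n_per_length)))) {
      want <- n_per_length[[as.character(L)]]
      if (want > 4^L)
        stop("infeasible request: ", want, " MIDs of length ", L,
             " exceed the 4^", L, " possible sequences")
      got <- 0L
      while (got < want) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("MID generation budget of ", max_attempts,
               " candidates exhausted (", orientation, "): obtained ",
               length(acc), " of ", sum(n_per_length))
        cand <- random_dna(L)
        if (max_homopolymer(cand) > cons$max_homopolymer) next
        gc <- gc_fraction(cand)
        if (gc < cons$gc_bounds[1] || gc > cons$gc_bounds[2]) next
        same <- acc[acc_len == L]
        if (length(same) &&
            min(cpp_levenshtein(rep(cand, length(same)), same)) <
              cons$min_same_length_distance) next
        other <- acc[acc_len != L]
        if (length(other) &&
            min(cpp_levenshtein(rep(cand, length(other)), other)) <
              cons$min_cross_length_distance) next
        if (isTRUE(cons$forbid_prefix)) {
          shorter <- acc[acc_len < L]
          if (length(shorter) && any(startsWith(cand, shorter))) next
          longer <- acc[acc_len > L]
          if (length(longer) && any(startsWith(longer, cand))) next
        }
        acc <- c(acc, cand); acc_len <- c(acc_len, L); got <- got + 1L
      }
    }
    data.frame(id = sprintf("%s%03d", offset, seq_along(acc)),
               sequence = acc, stringsAsFactors = FALSE)
  }
  set <- mid_set(gen_one("forward", "F"), gen_one("reverse", "R"),
                 constraints = cons)
  stopifnot(validate_mid_set(set)$pass)
  set
}

#' Dual-index sample capacity
#'
#' With a MID at each end of the template, sample identity is the ordered
#' (forward, reverse) pair, so n forward and m reverse MIDs index n x m
#' replicates (9,216 for 96 + 96).
#'
#' @param n_fwd,n_rev nonnegative MID counts.
#' @return integer capacity.
#' @export
dual_index_capacity <- function(n_fwd, n_rev) {
  stopifnot(n_fwd >= 0, n_rev >= 0)
  as.integer(n_fwd) * as.integer(n_rev)
}

#' Read / write MID sets as TSV
#'
#' Columns `id`, `sequence`, `length`, `orientation`.
#'
#' @param set a [mid_set()]; `path` a file path.
#' @return `read_mid_set`: a [mid_set()].
#' @export
write_mid_set <- function(set, path) {
  stopifnot(inherits(set, "mid_set"))
  write.table(rbind(set$forward, set$reverse), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mid_set
#' @param constraints constraint list to attach on read (see [mid_set()]).
#' @export
read_mid_set <- function(path, constraints = list()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  mid_set(df[df$orientation == "forward", ],
          df[df$orientation == "reverse", ], constraints)
}
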