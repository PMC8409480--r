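# Shared fixtures (built once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fix_primers <- function() {
  list(fwd = "GTGYCAGCMGCCGCGGTAA",  # 515F
       rev = "GGACTACNVGGGTWTCTAAT") # 806R
}

fix_mids <- function() {
  fixture("mids", generate_mid_set(c("8" = 32, "9" = 32, "10" = 32),
                                   seed = 101))
}

fix_coligos <- function() {
  fixture("coligos", generate_coligo_identifiers(96, seed = 101))
}

fix_layout <- function() {
  fixture("layout", diagonal_layout(fix_mids()$forward$id,
                                    fix_mids()$reverse$id,
                                    fix_coligos()$id))
}

fix_demux_config <- function(...) {
  demux_config(fix_mids(), fix_primers(), fix_layout(), ...)
}

# Independent full-matrix Levenshtein DP, written before (and apart from)
# the compiled implementation; used only as an oracle.
oracle_lev <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  D <- matrix(0L, la + 1, lb + 1)
  D[, 1] <- 0:la; D[1, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb))
    D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                           D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  D[la + 1, lb + 1]
}

# Naive set-based detectability enumeration (the oracle for the bitmask
# implementation): mixtures is a list of integer vectors.
oracle_detectability <- function(mixtures, n_donors = 1) {
  n <- length(mixtures)
  total <- 0L; detected <- 0L
  donor_sets <- if (n_donors == 1) lapply(seq_len(n), identity) else
    combn(n, 2, simplify = FALSE)
  for (r in seq_len(n)) {
    cand <- Filter(function(ds) !r %in% ds, donor_sets)
    for (ds in cand) {
      total <- total + 1L
      F_obs <- setdiff(sort(unique(unlist(mixtures[ds]))), mixtures[[r]])
      if (length(F_obs) == 0L) next
      reproducing <- sum(vapply(cand, function(ds2)
        identical(setdiff(sort(unique(unlist(mixtures[ds2]))),
                          mixtures[[r]]), F_obs), logical(1)))
      if (reproducing == 1L) detected <- detected + 1L
    }
  }
  detected / total
}

# IUPAC complement oracle: explicit lookup table, no string tricks.
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
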