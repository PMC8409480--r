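#' Mixture schemes: k-of-n tracer panels
#'
#' An alternative tracer design combines k oligos from a small panel into a
#' per-well mixture (the classic case: 3 of 12, giving choose(12, 3) = 220
#' distinct mixtures). Contamination shows up as "foreign" oligos in a
#' well; an event is unambiguously attributable only when exactly one
#' candidate donor (set) could have produced the observed foreign oligos.
#' `mixture_detectability()` quantifies that fraction exhaustively.
#'
#' @param panel_size number of oligos in the panel.
#' @param mixture_size oligos per mixture (k).
#' @return `enumerate_mixtures`: object of class `mixture_scheme` holding
#'   all k-subsets in lexicographic order (`mixtures` is an n x k integer
#'   matrix of 1-based panel indices).
#' @examples
#' sch <- enumerate_mixtures(12, 3)
#' nrow(sch$mixtures)  # 220
#' @export
enumerate_mixtures <- function(panel_size, mixture_size) {
  if (mixture_size <= 0 || mixture_size > panel_size)
    stop("need 0 < mixture_size <= panel_size")
  m <- t(combn(seq_len(panel_size), mixture_size))
  structure(list(panel_size = as.integer(panel_size),
                 mixture_size = as.integer(mixture_size),
                 mixtures = m, well_assignment = NULL),
            class = "mixture_scheme")
}

#' Build a mixture scheme from an explicit subset list
#'
#' @param mixtures list of integer vectors (1-based panel indices) or an
#'   n x k matrix.
#' @param panel_size size of the oligo panel.
#' @return a `mixture_scheme`.
#' @export
mixture_scheme <- function(mixtures, panel_size) {
  if (is.matrix(mixtures)) mixtures <- lapply(seq_len(nrow(mixtures)),
                                              function(i) mixtures[i, ])
  k <- unique(lengths(mixtures))
  if (length(k) != 1L) stop("all mixtures must have the same size")
  m <- t(vapply(mixtures, function(v) sort(as.integer(v)), integer(k)))
  if (any(m < 1L | m > panel_size)) stop("panel indices out of range")
  if (any(apply(m, 1, anyDuplicated) > 0))
    stop("mixtures must not repeat an oligo")
  structure(list(panel_size = as.integer(panel_size), mixture_size = k,
                 mixtures = m, well_assignment = NULL),
            class = "mixture_scheme")
}

#' @export
print.mixture_scheme <- function(x, ...) {
  cat(sprintf("mixture_scheme: %d mixtures of %d from a panel of %d\n",
              nrow(x$mixtures), x$mixture_size, x$panel_size))
  if (!is.null(x$well_assignment))
    cat(sprintf("  assigned to %d wells\n", length(x$well_assignment)))
  invisible(x)
}

scheme_masks <- function(scheme) {
  apply(scheme$mixtures, 1, function(v) sum(bitwShiftL(1L, v - 1L)))
}

#' Arrange mixtures on a plate so neighbours differ as much as possible
#'
#' Greedy placement in row-major well order: each well receives the unused
#' mixture maximizing the minimum symmetric-difference size to the already
#' placed orthogonal neighbours (ties broken by a seeded random draw).
#'
#' @param scheme a `mixture_scheme`.
#' @param n_rows,n_cols plate geometry.
#' @param seed integer seed for tie-breaking.
#' @return the scheme with `well_assignment`: named integer vector mapping
#'   well label to a row of `mixtures`.
#' @export
assign_mixtures_to_plate <- function(scheme, n_rows = 8L, n_cols = 12L,
                                     seed = 1L) {
  stopifnot(inherits(scheme, "mixture_scheme"))
  n_wells <- n_rows * n_cols
  nmix <- nrow(scheme$mixtures)
  if (nmix < n_wells)
    stop("scheme has ", nmix, " mixtures but the plate has ", n_wells,
         " wells")
  set.seed(seed)
  masks <- scheme_masks(scheme)
  popcount <- function(x) {
    n <- integer(length(x))
    while (any(x > 0L)) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
    n
  }
  grid <- expand.grid(col = 0:(n_cols - 1L), row = 0:(n_rows - 1L))
  placed <- integer(n_wells)  # mixture index per well position
  for (w in seq_len(n_wells)) {
    r <- grid$row[w]; cc <- grid$col[w]
    nb <- which((abs(grid$row - r) + abs(grid$col - cc)) == 1L &
                  seq_len(n_wells) < w)
    free <- setdiff(seq_len(nmix), placed[seq_len(w - 1L)])
    if (length(nb) == 0L) {
      placed[w] <- free[sample.int(length(free), 1L)]
      next
    }
    nb_masks <- masks[placed[nb]]
    score <- vapply(free, function(mi)
      min(popcount(bitwXor(masks[mi], nb_masks))), numeric(1))
    best <- free[score == max(score)]
    placed[w] <- best[sample.int(length(best), 1L)]
  }
  scheme$well_assignment <- setNames(placed,
                                     label_from_well(grid$row, grid$col))
  scheme
}

#' Fraction of contamination events that are unambiguously attributable
#'
#' Exhaustive enumeration over all ordered (donor set, recipient) choices
#' among the scheme's mixtures (restricted to plate-assigned mixtures when
#' a well assignment is present). The observable is the foreign oligo set
#' F = union(donors) \ recipient; an event is unambiguously detected when
#' exactly one candidate donor set of the stated size reproduces F. Events
#' with F empty (donors hidden inside the recipient's own mixture) are
#' undetectable by construction.
#'
#' @param scheme a `mixture_scheme`.
#' @param n_donors 1 (single-donor events) or 2 (pairwise-combined donors).
#' @return fraction in `[0, 1]` of events unambiguously detected.
#' @export
mixture_detectability <- function(scheme, n_donors = 1L) {
  stopifnot(inherits(scheme, "mixture_scheme"))
  if (!n_donors %in% c(1L, 2L))
    stop("n_donors must be 1 or 2")
  masks <- scheme_masks(scheme)
  if (!is.null(scheme$well_assignment))
    masks <- masks[unique(scheme$well_assignment)]
  n <- length(masks)
  if (n < 2L) stop("need at least 2 mixtures")
  detected <- 0L; total <- 0L
  if (n_donors == 1L) {
    for (r in seq_len(n)) {
      Fs <- bitwAnd(masks, bitwNot(masks[r]))  # F for every candidate donor
      tab <- table(Fs)
      donors <- setdiff(seq_len(n), r)
      f <- Fs[donors]
      detected <- detected + sum(f != 0L & tab[as.character(f)] == 1L)
      total <- total + length(donors)
    }
  } else {
    for (r in seq_len(n)) {
      cand <- setdiff(seq_len(n), r)
      pr <- combn(cand, 2L)
      Fs <- bitwAnd(bitwOr(masks[pr[1, ]], masks[pr[2, ]]),
                    bitwNot(masks[r]))
      tab <- table(Fs)
      detected <- detected + sum(Fs != 0L & tab[as.character(Fs)] == 1L)
      total <- total + length(Fs)
    }
  }
  detected / total
}
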