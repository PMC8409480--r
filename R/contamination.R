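#' Well-by-coligo count matrices
#'
#' The central object of contamination diagnostics: read counts of every
#' coligo identifier in every well, plus each well's total read count (all
#' reads, not only coligo reads).
#'
#' @param counts integer matrix, wells (rows, labelled) x coligo ids
#'   (columns, named).
#' @param total_reads named vector of per-well total reads; defaults to the
#'   per-well coligo totals.
#' @return object of class `coligo_count_matrix`.
#' @export
coligo_count_matrix <- function(counts, total_reads = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have well row names and coligo column names")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(total_reads)) total_reads <- rowSums(counts)
  total_reads <- total_reads[rownames(counts)]
  if (any(is.na(total_reads)))
    stop("total_reads missing for some wells")
  if (any(rowSums(counts) > total_reads + 1e-9))
    stop("per-well coligo total exceeds per-well total reads")
  structure(list(counts = counts, total_reads = total_reads,
                 wells = rownames(counts), coligo_ids = colnames(counts)),
            class = "coligo_count_matrix")
}

#' @export
print.coligo_count_matrix <- function(x, ...) {
  cat(sprintf("coligo_count_matrix: %d wells x %d coligos, %d coligo reads\n",
              length(x$wells), length(x$coligo_ids), sum(x$counts)))
  invisible(x)
}

#' Extract coligo identities from primer-trimmed forward reads
#'
#' Takes the bases immediately following the (already removed) forward
#' primer: an exact match of the leading `id_length`-mer is preferred;
#' otherwise the unique identifier within `max_edits` Levenshtein edits of
#' the leading window (which flexes one base either way to absorb single
#' indels) is accepted; anything else returns `NA`.
#'
#' @param seqs character vector of forward reads with MID+primer trimmed.
#' @param identifiers data.frame (`id`, `sequence`) or named character
#'   vector of coligo identifiers.
#' @param id_length identifier length (default 13).
#' @param max_edits tolerance; 0 forces exact-only matching.
#' @return character vector of coligo ids (`NA` where unmatched).
#' @export
extract_coligo_id <- function(seqs, identifiers, id_length = 13L,
                              max_edits = 1L) {
  if (is.data.frame(identifiers))
    identifiers <- setNames(identifiers$sequence, identifiers$id)
  idx <- cpp_coligo_match(toupper(seqs), toupper(unname(identifiers)),
                          as.integer(id_length), as.integer(max_edits))
  out <- rep(NA_character_, length(idx))
  out[idx > 0L] <- names(identifiers)[idx[idx > 0L]]
  out
}

#' Count coligo reads per well
#'
#' @param reads data.frame with columns `well` and `seq` (primer-trimmed
#'   forward reads, e.g. the assigned rows of a [demultiplex_run()]
#'   result), or a named list well -> character vector of reads.
#' @param identifiers coligo identifier table (see [extract_coligo_id()]).
#' @param layout a [plate_layout()]; every observed well must be on it.
#' @param id_length,max_edits matching parameters.
#' @return a [coligo_count_matrix()] over all layout wells (rows) and all
#'   identifiers (columns); per-well totals are the numbers of reads
#'   supplied, matched or not.
#' @export
count_coligos <- function(reads, identifiers, layout, id_length = 13L,
                          max_edits = 1L) {
  stopifnot(inherits(layout, "plate_layout"))
  if (is.list(reads) && !is.data.frame(reads))
    reads <- data.frame(well = rep(names(reads), lengths(reads)),
                        seq = unlist(reads, use.names = FALSE),
                        stringsAsFactors = FALSE)
  if (is.data.frame(identifiers))
    ids <- setNames(identifiers$sequence, identifiers$id)
  else ids <- identifiers
  wells <- layout$assignments$well
  unknown <- setdiff(unique(reads$well), wells)
  if (length(unknown))
    stop("well(s) absent from layout: ", paste(unknown, collapse = ", "))
  counts <- matrix(0L, nrow = length(wells), ncol = length(ids),
                   dimnames = list(wells, names(ids)))
  total <- setNames(integer(length(wells)), wells)
  if (nrow(reads)) {
    hit <- extract_coligo_id(reads$seq, ids, id_length, max_edits)
    tt <- table(reads$well)
    total[names(tt)] <- as.integer(tt)
    ok <- !is.na(hit)
    if (any(ok)) {
      tab <- table(reads$well[ok], hit[ok])
      counts[rownames(tab), colnames(tab)] <-
        counts[rownames(tab), colnames(tab)] + as.matrix(tab)
    }
  }
  coligo_count_matrix(counts, total)
}

#' Extract the coligo count matrix from a demultiplexing result
#'
#' Forward reads only, as recommended for short tracer inserts that do not
#' merge reliably across mates.
#'
#' @param res a `demux_result`.
#' @param identifiers coligo identifier table.
#' @param layout a [plate_layout()].
#' @param ... passed to [count_coligos()].
#' @return a [coligo_count_matrix()].
#' @export
count_coligos_from_demux <- function(res, identifiers, layout, ...) {
  asn <- res$assignments
  ok <- asn[asn$reason == "assigned", ]
  count_coligos(data.frame(well = ok$well, seq = ok$r1_seq,
                           stringsAsFactors = FALSE),
                identifiers, layout, ...)
}

layout_expected_coligo <- function(layout) {
  a <- layout$assignments
  setNames(a$expected_coligo_id, a$well)
}

#' Per-well and plate-level cross-contamination metrics
#'
#' For each well: reads of the expected coligo, foreign-coligo reads, the
#' proportion of the well's coligo reads that are the expected one, the
#' number of distinct foreign coligos observed at or above
#' `min_foreign_reads`, and coligo reads as a fraction of all reads.
#' Plate summary: fraction of wells with any foreign coligo, fraction with
#' more than one distinct foreign coligo, the median foreign proportion
#' (over wells with at least one coligo read), and the overall proportion
#' of coligo reads that are out of place. Wells with zero coligo reads are
#' excluded from proportion medians and tallied separately.
#'
#' @param mat a [coligo_count_matrix()].
#' @param layout a [plate_layout()]; every matrix well needs a nonempty
#'   `expected_coligo_id`.
#' @param min_foreign_reads reads required before a foreign coligo counts
#'   as evidence of contamination (default 1).
#' @return object of class `contamination_report`: `per_well` data.frame
#'   and `summary` list.
#' @export
contamination_report <- function(mat, layout, min_foreign_reads = 1L) {
  stopifnot(inherits(mat, "coligo_count_matrix"),
            inherits(layout, "plate_layout"))
  expected <- layout_expected_coligo(layout)[mat$wells]
  if (any(is.na(expected) | expected == ""))
    stop("well(s) without an expected coligo in the layout: ",
         paste(mat$wells[is.na(expected) | expected == ""], collapse = ", "))
  miss <- setdiff(unique(expected), mat$coligo_ids)
  if (length(miss))
    stop("expected coligo(s) absent from the matrix: ",
         paste(miss, collapse = ", "))
  cnt <- mat$counts
  exp_reads <- cnt[cbind(seq_along(mat$wells), match(expected,
                                                     mat$coligo_ids))]
  coligo_total <- rowSums(cnt)
  foreign <- coligo_total - exp_reads
  foreign_mat <- cnt
  foreign_mat[cbind(seq_along(mat$wells), match(expected,
                                                mat$coligo_ids))] <- 0L
  n_distinct_foreign <- rowSums(foreign_mat >= min_foreign_reads)
  prop_expected <- ifelse(coligo_total > 0, exp_reads / coligo_total, NA)
  per_well <- data.frame(
    well = mat$wells, expected_coligo = unname(expected),
    expected_coligo_reads = unname(exp_reads),
    foreign_coligo_reads = unname(foreign),
    coligo_total = unname(coligo_total),
    proportion_expected = unname(prop_expected),
    n_distinct_foreign = unname(n_distinct_foreign),
    coligo_fraction_of_reads = unname(
      ifelse(mat$total_reads > 0, coligo_total / mat$total_reads, 0)),
    stringsAsFactors = FALSE)
  observed <- coligo_total > 0
  summary <- list(
    n_wells = length(mat$wells),
    n_wells_no_coligo = sum(!observed),
    frac_wells_with_any_foreign = mean(foreign >= min_foreign_reads),
    frac_wells_with_multiple_foreign = mean(n_distinct_foreign >= 2L),
    median_foreign_proportion =
      if (any(observed)) median(1 - prop_expected[observed]) else NA_real_,
    overall_out_of_place_proportion =
      if (sum(coligo_total) > 0) sum(foreign) / sum(coligo_total) else NA_real_,
    min_foreign_reads = min_foreign_reads)
  structure(list(per_well = per_well, summary = summary),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  s <- x$summary
  cat("contamination_report\n")
  cat(sprintf("  wells: %d (%d with no coligo reads)\n", s$n_wells,
              s$n_wells_no_coligo))
  cat(sprintf("  wells with any foreign coligo (>=%d reads): %.1f%%\n",
              s$min_foreign_reads, 100 * s$frac_wells_with_any_foreign))
  cat(sprintf("  wells with multiple foreign coligos: %.1f%%\n",
              100 * s$frac_wells_with_multiple_foreign))
  cat(sprintf("  median foreign proportion: %.4g\n",
              s$median_foreign_proportion))
  cat(sprintf("  coligo reads out of place overall: %.4g%%\n",
              100 * s$overall_out_of_place_proportion))
  invisible(x)
}

#' Spatial profile of contamination events
#'
#' Each (recipient well, foreign coligo) pair with at least
#' `min_foreign_reads` reads is one event, binned by the Euclidean
#' distance between the foreign coligo's home well and the recipient
#' (rounded half away from zero by default). A well containing several
#' foreign coligos contributes several events. Foreign coligos with no
#' home well on the layout are binned as `"external"`.
#'
#' @inheritParams contamination_report
#' @param rounded round distances to integers.
#' @return object of class `contamination_profile`: data.frame `events`
#'   (recipient, coligo, home, distance, reads) and `histogram`
#'   (distance, count).
#' @export
contamination_distance_profile <- function(mat, layout,
                                           min_foreign_reads = 1L,
                                           rounded = TRUE) {
  stopifnot(inherits(mat, "coligo_count_matrix"),
            inherits(layout, "plate_layout"))
  expected <- layout_expected_coligo(layout)[mat$wells]
  home <- setNames(names(layout_expected_coligo(layout)),
                   layout_expected_coligo(layout))
  home <- home[nzchar(names(home))]
  cnt <- mat$counts
  cnt[cbind(seq_along(mat$wells),
            match(expected, mat$coligo_ids))] <- 0L
  idx <- which(cnt >= min_foreign_reads, arr.ind = TRUE)
  events <- data.frame(
    recipient = mat$wells[idx[, 1]],
    coligo = mat$coligo_ids[idx[, 2]],
    reads = cnt[idx], stringsAsFactors = FALSE)
  events$home <- unname(home[events$coligo])
  events$distance <- rep(NA_real_, nrow(events))
  known <- !is.na(events$home)
  if (any(known))
    events$distance[known] <- well_distance(
      events$home[known], events$recipient[known], rounded = rounded,
      n_rows = layout$n_rows, n_cols = layout$n_cols)
  hist <- if (any(known)) {
    tt <- table(events$distance[known])
    data.frame(distance = as.numeric(names(tt)), count = as.integer(tt))
  } else data.frame(distance = numeric(), count = integer())
  structure(list(events = events, histogram = hist,
                 n_external = sum(!known)),
            class = "contamination_profile")
}

#' @export
print.contamination_profile <- function(x, ...) {
  cat(sprintf("contamination_profile: %d event(s), %d from outside the plate\n",
              nrow(x$events), x$n_external))
  if (nrow(x$histogram)) print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' @export
plot.contamination_profile <- function(x, ...) {
  if (!nrow(x$histogram)) {
    plot.new(); title("no contamination events"); return(invisible(x))
  }
  graphics::barplot(setNames(x$histogram$count,
                             x$histogram$distance),
                    xlab = "rounded Euclidean distance (well pitch)",
                    ylab = "contamination events", ...)
  invisible(x)
}

#' Estimate per-event migration fractions
#'
#' For every foreign-coligo event, the migrated fraction of the donor pool
#' is estimated as the ratio of the foreign coligo's read fraction in the
#' recipient to the same coligo's read fraction in its home (donor) well;
#' read depth differences between the two wells cancel out.
#'
#' @inheritParams contamination_distance_profile
#' @return the [contamination_distance_profile()] events data.frame with
#'   extra columns `reads_home`, `migration_fraction_hat` (`NA` when the
#'   donor has no reads of its own coligo).
#' @export
estimate_event_fractions <- function(mat, layout, min_foreign_reads = 1L) {
  prof <- contamination_distance_profile(mat, layout, min_foreign_reads,
                                         rounded = FALSE)
  ev <- prof$events
  ev <- ev[!is.na(ev$home), , drop = FALSE]
  if (!nrow(ev)) {
    ev$reads_home <- numeric(0); ev$migration_fraction_hat <- numeric(0)
    return(ev)
  }
  ev$reads_home <- mat$counts[cbind(match(ev$home, mat$wells),
                                    match(ev$coligo, mat$coligo_ids))]
  f_rec <- ev$reads / mat$total_reads[ev$recipient]
  f_home <- ev$reads_home / mat$total_reads[ev$home]
  ev$migration_fraction_hat <- ifelse(f_home > 0, f_rec / f_home, NA_real_)
  ev
}

#' Check whether a plate was read in a 180-degree-rotated orientation
#'
#' Compares the read-weighted fraction of coligo reads matching each
#' well's expected coligo under the as-given layout (`score_0`) and under
#' the 180-degree-rotated layout (`score_180`); the better-scoring
#' orientation wins. An exact tie keeps the as-given orientation with a
#' warning recorded.
#'
#' @inheritParams contamination_report
#' @return list with `orientation` ("0" or "180"), `score_0`, `score_180`,
#'   `flagged` (TRUE when the rotated layout fits better), `warning`.
#' @export
detect_plate_rotation <- function(mat, layout) {
  stopifnot(inherits(mat, "coligo_count_matrix"),
            inherits(layout, "plate_layout"))
  total <- sum(mat$counts)
  if (total == 0) stop("rotation undeterminable: zero coligo reads")
  score <- function(l) {
    expected <- layout_expected_coligo(l)[mat$wells]
    j <- match(expected, mat$coligo_ids)
    ok <- !is.na(j) & !is.na(expected) & nzchar(expected)
    sum(mat$counts[cbind(which(ok), j[ok])]) / total
  }
  s0 <- score(layout)
  s180 <- score(rotate_layout(layout))
  tie <- isTRUE(all.equal(s0, s180))
  list(orientation = if (!tie && s180 > s0) "180" else "0",
       score_0 = s0, score_180 = s180,
       flagged = !tie && s180 > s0,
       warning = if (tie) "orientation scores tied; assuming 0 degrees"
                 else NULL)
}

#' Per-sample spike-in read fractions
#'
#' Fractions of each sample's reads attributed to coligo features and to
#' the ISD, with frequency histograms on a log10 axis (samples with zero
#' spike-in reads are excluded from the histograms).
#'
#' @param table a [feature_table()] whose coligo/ISD features are flagged.
#' @return list with `per_sample` data.frame (`sample_id`,
#'   `coligo_fraction`, `isd_fraction`) and `coligo_hist`, `isd_hist`
#'   (objects from [graphics::hist()], not plotted).
#' @export
spikein_fraction_summary <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cnt <- table$counts
  tot <- rowSums(cnt)
  cfrac <- if (length(table$coligo_features))
    rowSums(cnt[, table$coligo_features, drop = FALSE]) / pmax(tot, 1)
  else rep(0, nrow(cnt))
  ifrac <- if (length(table$isd_features))
    rowSums(cnt[, table$isd_features, drop = FALSE]) / pmax(tot, 1)
  else rep(0, nrow(cnt))
  mk_hist <- function(f) if (any(f > 0))
    graphics::hist(log10(f[f > 0]), plot = FALSE) else NULL
  list(per_sample = data.frame(sample_id = rownames(cnt),
                               coligo_fraction = unname(cfrac),
                               isd_fraction = unname(ifrac),
                               stringsAsFactors = FALSE),
       coligo_hist = mk_hist(cfrac), isd_hist = mk_hist(ifrac))
}

#' Read / write coligo count matrices as TSV
#'
#' Wells as rows (first column `well`), coligo ids as columns, plus a
#' final `total_reads` column.
#'
#' @param mat a [coligo_count_matrix()]; `path` a file path.
#' @export
write_coligo_counts <- function(mat, path) {
  df <- data.frame(well = mat$wells, mat$counts,
                   total_reads = mat$total_reads, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_coligo_counts
#' @return `read_coligo_counts`: a [coligo_count_matrix()].
#' @export
read_coligo_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  wells <- df$well
  total <- setNames(df$total_reads, wells)
  cnt <- as.matrix(df[, setdiff(names(df), c("well", "total_reads")),
                      drop = FALSE])
  rownames(cnt) <- wells
  coligo_count_matrix(cnt, total)
}
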