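#' Demultiplexing configuration
#'
#' Binds a MID set, locus primer pairs, and a plate layout into the
#' matching policy used by [demultiplex_run()]. The MID error tolerance
#' must stay below the set's minimum same-length distance so that accepted
#' corrections are provably unique.
#'
#' @param mid_set a [mid_set()].
#' @param primers named list, locus -> `list(fwd = , rev = )` (IUPAC codes
#'   allowed); a single unnamed pair is given locus name `"locus1"`.
#' @param layout a [plate_layout()] mapping (forward, reverse) MID pairs to
#'   samples.
#' @param max_mid_edits maximum Levenshtein edits tolerated in a MID
#'   (default 1).
#' @param max_primer_mismatches maximum primer mismatches, substitutions
#'   only (default 2).
#' @return object of class `demux_config`.
#' @export
demux_config <- function(mid_set, primers, layout, max_mid_edits = 1L,
                         max_primer_mismatches = 2L) {
  stopifnot(inherits(mid_set, "mid_set"), inherits(layout, "plate_layout"))
  if (!is.list(primers[[1]])) primers <- list(locus1 = primers)
  if (is.null(names(primers)))
    names(primers) <- paste0("locus", seq_along(primers))
  for (p in primers) {
    stopifnot(all(c("fwd", "rev") %in% names(p)))
    assert_dna(p$fwd, "fwd primer", allow_iupac = TRUE)
    assert_dna(p$rev, "rev primer", allow_iupac = TRUE)
  }
  if (max_mid_edits >= mid_set$constraints$min_same_length_distance)
    stop("max_mid_edits (", max_mid_edits,
         ") must be below the MID set's minimum same-length distance (",
         mid_set$constraints$min_same_length_distance, ")")
  a <- layout$assignments
  used <- a$role != "empty"
  known <- setNames(a$sample_id[used],
                    paste(a$fwd_mid_id[used], a$rev_mid_id[used], sep = "\r"))
  wells <- setNames(a$well[used],
                    paste(a$fwd_mid_id[used], a$rev_mid_id[used], sep = "\r"))
  structure(list(mid_set = mid_set, primers = primers, layout = layout,
                 max_mid_edits = as.integer(max_mid_edits),
                 max_primer_mismatches = as.integer(max_primer_mismatches),
                 pair_to_sample = known, pair_to_well = wells),
            class = "demux_config")
}

REASON_CODES <- c("assigned", "no_mid", "ambiguous_mid", "no_primer")

#' Match a variable-length MID plus anchored primer at the start of reads
#'
#' Candidate MID lengths are tried longest first; at each length the
#' leading window is scored against all candidates of that length (edit
#' distance) and the primer against the bases that follow (IUPAC-aware,
#' substitutions only). The unique candidate minimizing
#' (MID edits, primer mismatches) within tolerance is accepted; a tie is
#' reported as `ambiguous_mid`, a read with no MID in reach as `no_mid`,
#' and a read whose MID matches but whose primer does not as `no_primer`.
#'
#' @param seqs character vector of read sequences.
#' @param mids data.frame with `id`, `sequence` (one orientation of a
#'   [mid_set()]), or a named character vector.
#' @param primer primer expected right after the MID (IUPAC allowed).
#' @param max_mid_edits,max_primer_mismatches tolerances.
#' @return data.frame with columns `mid_id` (NA when unassigned),
#'   `consumed` (bases of MID+primer to trim), `mid_edits`, `primer_mm`,
#'   `reason`.
#' @export
match_prefix <- function(seqs, mids, primer, max_mid_edits = 1L,
                         max_primer_mismatches = 2L) {
  if (is.data.frame(mids)) mids <- setNames(mids$sequence, mids$id)
  m <- cpp_match_prefix(toupper(seqs), toupper(unname(mids)),
                        toupper(primer), max_mid_edits,
                        max_primer_mismatches)
  mid_id <- rep(NA_character_, nrow(m))
  mid_id[m$idx > 0L] <- names(mids)[m$idx[m$idx > 0L]]
  data.frame(mid_id = mid_id,
             consumed = m$consumed, mid_edits = m$mid_edits,
             primer_mm = m$primer_mm, reason = REASON_CODES[m$reason + 1L],
             stringsAsFactors = FALSE)
}

#' Demultiplex read pairs held in memory
#'
#' Vectorized core of [demultiplex_run()]: forward MID+primer matching on
#' R1, reverse matching on R2, locus agreement between mates, sample lookup
#' from the layout's dual-index pairs, and trimming of the technical
#' prefix (MID + primer) from sequence and quality alike.
#'
#' @param r1,r2 data.frames with `id`, `sequence`, `quality`.
#' @param config a [demux_config()].
#' @return data.frame, one row per pair: `read_id`, `sample_id`, `well`,
#'   `locus`, `fwd_mid_id`, `rev_mid_id`, `fwd_mid_edits`, `rev_mid_edits`,
#'   `reason` ("assigned" or an unassigned-reason code), and trimmed
#'   `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @export
demultiplex_reads <- function(r1, r2, config) {
  stopifnot(inherits(config, "demux_config"), nrow(r1) == nrow(r2))
  n <- nrow(r1)
  if (n == 0L)
    return(data.frame(read_id = character(), sample_id = character(),
                      well = character(), locus = character(),
                      fwd_mid_id = character(), rev_mid_id = character(),
                      fwd_mid_edits = integer(), rev_mid_edits = integer(),
                      reason = character(), r1_seq = character(),
                      r1_qual = character(), r2_seq = character(),
                      r2_qual = character(), stringsAsFactors = FALSE))
  loci <- names(config$primers)
  fm <- lapply(loci, function(l)
    match_prefix(r1$sequence, config$mid_set$forward,
                 config$primers[[l]]$fwd, config$max_mid_edits,
                 config$max_primer_mismatches))
  rm_ <- lapply(loci, function(l)
    match_prefix(r2$sequence, config$mid_set$reverse,
                 config$primers[[l]]$rev, config$max_mid_edits,
                 config$max_primer_mismatches))
  names(fm) <- names(rm_) <- loci

  locus <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  fwd_id <- rev_id <- rep(NA_character_, n)
  fwd_ed <- rev_ed <- integer(n)
  cons1 <- cons2 <- integer(n)

  fok <- vapply(loci, function(l) fm[[l]]$reason == "assigned",
                logical(n)) |> matrix(nrow = n)
  rok <- vapply(loci, function(l) rm_[[l]]$reason == "assigned",
                logical(n)) |> matrix(nrow = n)
  joint <- fok & rok
  has_joint <- rowSums(joint) > 0L
  first_joint <- apply(joint, 1, function(z) which(z)[1])
  for (li in seq_along(loci)) {
    sel <- has_joint & first_joint == li
    if (!any(sel)) next
    l <- loci[li]
    locus[sel] <- l
    reason[sel] <- "assigned"
    fwd_id[sel] <- fm[[l]]$mid_id[sel]; rev_id[sel] <- rm_[[l]]$mid_id[sel]
    fwd_ed[sel] <- fm[[l]]$mid_edits[sel]; rev_ed[sel] <- rm_[[l]]$mid_edits[sel]
    cons1[sel] <- fm[[l]]$consumed[sel]; cons2[sel] <- rm_[[l]]$consumed[sel]
  }
  conflict <- !has_joint & rowSums(fok) > 0L & rowSums(rok) > 0L
  reason[conflict] <- "locus_conflict"
  rest <- !has_joint & !conflict
  # report the blocking mate's reason from the first locus
  r1_reason <- fm[[1]]$reason; r2_reason <- rm_[[1]]$reason
  f_bad <- rest & rowSums(fok) == 0L
  reason[f_bad] <- paste0("fwd_", r1_reason[f_bad])
  r_bad <- rest & !f_bad
  reason[r_bad] <- paste0("rev_", r2_reason[r_bad])

  key <- paste(fwd_id, rev_id, sep = "\r")
  sample_id <- unname(config$pair_to_sample[key])
  well <- unname(config$pair_to_well[key])
  unknown <- reason == "assigned" & is.na(sample_id)
  reason[unknown] <- "unknown_pairing"
  sample_id[reason != "assigned"] <- NA_character_
  well[reason != "assigned"] <- NA_character_
  keep <- reason == "assigned"
  out <- data.frame(
    read_id = r1$id, sample_id = sample_id, well = well, locus = locus,
    fwd_mid_id = fwd_id, rev_mid_id = rev_id,
    fwd_mid_edits = ifelse(keep, fwd_ed, NA_integer_),
    rev_mid_edits = ifelse(keep, rev_ed, NA_integer_),
    reason = reason,
    r1_seq = ifelse(keep, substring(r1$sequence, cons1 + 1L), r1$sequence),
    r1_qual = ifelse(keep, substring(r1$quality, cons1 + 1L), r1$quality),
    r2_seq = ifelse(keep, substring(r2$sequence, cons2 + 1L), r2$sequence),
    r2_qual = ifelse(keep, substring(r2$quality, cons2 + 1L), r2$quality),
    stringsAsFactors = FALSE)
  out
}

#' Demultiplex a single read pair
#'
#' @param pair list with `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`,
#'   `read_id`.
#' @param config a [demux_config()].
#' @return one-row assignment record (see [demultiplex_reads()]).
#' @export
demultiplex_pair <- function(pair, config) {
  stopifnot(nchar(pair$r1_seq) == nchar(pair$r1_qual),
            nchar(pair$r2_seq) == nchar(pair$r2_qual))
  r1 <- data.frame(id = pair$read_id %||% "read1", sequence = pair$r1_seq,
                   quality = pair$r1_qual, stringsAsFactors = FALSE)
  r2 <- data.frame(id = pair$read_id %||% "read1", sequence = pair$r2_seq,
                   quality = pair$r2_qual, stringsAsFactors = FALSE)
  demultiplex_reads(r1, r2, config)
}

#' Demultiplex paired FASTQ files
#'
#' Streams both mates (which must agree in count and order of read ids),
#' assigns each pair to a well via its inline dual index, and, when
#' `out_dir` is given, writes per-sample paired FASTQ files, a pair of
#' "undetermined" files with the unassignment reason in the header
#' comment, and TSV run statistics.
#'
#' @param r1_path,r2_path FASTQ(.gz) mate files.
#' @param config a [demux_config()].
#' @param out_dir output directory (created); `NULL` keeps results in
#'   memory only.
#' @param gz gzip per-sample output files.
#' @return object of class `demux_result`: `assignments` (per-read table),
#'   `stats` (per sample x locus: `n_reads`, `n_fwd_mid_corrected`,
#'   `n_rev_mid_corrected`), `reason_counts`, `n_input`.
#' @export
demultiplex_run <- function(r1_path, r2_path, config, out_dir = NULL,
                            gz = TRUE) {
  pr <- read_fastq_paired(r1_path, r2_path)
  asn <- demultiplex_reads(pr$r1, pr$r2, config)
  res <- demux_result(asn, nrow(pr$r1))
  if (!is.null(out_dir)) write_demux_result(res, out_dir, gz = gz)
  res
}

demux_result <- function(asn, n_input) {
  ok <- asn[asn$reason == "assigned", ]
  stats <- if (nrow(ok)) {
    agg <- aggregate(cbind(n_reads = rep(1L, nrow(ok)),
                           n_fwd_mid_corrected = ok$fwd_mid_edits > 0L,
                           n_rev_mid_corrected = ok$rev_mid_edits > 0L),
                     by = list(sample_id = ok$sample_id, locus = ok$locus),
                     FUN = sum)
    agg[order(agg$sample_id, agg$locus), ]
  } else data.frame(sample_id = character(), locus = character(),
                    n_reads = integer(), n_fwd_mid_corrected = integer(),
                    n_rev_mid_corrected = integer())
  reason_counts <- table(asn$reason)
  stopifnot(sum(reason_counts) == n_input)  # conservation
  structure(list(assignments = asn, stats = stats,
                 reason_counts = reason_counts, n_input = n_input),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  n_ok <- sum(x$assignments$reason == "assigned")
  cat(sprintf("demux_result: %d read pairs, %d assigned (%.2f%%)\n",
              x$n_input, n_ok, ifelse(x$n_input > 0,
                                      100 * n_ok / x$n_input, 0)))
  print(x$reason_counts)
  invisible(x)
}

write_demux_result <- function(res, out_dir, gz = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  asn <- res$assignments
  ext <- if (gz) ".fastq.gz" else ".fastq"
  ok <- asn[asn$reason == "assigned", ]
  for (s in unique(ok$sample_id)) {
    sub <- ok[ok$sample_id == s, ]
    write_fastq(data.frame(id = sub$read_id, sequence = sub$r1_seq,
                           quality = sub$r1_qual),
                file.path(out_dir, paste0(s, "_R1", ext)), gz = gz)
    write_fastq(data.frame(id = sub$read_id, sequence = sub$r2_seq,
                           quality = sub$r2_qual),
                file.path(out_dir, paste0(s, "_R2", ext)), gz = gz)
  }
  un <- asn[asn$reason != "assigned", ]
  if (nrow(un)) {
    ids <- paste(un$read_id, un$reason)
    write_fastq(data.frame(id = ids, sequence = un$r1_seq,
                           quality = un$r1_qual),
                file.path(out_dir, paste0("undetermined_R1", ext)), gz = gz)
    write_fastq(data.frame(id = ids, sequence = un$r2_seq,
                           quality = un$r2_qual),
                file.path(out_dir, paste0("undetermined_R2", ext)), gz = gz)
  }
  write_tsv(res$stats, file.path(out_dir, "demux_stats.tsv"))
  write_tsv(data.frame(reason = names(res$reason_counts),
                       n_reads = as.integer(res$reason_counts)),
            file.path(out_dir, "demux_reasons.tsv"))
  invisible(out_dir)
}
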