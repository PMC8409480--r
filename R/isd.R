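#' Feature tables (samples x features)
#'
#' A plain counts container for ESV/taxon tables with optional flags
#' marking which features are the internal standard (ISD) and which are
#' coligo tracers.
#'
#' @param counts numeric matrix, samples (rows, named) x features
#'   (columns, named), nonnegative.
#' @param isd_features,coligo_features character vectors of feature names.
#' @param sequences optional named character vector of feature sequences.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, isd_features = character(),
                          coligo_features = character(),
                          sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and feature column names")
  if (any(counts < 0)) stop("counts must be nonnegative")
  miss <- setdiff(c(isd_features, coligo_features), colnames(counts))
  if (length(miss))
    stop("flagged feature(s) absent from table: ",
         paste(miss, collapse = ", "))
  structure(list(counts = counts, isd_features = isd_features,
                 coligo_features = coligo_features, sequences = sequences),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%d ISD, %d coligo)\n",
              nrow(x$counts), ncol(x$counts), length(x$isd_features),
              length(x$coligo_features)))
  invisible(x)
}

#' Identify the ESVs that belong to the ISD
#'
#' Denoising typically splits a spike-in into several exact sequence
#' variants; all of them must be summed before computing the ISD
#' proportion. A feature is called ISD-derived when its global
#' (Needleman-Wunsch) alignment to the ISD reference reaches the identity
#' and coverage thresholds.
#'
#' @param feature_sequences named character vector (feature id ->
#'   sequence).
#' @param isd_sequence the ISD reference sequence.
#' @param min_identity minimum alignment identity (matches / alignment
#'   length; default 0.95).
#' @param min_coverage minimum feature-length / ISD-length ratio (default
#'   0.9).
#' @return character vector of matching feature ids.
#' @export
match_isd_esvs <- function(feature_sequences, isd_sequence,
                           min_identity = 0.95, min_coverage = 0.9) {
  if (is.null(isd_sequence) || !nzchar(isd_sequence))
    stop("ISD sequence is empty")
  if (length(feature_sequences) == 0L) return(character())
  assert_dna(feature_sequences, "feature sequence")
  assert_dna(isd_sequence, "ISD sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  identity <- vapply(feature_sequences, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(s)),
      Biostrings::DNAString(toupper(isd_sequence)), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
    Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  }, numeric(1))
  coverage <- pmin(nchar(feature_sequences), nchar(isd_sequence)) /
    nchar(isd_sequence)
  names(feature_sequences)[identity >= min_identity &
                             coverage >= min_coverage]
}

#' Collapse ISD-derived features into a single ISD feature
#'
#' The matched features are removed and replaced by one feature (named
#' `isd_name`) holding their per-sample sum; every other count is
#' untouched, so per-sample totals are conserved.
#'
#' @param table a [feature_table()].
#' @param isd_feature_ids feature ids to collapse (e.g. from
#'   [match_isd_esvs()]).
#' @param isd_name name of the collapsed feature (default "ISD").
#' @return a [feature_table()] with `isd_features = isd_name`.
#' @export
collapse_isd <- function(table, isd_feature_ids, isd_name = "ISD") {
  stopifnot(inherits(table, "feature_table"))
  cnt <- table$counts
  if (length(isd_feature_ids) == 0L) {
    warning("no ISD-matching features; adding a zero-count ISD feature")
    isd <- rep(0, nrow(cnt))
  } else {
    miss <- setdiff(isd_feature_ids, colnames(cnt))
    if (length(miss))
      stop("id(s) absent from table: ", paste(miss, collapse = ", "))
    isd <- rowSums(cnt[, isd_feature_ids, drop = FALSE])
  }
  keep <- setdiff(colnames(cnt), c(isd_feature_ids, isd_name))
  out <- cbind(cnt[, keep, drop = FALSE],
               matrix(isd, ncol = 1, dimnames = list(NULL, isd_name)))
  feature_table(out, isd_features = isd_name,
                coligo_features = intersect(table$coligo_features, keep),
                sequences = table$sequences)
}

#' Normalize a feature table by the internal standard
#'
#' Converts compositional counts to the consistent ISD scale: for each
#' sample, y_i = x_i / x_ISD, where x may be read counts or proportions
#' (the ratio is identical either way). Samples whose ISD count is zero
#' are flagged `no_isd` and left undefined rather than pseudocounted
#' (optionally, `pseudocount` adds its value to the ISD count only).
#' Coligo features are tracers, not standards, and are excluded from the
#' output.
#'
#' @param table a [feature_table()] with a single (collapsed) ISD feature.
#' @param pseudocount value added to zero ISD counts (default 0 = off).
#' @return object of class `isd_ratio_table`: `ratios` (samples x
#'   biological features) and `status` ("ok" or "no_isd" per sample).
#' @export
isd_normalize <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (length(table$isd_features) != 1L)
    stop("table must carry exactly one ISD feature; run collapse_isd() first")
  cnt <- table$counts
  isd <- cnt[, table$isd_features]
  if (pseudocount > 0) isd[isd == 0] <- pseudocount
  status <- setNames(ifelse(isd > 0, "ok", "no_isd"), rownames(cnt))
  bio <- setdiff(colnames(cnt), c(table$isd_features,
                                  table$coligo_features))
  ratios <- cnt[, bio, drop = FALSE] / isd
  ratios[status == "no_isd", ] <- NA_real_
  structure(list(ratios = ratios, status = status,
                 isd_feature = table$isd_features),
            class = "isd_ratio_table")
}

#' @export
print.isd_ratio_table <- function(x, ...) {
  cat(sprintf("isd_ratio_table: %d samples x %d features (%d without ISD)\n",
              nrow(x$ratios), ncol(x$ratios), sum(x$status == "no_isd")))
  invisible(x)
}

#' Spike designs: the known per-sample ISD amounts
#'
#' @param sample_id,isd_amount vectors of equal length (amounts
#'   nonnegative, in a single stated unit).
#' @param unit unit label, e.g. "copies" or "pg".
#' @return object of class `spike_design`.
#' @export
spike_design <- function(sample_id, isd_amount, unit = "copies") {
  if (any(isd_amount < 0)) stop("isd_amount must be nonnegative")
  structure(list(amounts = setNames(as.numeric(isd_amount),
                                    as.character(sample_id)),
                 unit = unit), class = "spike_design")
}

#' Estimate absolute abundances from ISD ratios
#'
#' Within-taxon, across-sample rescaling: estimate_i = y_i times the known
#' ISD amount of the sample, in the spike's unit. (Between-taxon
#' comparisons remain confounded by copy-number and amplification-
#' efficiency differences and are deliberately not offered.)
#'
#' @param ratios an [isd_normalize()] result.
#' @param design a [spike_design()] covering every sample.
#' @return matrix of estimates (samples x features) with attribute
#'   `"unit"`; `no_isd` samples stay `NA`.
#' @export
absolute_abundance <- function(ratios, design) {
  stopifnot(inherits(ratios, "isd_ratio_table"),
            inherits(design, "spike_design"))
  miss <- setdiff(rownames(ratios$ratios), names(design$amounts))
  if (length(miss))
    stop("sample(s) missing from spike design: ",
         paste(miss, collapse = ", "))
  amt <- design$amounts[rownames(ratios$ratios)]
  if (any(amt == 0)) warning("zero spike amount(s): estimates degenerate to 0")
  est <- ratios$ratios * amt
  attr(est, "unit") <- design$unit
  est
}

#' Quantitative-behaviour check across an ISD dilution series
#'
#' As more ISD is spiked into a fixed background, its share of reads must
#' rise in step. The check regresses log10 of the ISD's read-count odds,
#' p/(1-p), on log10 of the spike amount: odds are proportional to the
#' spiked amount over the whole range (proportions themselves saturate),
#' so the expected slope is 1. Levels with zero ISD reads are excluded and
#' reported.
#'
#' @param x either a list of [feature_table()]s (one per dilution level,
#'   each with a collapsed ISD feature and a single sample) or a numeric
#'   vector of ISD read proportions.
#' @param spike_amounts positive spike amounts, one per level; at least 3
#'   levels spanning more than one order of magnitude.
#' @return list with `slope`, `intercept`, `monotone` (strictly increasing
#'   proportions with amount), `proportions`, `n_used`, `excluded`.
#' @export
isd_dilution_check <- function(x, spike_amounts) {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "feature_table"))) {
    p <- vapply(x, function(tb) {
      if (length(tb$isd_features) != 1L)
        stop("each table needs one collapsed ISD feature")
      cnt <- tb$counts
      sum(cnt[, tb$isd_features]) / sum(cnt)
    }, numeric(1))
  } else p <- as.numeric(x)
  if (length(p) != length(spike_amounts))
    stop("one proportion per spike amount required")
  if (length(p) < 3L) stop("need at least 3 dilution levels")
  if (any(spike_amounts <= 0)) stop("spike amounts must be positive")
  if (diff(range(log10(spike_amounts))) <= 1)
    stop("dilution series must span more than one order of magnitude")
  ord <- order(spike_amounts)
  p <- p[ord]; a <- spike_amounts[ord]
  use <- p > 0 & p < 1
  excluded <- which(!use)
  fit <- lm(log10(p[use] / (1 - p[use])) ~ log10(a[use]))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       monotone = all(diff(p) > 0), proportions = p, n_used = sum(use),
       excluded = excluded)
}

#' Read / write feature tables as TSV
#'
#' Orientation is auto-detected from the first header column:
#' `sample_id` means samples are rows; `feature_id` means features are
#' rows (the table is transposed on read). Flags are passed through the
#' `isd_features` / `coligo_features` arguments, not stored in the file.
#'
#' @param path TSV file.
#' @param isd_features,coligo_features see [feature_table()].
#' @return `read_feature_table`: a [feature_table()].
#' @export
read_feature_table <- function(path, isd_features = character(),
                               coligo_features = character()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  key <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (key == "feature_id") m <- t(m)
  else if (key != "sample_id")
    stop("first column must be 'sample_id' or 'feature_id', got '", key, "'")
  feature_table(m, isd_features, coligo_features)
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
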