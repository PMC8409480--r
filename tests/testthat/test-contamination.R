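test_that("coligo identity extraction corrects single edits and rejects strangers", {
  ids <- fix_coligos()
  # exact prefix + arbitrary tail
  expect_equal(extract_coligo_id(paste0(ids$sequence[7], "ACGTACGT"), ids),
               ids$id[7])
  # single substitution / insertion / deletion: unique at <=1 edit since the
  # set distance is >= 3 (certified by the DP oracle)
  set.seed(12)
  for (i in sample(96, 8)) {
    s <- ids$sequence[i]
    sub <- s; substr(sub, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                           substr(s, 5, 5))[1]
    ins <- paste0(substr(s, 1, 6), "A", substr(s, 7, 13))
    del <- paste0(substr(s, 1, 4), substr(s, 6, 13))
    for (mut in c(sub, ins, del)) {
      read <- paste0(mut, "GGTT")
      # oracle mirrors the flexible 12-14 nt window of the matcher
      d <- vapply(ids$sequence, function(ref)
        min(vapply(12:14, function(w)
          oracle_lev(substr(read, 1, w), ref), 0L)), 0L)
      expect_equal(sum(d <= 1), 1L)
      expect_equal(which(d <= 1), i, ignore_attr = TRUE)
      expect_equal(extract_coligo_id(read, ids), ids$id[i])
    }
  }
  # a 13-mer >= 2 edits from everything returns NA (verified by oracle)
  set.seed(13)
  repeat {
    rand <- random_seq(13)
    if (min(vapply(ids$sequence, oracle_lev, 0L, a = rand)) >= 2) break
  }
  expect_true(is.na(extract_coligo_id(paste0(rand, "AAAA"), ids)))
  # too-short reads and exact-only mode
  expect_true(is.na(extract_coligo_id("ACGT", ids)))
  sub1 <- ids$sequence[1]; substr(sub1, 2, 2) <- setdiff(
    c("A", "C", "G", "T"), substr(sub1, 2, 2))[1]
  expect_true(is.na(extract_coligo_id(sub1, ids, max_edits = 0)))
})

test_that("count matrices are diagonal without contamination and reject foreign wells", {
  ids <- fix_coligos(); lay <- fix_layout()
  a <- lay$assignments
  reads <- data.frame(
    well = rep(a$well, each = 3),
    seq = paste0(rep(ids$sequence[match(a$expected_coligo_id, ids$id)],
                     each = 3), "ACGT"),
    stringsAsFactors = FALSE)
  mat <- count_coligos(reads, ids, lay)
  expect_equal(sum(mat$counts), nrow(reads))
  diag_idx <- cbind(seq_along(mat$wells),
                    match(a$expected_coligo_id[match(mat$wells, a$well)],
                          mat$coligo_ids))
  expect_equal(sum(mat$counts[diag_idx]), sum(mat$counts))
  expect_error(count_coligos(data.frame(well = "Z9", seq = "ACGT"),
                             ids, lay), "absent")
  empty <- count_coligos(data.frame(well = character(),
                                    seq = character()), ids, lay)
  expect_equal(sum(empty$counts), 0L)
})

test_that("report metrics follow the toy OTU-table structure (pure, heavy, minor wells)", {
  ids <- fix_coligos(); lay <- fix_layout()
  a <- lay$assignments
  counts <- matrix(0L, 96, 96, dimnames = list(a$well, ids$id))
  diag_idx <- cbind(seq_len(96), match(a$expected_coligo_id, ids$id))
  counts[diag_idx] <- 100L
  # well 4 heavily contaminated by coligo 1; well 96 two minor contaminants
  counts[4, match(ids$id[1], colnames(counts))] <- 400L
  counts[96, match(ids$id[c(10, 20)], colnames(counts))] <- c(3L, 2L)
  mat <- coligo_count_matrix(counts)
  rep <- contamination_report(mat, lay)
  pw <- rep$per_well
  flagged <- pw$well[pw$foreign_coligo_reads >= 1]
  expect_setequal(flagged, a$well[c(4, 96)])
  expect_lt(pw$proportion_expected[4], pw$proportion_expected[96])
  expect_equal(pw$proportion_expected[1], 1)
  expect_equal(rep$summary$frac_wells_with_any_foreign, 2 / 96)
  expect_equal(rep$summary$frac_wells_with_multiple_foreign, 1 / 96)
  expect_equal(rep$summary$overall_out_of_place_proportion,
               405 / (96 * 100 + 405))
  # per-well conservation: expected + foreign = coligo total
  expect_equal(pw$expected_coligo_reads + pw$foreign_coligo_reads,
               pw$coligo_total)
})

test_that("simple proportion cases: half-foreign well and clean plate", {
  ids <- fix_coligos()[1:2, ]
  lay <- plate_layout(data.frame(
    well = c("A1", "A2"), sample_id = c("s1", "s2"),
    fwd_mid_id = c("F1", "F2"), rev_mid_id = c("R1", "R2"),
    expected_coligo_id = ids$id, isd_amount = 0, role = "sample"))
  cnt <- matrix(c(10L, 10L, 0L, 20L), 2, byrow = TRUE,
                dimnames = list(c("A1", "A2"), ids$id))
  rep <- contamination_report(coligo_count_matrix(cnt), lay)
  expect_equal(rep$per_well$proportion_expected, c(0.5, 1))
  clean <- matrix(c(10L, 0L, 0L, 20L), 2, byrow = TRUE,
                  dimnames = list(c("A1", "A2"), ids$id))
  rep2 <- contamination_report(coligo_count_matrix(clean), lay)
  expect_equal(rep2$summary$frac_wells_with_any_foreign, 0)
  expect_equal(rep2$summary$overall_out_of_place_proportion, 0)
})

test_that("wells with zero coligo reads are excluded from medians, tallied apart", {
  ids <- fix_coligos()[1:2, ]
  lay <- plate_layout(data.frame(
    well = c("A1", "A2"), sample_id = c("s1", "s2"),
    fwd_mid_id = c("F1", "F2"), rev_mid_id = c("R1", "R2"),
    expected_coligo_id = ids$id, isd_amount = 0, role = "sample"))
  cnt <- matrix(c(8L, 2L, 0L, 0L), 2, byrow = TRUE,
                dimnames = list(c("A1", "A2"), ids$id))
  rep <- contamination_report(coligo_count_matrix(cnt), lay)
  expect_equal(rep$summary$n_wells_no_coligo, 1L)
  expect_equal(rep$summary$median_foreign_proportion, 0.2)
  expect_true(is.na(rep$per_well$proportion_expected[2]))
})

test_that("distance profiles bin events by rounded well distance", {
  ids <- fix_coligos(); lay <- fix_layout()
  a <- lay$assignments
  counts <- matrix(0L, 96, 96, dimnames = list(a$well, ids$id))
  counts[cbind(seq_len(96), match(a$expected_coligo_id, ids$id))] <- 50L
  c_a1 <- a$expected_coligo_id[a$well == "A1"]
  # A1's coligo contaminates A2 (distance 1) and B2 (sqrt(2), rounds to 1)
  counts["A2", c_a1] <- 5L
  counts["B2", c_a1] <- 4L
  prof <- contamination_distance_profile(coligo_count_matrix(counts), lay)
  expect_equal(prof$histogram, data.frame(distance = 1, count = 2L))
  # diagonal matrix -> empty histogram
  counts["A2", c_a1] <- 0L; counts["B2", c_a1] <- 0L
  prof0 <- contamination_distance_profile(coligo_count_matrix(counts), lay)
  expect_equal(nrow(prof0$histogram), 0L)
  expect_equal(nrow(prof0$events), 0L)
})

test_that("rotation detection scores both orientations and errors on empty input", {
  ids <- fix_coligos(); lay <- fix_layout()
  a <- lay$assignments
  counts <- matrix(0L, 96, 96, dimnames = list(a$well, ids$id))
  diag_idx <- cbind(seq_len(96), match(a$expected_coligo_id, ids$id))
  counts[diag_idx] <- 60L
  rot <- detect_plate_rotation(coligo_count_matrix(counts), lay)
  expect_equal(rot$orientation, "0")
  expect_equal(rot$score_0, 1)
  expect_false(rot$flagged)
  # counts generated under the rotated layout
  rlay <- rotate_layout(lay)
  rcounts <- matrix(0L, 96, 96, dimnames = list(a$well, ids$id))
  rexp <- setNames(rlay$assignments$expected_coligo_id,
                   rlay$assignments$well)
  rcounts[cbind(seq_len(96), match(rexp[a$well], ids$id))] <- 60L
  rot2 <- detect_plate_rotation(coligo_count_matrix(rcounts), lay)
  expect_equal(rot2$orientation, "180")
  expect_equal(rot2$score_180, 1)
  expect_true(rot2$flagged)
  # 60/40 mixture of correct and rotated reads
  mix <- counts * 0L
  mix[diag_idx] <- 60L
  mix[cbind(seq_len(96), match(rexp[a$well], ids$id))] <-
    mix[cbind(seq_len(96), match(rexp[a$well], ids$id))] + 40L
  rot3 <- detect_plate_rotation(coligo_count_matrix(mix), lay)
  expect_equal(rot3$orientation, "0")
  expect_equal(rot3$score_0, 0.6)
  expect_equal(rot3$score_180, 0.4)
  zero <- counts * 0L
  expect_error(detect_plate_rotation(coligo_count_matrix(zero), lay),
               "undeterminable")
})

test_that("report metrics are invariant under joint permutation of wells and coligos", {
  ids <- fix_coligos(); lay <- fix_layout()
  set.seed(8)
  counts <- matrix(rpois(96 * 96, 0.05), 96, 96,
                   dimnames = list(lay$assignments$well, ids$id))
  diag_idx <- cbind(seq_len(96),
                    match(lay$assignments$expected_coligo_id, ids$id))
  counts[diag_idx] <- counts[diag_idx] + 40L
  s1 <- contamination_report(coligo_count_matrix(counts), lay)$summary
  perm <- sample(96)
  s2 <- contamination_report(
    coligo_count_matrix(counts[perm, perm]), lay)$summary
  expect_equal(s1, s2)
})

test_that("spike-in fraction summaries count coligo and ISD reads per sample", {
  cnt <- matrix(c(99, 1, 0, 90, 5, 5), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("taxon", "coligo01", "ISD")))
  ft <- feature_table(cnt, isd_features = "ISD",
                      coligo_features = "coligo01")
  sf <- spikein_fraction_summary(ft)
  expect_equal(sf$per_sample$coligo_fraction, c(0.01, 0.05))
  expect_equal(sf$per_sample$isd_fraction, c(0, 0.05))
  no_isd <- feature_table(cnt[, 1:2], coligo_features = "coligo01")
  expect_equal(spikein_fraction_summary(no_isd)$per_sample$isd_fraction,
               c(0, 0))
})

test_that("count matrices round-trip through TSV", {
  ids <- fix_coligos()[1:3, ]
  cnt <- matrix(c(5L, 0L, 1L, 0L, 7L, 0L), 2, 3, byrow = TRUE,
                dimnames = list(c("A1", "A2"), ids$id))
  mat <- coligo_count_matrix(cnt, c(A1 = 100L, A2 = 50L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coligo_counts(mat, path)
  back <- read_coligo_counts(path)
  expect_equal(back$counts, mat$counts)
  expect_equal(back$total_reads, mat$total_reads)
})
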