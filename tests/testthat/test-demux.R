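test_that("match_prefix assigns exact reads and corrects single substitutions", {
  mids <- fix_mids()
  p <- fix_primers()$fwd
  f <- mids$forward
  read <- paste0(f$sequence[1], p, "ACGTACGT")
  m <- match_prefix(read, f, p)
  expect_equal(m$mid_id, f$id[1])
  expect_equal(m$consumed, f$length[1] + nchar(p))
  expect_equal(m$reason, "assigned")

  # mutate one base of each MID; correction must recover it (set distance
  # >= 2 guarantees uniqueness at 1 edit; certified via the oracle below)
  set.seed(2)
  for (i in sample(nrow(f), 10)) {
    s <- f$sequence[i]
    pos <- sample(nchar(s), 1)
    sub <- setdiff(c("A", "C", "G", "T"), substr(s, pos, pos))[1]
    substr(s, pos, pos) <- sub
    others <- f$sequence[f$length == nchar(s) & f$id != f$id[i]]
    d_others <- min(vapply(others, oracle_lev, 0L, a = s))
    m <- match_prefix(paste0(s, p, "TTTT"), f, p)
    if (d_others > 1) {
      expect_equal(m$mid_id, f$id[i])
      expect_equal(m$mid_edits, 1L)
    } else {
      expect_equal(m$reason, "ambiguous_mid")  # equidistant tie
    }
  }
})

test_that("match_prefix reports ambiguous ties, missing MIDs and failed primers", {
  p <- "ACGTACGTAC"
  cand <- data.frame(id = c("M1", "M2"), sequence = c("AAAACCCC", "AAAACCCA"))
  # one substitution away from both candidates -> tie
  m <- match_prefix(paste0("AAAACCCG", p), cand, p,
                    max_mid_edits = 1)
  expect_equal(m$reason, "ambiguous_mid")
  m <- match_prefix(paste0("GGGGGGGG", p), cand, p)
  expect_equal(m$reason, "no_mid")
  m <- match_prefix(paste0("AAAACCCC", "TTTTTTTTTT"), cand, p)
  expect_equal(m$reason, "no_primer")
})

test_that("primer matching honours IUPAC degeneracy", {
  cand <- data.frame(id = "M1", sequence = "AAAACCCC")
  # R matches A or G; N matches anything
  m <- match_prefix("AAAACCCCARGNT", cand, "ARGNT", max_primer_mismatches = 0)
  expect_equal(m$reason, "assigned")
  m <- match_prefix("AAAACCCCACGNT", cand, "ARGNT", max_primer_mismatches = 0)
  expect_equal(m$reason, "no_primer")  # C does not match R
})

test_that("pair demultiplexing handles locus conflicts and unknown pairings", {
  mids <- fix_mids()
  lay <- fix_layout()
  primers2 <- list(
    p16S = fix_primers(),
    pITS = list(fwd = "CTTGGTCATTTAGAGGAAGTAA",  # ITS1f
                rev = "GCTGCGTTCTTCATCGATGC"))   # ITS2
  cfg <- demux_config(mids, primers2, lay)
  a <- lay$assignments[1, ]
  fseq <- mids$forward$sequence[mids$forward$id == a$fwd_mid_id]
  rseq <- mids$reverse$sequence[mids$reverse$id == a$rev_mid_id]
  mk <- function(r1, r2) list(read_id = "r", r1_seq = r1, r2_seq = r2,
                              r1_qual = strrep("I", nchar(r1)),
                              r2_qual = strrep("I", nchar(r2)))
  tail <- strrep("ACGT", 10)
  good <- mk(paste0(fseq, primers2$p16S$fwd, tail),
             paste0(rseq, primers2$p16S$rev, tail))
  res <- demultiplex_pair(good, cfg)
  expect_equal(res$reason, "assigned")
  expect_equal(res$sample_id, a$sample_id)
  expect_equal(res$locus, "p16S")
  expect_equal(nchar(res$r1_seq),
               nchar(good$r1_seq) - nchar(fseq) - nchar(primers2$p16S$fwd))

  confl <- mk(paste0(fseq, primers2$p16S$fwd, tail),
              paste0(rseq, primers2$pITS$rev, tail))
  expect_equal(demultiplex_pair(confl, cfg)$reason, "locus_conflict")

  # valid MIDs whose pairing is not on the plate
  b <- lay$assignments[2, ]
  rseq2 <- mids$reverse$sequence[mids$reverse$id == b$rev_mid_id]
  unk <- mk(paste0(fseq, primers2$p16S$fwd, tail),
            paste0(rseq2, primers2$p16S$rev, tail))
  expect_equal(demultiplex_pair(unk, cfg)$reason, "unknown_pairing")
})

test_that("zero-error simulation round-trips to the correct wells with trimming intact", {
  mids <- fix_mids(); cids <- fix_coligos()
  cfg <- sim_config(seed = 31, mid_set = mids, coligos = cids,
                    primers = fix_primers(), coligo_fraction = 0.02,
                    isd_fraction = 0.01,
                    errors = list(sub_rate = 0, indel_rate = 0),
                    reads_per_well = list(mean = 30, dispersion = 10))
  run <- simulate_run(cfg)
  dc <- demux_config(mids, fix_primers(), cfg$layout)
  asn <- demultiplex_reads(run$reads$r1, run$reads$r2, dc)
  expect_true(all(asn$reason == "assigned"))
  expect_identical(asn$well, run$reads$truth$well)
  # conservation and trimming exactness
  expect_equal(nrow(asn), nrow(run$reads$r1))
  mid_seq <- setNames(mids$forward$sequence, mids$forward$id)
  rebuilt <- paste0(mid_seq[asn$fwd_mid_id], fix_primers()$fwd, asn$r1_seq)
  expect_identical(unname(rebuilt), run$reads$r1$sequence)
  expect_equal(nchar(asn$r1_qual), nchar(asn$r1_seq))
})

test_that("no single edit in a MID region can reassign a read to a different sample", {
  mids <- fix_mids()
  p <- fix_primers()$fwd
  f <- mids$forward
  tail <- strrep("GTCA", 12)
  reads <- character(0); truth <- character(0); kind <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(f))) {
    s <- f$sequence[i]; L <- nchar(s)
    muts <- character(0); mkind <- character(0)
    for (pos in seq_len(L)) for (b in bases) {
      if (substr(s, pos, pos) != b) {
        m <- s; substr(m, pos, pos) <- b
        muts <- c(muts, m); mkind <- c(mkind, "sub")
      }
    }
    for (pos in seq_len(L)) {
      muts <- c(muts, paste0(substr(s, 1, pos - 1), substr(s, pos + 1, L)))
      mkind <- c(mkind, "del")
    }
    for (pos in 0:L) for (b in bases) {
      muts <- c(muts, paste0(substr(s, 1, pos), b, substr(s, pos + 1, L)))
      mkind <- c(mkind, "ins")
    }
    reads <- c(reads, paste0(muts, p, tail))
    truth <- c(truth, rep(f$id[i], length(muts)))
    kind <- c(kind, mkind)
  }
  m <- match_prefix(reads, f, p)
  hit <- m$reason == "assigned"
  # the safety property: an edited read is corrected or dropped, never moved
  expect_true(all(m$mid_id[hit] == truth[hit]))
  # substitutions are nearly always correctable (ambiguity needs a
  # distance-2 neighbour); indels mostly shift the primer and are dropped
  expect_gt(mean(hit[kind == "sub"]), 0.9)
})

test_that("file-level demultiplexing conserves reads and rejects desynced mates", {
  mids <- fix_mids()
  cfg <- sim_config(seed = 33, mid_set = mids, coligos = fix_coligos(),
                    primers = fix_primers(),
                    errors = list(sub_rate = 0.005, indel_rate = 1e-4),
                    reads_per_well = list(mean = 10, dispersion = 5))
  dir <- withr::local_tempdir()
  simulate_run(cfg, out_dir = dir)
  dc <- demux_config(mids, fix_primers(), cfg$layout)
  out <- file.path(dir, "demux")
  res <- demultiplex_run(file.path(dir, "r1.fastq.gz"),
                         file.path(dir, "r2.fastq.gz"), dc, out_dir = out)
  expect_equal(sum(res$reason_counts), res$n_input)
  expect_true(file.exists(file.path(out, "demux_stats.tsv")))
  expect_equal(sum(res$stats$n_reads),
               sum(res$assignments$reason == "assigned"))
  # truncate r2 -> desync error naming the first bad record
  r2 <- read_fastq(file.path(dir, "r2.fastq.gz"))
  write_fastq(r2[-nrow(r2), ], file.path(dir, "r2_short.fastq.gz"))
  expect_error(demultiplex_run(file.path(dir, "r1.fastq.gz"),
                               file.path(dir, "r2_short.fastq.gz"), dc),
               "desynchronized")
})

test_that("empty input yields an empty result with zero counts", {
  dir <- withr::local_tempdir()
  e1 <- file.path(dir, "e1.fastq"); e2 <- file.path(dir, "e2.fastq")
  file.create(e1, e2)
  res <- demultiplex_run(e1, e2, fix_demux_config())
  expect_equal(res$n_input, 0L)
  expect_equal(nrow(res$stats), 0L)
})
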