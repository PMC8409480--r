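#' Simulation configuration
#'
#' Defines a synthetic plate experiment: per-well communities (log-normal
#' taxon abundances over fixed random reference amplicons), small coligo
#' and ISD spike fractions, a spatial contamination process, a per-base
#' error model, and negative-binomial sequencing depth. Reads follow the
#' library structure MID + locus primer + template on both mates, so the
#' output exercises the demultiplexer, the contamination analytics, and
#' the ISD normalization end to end against known truth.
#'
#' The contamination process draws, for each event, a donor well with
#' probability proportional to
#' `(1 - epsilon) * exp(-distance / lambda) + epsilon * uniform`,
#' and moves a `Beta(beta_a, beta_b)` fraction of the donor's
#' (pre-contamination) molecule pool into the recipient before reads are
#' sampled. Defaults emulate minor, mostly short-range contamination.
#'
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param mid_set a [mid_set()] supplying at least one MID pair per well.
#' @param coligos coligo identifier data.frame (`id`, `sequence`).
#' @param primers list with `fwd` and `rev` locus primers.
#' @param layout optional [plate_layout()]; defaults to the diagonal
#'   design (well i: forward MID i, reverse MID i, coligo i).
#' @param n_rows,n_cols plate geometry.
#' @param n_taxa,taxon_meanlog,taxon_sdlog community size and log-normal
#'   abundance parameters.
#' @param taxon_seq_length length of the simulated amplicon interiors.
#' @param isd_sequence ISD reference (default: a random 170-mer drawn from
#'   the seed).
#' @param isd_fraction,coligo_fraction expected molecule fractions of the
#'   spikes per well (defaults 1e-3 and 1e-4: realized read fractions land
#'   in the small-percentage band typical of low-level spiking).
#' @param contamination list: `event_rate` (per-well probability of
#'   receiving one event), `n_events` (overrides `event_rate` with an
#'   exact count), `lambda` (kernel range, well-pitch units), `epsilon`
#'   (uniform floor weight), `beta_a`, `beta_b` (migration-fraction Beta).
#' @param errors list: `sub_rate`, `indel_rate` per base.
#' @param reads_per_well list: `mean`, `dispersion` (negative-binomial
#'   size).
#' @param read_length read length in cycles; `qual_char` constant quality.
#' @param adapter 3' pad used when a template is shorter than the read.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, mid_set, coligos, primers,
                       layout = NULL, n_rows = 8L, n_cols = 12L,
                       n_taxa = 30L, taxon_meanlog = 0, taxon_sdlog = 1,
                       taxon_seq_length = 210L, isd_sequence = NULL,
                       isd_fraction = 1e-3, coligo_fraction = 1e-4,
                       contamination = list(), errors = list(),
                       reads_per_well = list(), read_length = 150L,
                       qual_char = "I", adapter = "AGATCGGAAGAGC") {
  if (missing(seed)) stop("seed is mandatory")
  cont <- list(event_rate = 0, n_events = NULL, lambda = 1, epsilon = 0.05,
               beta_a = 1, beta_b = 499)
  cont[names(contamination)] <- contamination
  err <- list(sub_rate = 0.001, indel_rate = 1e-4)
  err[names(errors)] <- errors
  depth <- list(mean = 2000, dispersion = 10)
  depth[names(reads_per_well)] <- reads_per_well
  stopifnot(isd_fraction >= 0, coligo_fraction >= 0,
            err$sub_rate >= 0, err$sub_rate <= 1,
            err$indel_rate >= 0, err$indel_rate <= 1,
            cont$event_rate >= 0, cont$event_rate <= 1)
  if (isd_fraction + coligo_fraction >= 1)
    stop("spike fractions must sum below 1")
  if (is.null(layout)) {
    layout <- diagonal_layout(mid_set$forward$id, mid_set$reverse$id,
                              coligos$id, n_rows, n_cols)
  }
  max_prefix <- max(mid_set$forward$length) + nchar(primers$fwd)
  max_prefix <- max(max_prefix,
                    max(mid_set$reverse$length) + nchar(primers$rev))
  if (read_length <= max_prefix)
    stop("read_length (", read_length, ") must exceed the longest ",
         "MID+primer prefix (", max_prefix, ")")
  structure(list(seed = as.integer(seed), mid_set = mid_set,
                 coligos = coligos, primers = primers, layout = layout,
                 n_rows = layout$n_rows, n_cols = layout$n_cols,
                 n_taxa = as.integer(n_taxa),
                 taxon_meanlog = taxon_meanlog, taxon_sdlog = taxon_sdlog,
                 taxon_seq_length = as.integer(taxon_seq_length),
                 isd_sequence = isd_sequence,
                 isd_fraction = isd_fraction,
                 coligo_fraction = coligo_fraction,
                 contamination = cont, errors = err,
                 reads_per_well = depth,
                 read_length = as.integer(read_length),
                 qual_char = qual_char, adapter = adapter),
            class = "sim_config")
}

#' Simulate per-well molecule pools and contamination events
#'
#' Builds each well's molecule pool (taxa at log-normal relative
#' abundances, the well's own coligo, and the ISD at their configured
#' expected fractions), then applies contamination events: each moves a
#' Beta-distributed fraction of a donor's pre-contamination pool into a
#' recipient. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_plate`: `pools` (wells x molecule-class
#'   weight matrix, columns `taxon_*`, coligo ids, `ISD`), `truth` (list:
#'   `taxon_weights`, `events` data.frame with `donor`, `recipient`,
#'   `migration_fraction`, per-well `isd_amount`), `taxon_seqs`,
#'   `isd_sequence`, `config`.
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  # identifier sets are designed to be dissimilar from natural sequences;
  # emulate that by redrawing any template whose leading window would be
  # mistaken for a coligo identifier
  draw_clear <- function(n, len) {
    out <- random_dna(rep(len, n))
    repeat {
      clash <- !is.na(extract_coligo_id(out, setNames(
        config$coligos$sequence, config$coligos$id)))
      if (!any(clash)) return(out)
      out[clash] <- random_dna(rep(len, sum(clash)))
    }
  }
  taxon_seqs <- setNames(draw_clear(config$n_taxa, config$taxon_seq_length),
                         sprintf("taxon_%02d", seq_len(config$n_taxa)))
  isd_seq <- config$isd_sequence %||% draw_clear(1L, 170L)
  a <- config$layout$assignments
  a <- a[a$role != "empty", ]
  wells <- a$well
  n_wells <- length(wells)
  coligo_ids <- config$coligos$id
  classes <- c(names(taxon_seqs), coligo_ids, "ISD")
  pools <- matrix(0, n_wells, length(classes),
                  dimnames = list(wells, classes))
  tw <- matrix(rlnorm(n_wells * config$n_taxa, config$taxon_meanlog,
                      config$taxon_sdlog),
               n_wells, config$n_taxa, dimnames = list(wells,
                                                       names(taxon_seqs)))
  native <- 1 - config$isd_fraction - config$coligo_fraction
  pools[, names(taxon_seqs)] <- tw / rowSums(tw) * native
  own <- a$expected_coligo_id
  has_col <- nzchar(own)
  pools[cbind(which(has_col), match(own[has_col], classes))] <-
    config$coligo_fraction
  pools[, "ISD"] <- config$isd_fraction

  # contamination events drawn against the pre-contamination pools
  cont <- config$contamination
  wc <- well_from_label(wells, config$n_rows, config$n_cols)
  if (!is.null(cont$n_events)) {
    rec_idx <- sample.int(n_wells, cont$n_events,
                          replace = cont$n_events > n_wells)
  } else {
    rec_idx <- which(runif(n_wells) < cont$event_rate)
  }
  events <- data.frame(donor = character(), recipient = character(),
                       migration_fraction = numeric(),
                       stringsAsFactors = FALSE)
  if (length(rec_idx)) {
    pools0 <- pools
    don_idx <- vapply(rec_idx, function(r) {
      d <- sqrt((wc$row - wc$row[r])^2 + (wc$col - wc$col[r])^2)
      w <- (1 - cont$epsilon) * exp(-d / cont$lambda) / sum(exp(-d / cont$lambda)) +
        cont$epsilon / n_wells
      w[r] <- 0
      sample.int(n_wells, 1L, prob = w)
    }, integer(1))
    m <- rbeta(length(rec_idx), cont$beta_a, cont$beta_b)
    for (k in seq_along(rec_idx))
      pools[rec_idx[k], ] <- pools[rec_idx[k], ] + m[k] * pools0[don_idx[k], ]
    events <- data.frame(donor = wells[don_idx], recipient = wells[rec_idx],
                         migration_fraction = m, stringsAsFactors = FALSE)
  }
  structure(list(pools = pools,
                 truth = list(taxon_weights = tw, events = events,
                              isd_amount = setNames(a$isd_amount, wells)),
                 taxon_seqs = taxon_seqs, isd_sequence = isd_seq,
                 wells = wells, assignments = a, config = config),
            class = "sim_plate")
}

#' @export
print.sim_plate <- function(x, ...) {
  cat(sprintf("sim_plate: %d wells, %d taxa, %d contamination event(s)\n",
              length(x$wells), x$config$n_taxa, nrow(x$truth$events)))
  invisible(x)
}

# Apply per-base substitutions and indels; vectorized over reads.
mutate_seqs <- function(seqs, sub_rate, indel_rate) {
  n <- length(seqs)
  if (n == 0 || (sub_rate == 0 && indel_rate == 0)) return(seqs)
  bases <- c("A", "C", "G", "T")
  if (sub_rate > 0) {
    len <- nchar(seqs)
    nerr <- rbinom(n, len, sub_rate)
    for (k in seq_len(max(nerr, 0))) {
      sel <- which(nerr >= k)
      if (!length(sel)) break
      pos <- 1L + floor(runif(length(sel)) * len[sel])
      cur <- substr(seqs[sel], pos, pos)
      new <- sample(bases, length(sel), replace = TRUE)
      redo <- which(new == cur)
      while (length(redo)) {
        new[redo] <- sample(bases, length(redo), replace = TRUE)
        redo <- redo[new[redo] == cur[redo]]
      }
      substr(seqs[sel], pos, pos) <- new
    }
  }
  if (indel_rate > 0) {
    len <- nchar(seqs)
    nind <- rbinom(n, len + 1L, indel_rate)
    for (i in which(nind > 0)) {
      for (k in seq_len(nind[i])) {
        L <- nchar(seqs[i])
        pos <- 1L + floor(runif(1) * L)
        if (runif(1) < 0.5) {  # insertion before pos
          seqs[i] <- paste0(substr(seqs[i], 1, pos - 1), sample(bases, 1),
                            substr(seqs[i], pos, L))
        } else {               # deletion of pos
          seqs[i] <- paste0(substr(seqs[i], 1, pos - 1),
                            substr(seqs[i], pos + 1, L))
        }
      }
    }
  }
  seqs
}

#' Simulate paired reads from a plate
#'
#' Per well, the read count is negative-binomial and each read samples a
#' molecule from the well's pool. R1 = forward MID + forward primer +
#' template (5'->3'); R2 = reverse MID + reverse primer + reverse
#' complement of the template. Templates shorter than the read (coligos
#' are short inserts) are padded 3' with an adapter stub and then random
#' bases, modelling read-through. Per-base errors are applied after
#' construction; qualities are constant.
#'
#' @param sim a [simulate_plate()] result.
#' @param r1_path,r2_path optional FASTQ(.gz) outputs.
#' @param truth_path optional TSV output of per-read truth.
#' @return list with data.frames `r1`, `r2` (`id`, `sequence`,
#'   `quality`) and `truth` (`read_id`, `well`, `class`).
#' @export
simulate_reads <- function(sim, r1_path = NULL, r2_path = NULL,
                           truth_path = NULL) {
  stopifnot(inherits(sim, "sim_plate"))
  config <- sim$config
  set.seed(config$seed + 1L)
  a <- sim$assignments
  fwd_mid <- setNames(config$mid_set$forward$sequence,
                      config$mid_set$forward$id)[a$fwd_mid_id]
  rev_mid <- setNames(config$mid_set$reverse$sequence,
                      config$mid_set$reverse$id)[a$rev_mid_id]
  interiors <- c(sim$taxon_seqs,
                 setNames(config$coligos$sequence, config$coligos$id),
                 ISD = sim$isd_sequence)
  classes <- colnames(sim$pools)
  depth <- config$reads_per_well
  n_reads <- rnbinom(length(sim$wells), size = depth$dispersion,
                     mu = depth$mean)
  well_idx <- rep(seq_along(sim$wells), n_reads)
  tpl <- unlist(lapply(seq_along(sim$wells), function(w) {
    if (n_reads[w] == 0L) return(integer())
    cnt <- rmultinom(1, n_reads[w], sim$pools[w, ])[, 1]
    idx <- rep(seq_along(classes), cnt)
    idx[sample.int(length(idx))]
  }))
  total <- length(tpl)
  fp <- toupper(config$primers$fwd); rp <- toupper(config$primers$rev)
  interior <- unname(interiors[classes[tpl]])
  amp_r1 <- paste0(fwd_mid[well_idx], fp, interior, reverse_complement(rp))
  rc_int <- vapply(interiors, reverse_complement, "")  # computed once
  amp_r2 <- paste0(rev_mid[well_idx], rp, unname(rc_int[classes[tpl]]),
                   reverse_complement(fp))
  pad_to <- config$read_length + 10L
  pad <- function(x) {
    short <- which(nchar(x) < pad_to)
    if (length(short)) {
      need <- pad_to - nchar(x)[short] - nchar(config$adapter)
      tail <- vapply(pmax(need, 0L), function(k)
        if (k > 0) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                         collapse = "") else "", "")
      x[short] <- substr(paste0(x[short], config$adapter, tail), 1, pad_to)
    }
    x
  }
  r1 <- pad(amp_r1); r2 <- pad(amp_r2)
  r1 <- mutate_seqs(r1, config$errors$sub_rate, config$errors$indel_rate)
  r2 <- mutate_seqs(r2, config$errors$sub_rate, config$errors$indel_rate)
  r1 <- substr(r1, 1, config$read_length)
  r2 <- substr(r2, 1, config$read_length)
  ids <- sprintf("sim_%07d", seq_len(total))
  out <- list(
    r1 = data.frame(id = ids, sequence = r1,
                    quality = strrep(config$qual_char, nchar(r1)),
                    stringsAsFactors = FALSE),
    r2 = data.frame(id = ids, sequence = r2,
                    quality = strrep(config$qual_char, nchar(r2)),
                    stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, well = sim$wells[well_idx],
                       class = classes[tpl], stringsAsFactors = FALSE))
  if (!is.null(r1_path)) write_fastq(out$r1, r1_path)
  if (!is.null(r2_path)) write_fastq(out$r2, r2_path)
  if (!is.null(truth_path)) write_tsv(out$truth, truth_path)
  out
}

#' Sample a well-by-coligo count matrix directly from simulated pools
#'
#' Count-level shortcut past FASTQ serialization and demultiplexing: per
#' well a negative-binomial read depth is drawn and molecules are sampled
#' multinomially from the pool, exactly as [simulate_reads()] does, but
#' only the per-class counts are kept. Used for large contamination-
#' recovery experiments; the full read-level pipeline behaves identically
#' up to sequencing error.
#'
#' @param sim a [simulate_plate()] result.
#' @return a [coligo_count_matrix()] over the plate's wells and coligo
#'   ids; total reads per well include taxon and ISD reads.
#' @export
simulate_coligo_counts <- function(sim) {
  stopifnot(inherits(sim, "sim_plate"))
  config <- sim$config
  set.seed(config$seed + 1L)
  depth <- config$reads_per_well
  n_reads <- rnbinom(length(sim$wells), size = depth$dispersion,
                     mu = depth$mean)
  cnt <- t(vapply(seq_along(sim$wells), function(w)
    rmultinom(1, n_reads[w], sim$pools[w, ])[, 1],
    integer(ncol(sim$pools))))
  rownames(cnt) <- sim$wells
  coligo_ids <- config$coligos$id
  coligo_count_matrix(cnt[, coligo_ids, drop = FALSE],
                      setNames(n_reads, sim$wells))
}

#' Simulate an ISD dilution series
#'
#' One sample per spike amount: a fixed mock-community background (weights
#' drawn once from the seed) plus an ISD whose molecule mass is
#' proportional to the amount, sequenced to a negative-binomial depth.
#' The ISD read proportion therefore follows amount-proportional odds,
#' the behaviour [isd_dilution_check()] verifies.
#'
#' @param seed integer seed.
#' @param amounts positive spike amounts (at least 2), e.g. in pg.
#' @param n_taxa mock-community richness.
#' @param mass_per_unit ISD molecule mass contributed per unit of amount,
#'   relative to a background mass of 1.
#' @param depth_mean,depth_dispersion negative-binomial read depth per
#'   level.
#' @return list with `tables` (one single-sample [feature_table()] per
#'   level, ISD collapsed), `amounts`, `proportions` (realized ISD read
#'   proportions).
#' @export
dilution_series <- function(seed, amounts, n_taxa = 10L,
                            mass_per_unit = 2.5e-4, depth_mean = 66000,
                            depth_dispersion = 20) {
  if (length(amounts) < 2L) stop("need at least 2 spike amounts")
  if (any(amounts <= 0)) stop("spike amounts must be positive")
  set.seed(seed)
  bg <- rlnorm(n_taxa, 0, 1)
  bg <- bg / sum(bg)  # background mass 1 at every level
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  tables <- lapply(seq_along(amounts), function(i) {
    w <- c(bg, amounts[i] * mass_per_unit)
    depth <- rnbinom(1, size = depth_dispersion, mu = depth_mean)
    cnt <- rmultinom(1, depth, w)[, 1]
    m <- matrix(cnt, nrow = 1,
                dimnames = list(sprintf("level_%02d", i), c(taxa, "ISD")))
    feature_table(m, isd_features = "ISD")
  })
  props <- vapply(tables, function(tb)
    sum(tb$counts[, "ISD"]) / sum(tb$counts), numeric(1))
  list(tables = tables, amounts = amounts, proportions = props)
}

#' Run a full simulation and write its outputs
#'
#' Convenience wrapper: [simulate_plate()] then [simulate_reads()], with
#' FASTQ, truth table, and a config echo written under `out_dir` when
#' given. Byte-identical outputs for identical configs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param gz gzip the FASTQ outputs.
#' @return list with `sim` (the [simulate_plate()] result) and `reads`
#'   (the [simulate_reads()] result).
#' @export
simulate_run <- function(config, out_dir = NULL, gz = TRUE) {
  sim <- simulate_plate(config)
  if (is.null(out_dir)) {
    reads <- simulate_reads(sim)
  } else {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (gz) ".fastq.gz" else ".fastq"
    reads <- simulate_reads(sim,
                            r1_path = file.path(out_dir, paste0("r1", ext)),
                            r2_path = file.path(out_dir, paste0("r2", ext)),
                            truth_path = file.path(out_dir, "truth.tsv"))
    echo <- config[c("seed", "n_taxa", "isd_fraction", "coligo_fraction",
                     "read_length")]
    echo$contamination <- config$contamination
    echo$errors <- config$errors
    echo$reads_per_well <- config$reads_per_well
    jsonlite::write_json(echo, file.path(out_dir, "config_echo.json"),
                         auto_unbox = TRUE, null = "null")
  }
  list(sim = sim, reads = reads)
}
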