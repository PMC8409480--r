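#' Sequence file input/output
#'
#' FASTA and FASTQ (plain or gzipped, autodetected) readers returning plain
#' data.frames, plus 4-line FASTQ serialization. Sequences are uppercased
#' on read.
#'
#' @param path file path (`.gz` handled transparently).
#' @return `read_fasta`: data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), sequence = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param records data.frame with `id` and `sequence`, or a named character
#'   vector.
#' @param width line-wrap width on write.
#' @export
write_fasta <- function(records, path, width = 80L) {
  if (is.data.frame(records))
    records <- setNames(records$sequence, records$id)
  x <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @rdname read_fasta
#' @return `read_fastq`: data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0L || is_empty_gz(path))
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  x <- tryCatch(
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        # harmless notice about unused metadata columns on the quality track
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e)
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e)))
  data.frame(id = names(x), sequence = toupper(as.character(x)),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

is_empty_gz <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (length(magic) == 2L && identical(as.integer(magic),
                                       c(0x1fL, 0x8bL))) {
    gz <- gzfile(path, "rb"); on.exit(close(gz), add = TRUE)
    length(readBin(gz, "raw", 1L)) == 0L
  } else FALSE
}

#' @rdname read_fasta
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param gz write gzip-compressed output.
#' @export
write_fastq <- function(reads, path, gz = grepl("\\.gz$", path)) {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    rec <- paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality)
    writeLines(rec, con)
  }
  invisible(path)
}

strip_mate_suffix <- function(ids) {
  ids <- sub("[ \t].*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Read paired FASTQ files
#'
#' Reads both mates and enforces id agreement (up to `/1` `/2` or
#' space-comment suffixes); raises an error naming the first desynchronized
#' record.
#'
#' @param r1,r2 mate file paths.
#' @return list with data.frames `r1`, `r2` (see [read_fastq()]).
#' @export
read_fastq_paired <- function(r1, r2) {
  a <- read_fastq(r1); b <- read_fastq(r2)
  if (nrow(a) != nrow(b)) {
    i <- min(nrow(a), nrow(b)) + 1L
    stop("mate files desynchronized: ", nrow(a), " vs ", nrow(b),
         " records (first unpaired record index ", i, ")")
  }
  ia <- strip_mate_suffix(a$id); ib <- strip_mate_suffix(b$id)
  bad <- which(ia != ib)
  if (length(bad))
    stop("mate id mismatch at record ", bad[1], ": '", ia[bad[1]],
         "' vs '", ib[bad[1]], "'")
  a$id <- ia; b$id <- ib
  list(r1 = a, r2 = b)
}

#' Write a TSV table (the package's single tabular dialect)
#'
#' Tab-delimited, header row, UTF-8, '.' decimal separator, no quoting or
#' row names.
#'
#' @param df data.frame; `path` output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
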