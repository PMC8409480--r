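#' Plate geometry: wells, labels, coordinates
#'
#' Wells are addressed 0-based: row 0 = row A (top), column 0 = column 1
#' (left). Labels are the usual letter+number form ("A1" .. "H12" on a
#' 96-well plate, up to "P24" on a 384-well plate). Distances are measured
#' in well-pitch units, with row and column pitch treated as equal.
#'
#' @param label character vector of well labels, e.g. "A1".
#' @param n_rows,n_cols plate geometry (8 x 12 for 96-well, 16 x 24 for
#'   384-well).
#' @return `well_from_label`: data.frame with columns `row`, `col`, `label`.
#' @examples
#' well_from_label("H12")         # row 7, col 11
#' label_from_well(1, 2)          # "B3"
#' well_distance("A1", "H12")     # sqrt(170)
#' @export
well_from_label <- function(label, n_rows = 8L, n_cols = 12L) {
  check_geometry(n_rows, n_cols)
  ok <- grepl("^[A-Za-z][0-9]+$", label)
  if (any(!ok))
    stop("malformed well label(s): ", paste(label[!ok], collapse = ", "))
  row <- match(toupper(substr(label, 1, 1)), LETTERS) - 1L
  col <- as.integer(substring(label, 2)) - 1L
  bad <- row >= n_rows | col < 0L | col >= n_cols
  if (any(bad))
    stop("well label(s) outside ", n_rows, "x", n_cols, " plate: ",
         paste(label[bad], collapse = ", "))
  data.frame(row = row, col = col,
             label = paste0(LETTERS[row + 1L], col + 1L),
             stringsAsFactors = FALSE)
}

#' @rdname well_from_label
#' @param row,col 0-based well coordinates (vectors recycle).
#' @return `label_from_well`: character vector of labels.
#' @export
label_from_well <- function(row, col) {
  stopifnot(all(row >= 0), all(col >= 0), all(row < 26))
  paste0(LETTERS[row + 1L], col + 1L)
}

#' @rdname well_from_label
#' @param a,b well labels (or data.frames from [well_from_label()]).
#' @param rounded if `TRUE`, round half away from zero to the nearest
#'   integer (the convention used for spatial contamination profiles).
#' @return `well_distance`: Euclidean distance(s) in well-pitch units.
#' @export
well_distance <- function(a, b, rounded = FALSE, n_rows = 8L, n_cols = 12L) {
  if (is.character(a)) a <- well_from_label(a, n_rows, n_cols)
  if (is.character(b)) b <- well_from_label(b, n_rows, n_cols)
  d <- sqrt((a$row - b$row)^2 + (a$col - b$col)^2)
  if (rounded) round_half_away(d) else d
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

check_geometry <- function(n_rows, n_cols) {
  if (!(n_rows * n_cols) %in% c(96L, 384L))
    stop("plate geometry must be 96-well (8x12) or 384-well (16x24), got ",
         n_rows, "x", n_cols)
  invisible(TRUE)
}

WELL_ROLES <- c("sample", "negative_control", "positive_control", "empty")

#' Plate layouts: per-well assignments
#'
#' A plate layout maps each well of a 96- or 384-well plate to a sample id,
#' a forward/reverse MID pair (the dual index), the coligo expected in that
#' well, the ISD spike amount, and a role. Each MID pair may occur at most
#' once (one unique dual index per replicate).
#'
#' @param assignments data.frame with columns `well`, `sample_id`,
#'   `fwd_mid_id`, `rev_mid_id`, `expected_coligo_id` (may be `""`),
#'   `isd_amount`, `role`.
#' @param n_rows,n_cols plate geometry.
#' @param isd_unit unit of `isd_amount` (label only, e.g. `"pg/ul"`).
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(assignments, n_rows = 8L, n_cols = 12L,
                         isd_unit = "pg/ul") {
  check_geometry(n_rows, n_cols)
  need <- c("well", "sample_id", "fwd_mid_id", "rev_mid_id",
            "expected_coligo_id", "isd_amount", "role")
  miss <- setdiff(need, names(assignments))
  if (length(miss)) stop("layout is missing column(s): ",
                         paste(miss, collapse = ", "))
  a <- as.data.frame(assignments)[, need]
  wc <- well_from_label(a$well, n_rows, n_cols)
  a$well <- wc$label
  if (anyDuplicated(a$well))
    stop("duplicated well(s): ", paste(unique(a$well[duplicated(a$well)]),
                                       collapse = ", "))
  bad_role <- !a$role %in% WELL_ROLES
  if (any(bad_role))
    stop("invalid role(s): ", paste(unique(a$role[bad_role]), collapse = ", "))
  pair <- paste(a$fwd_mid_id, a$rev_mid_id, sep = "+")
  used <- a$role != "empty"
  if (anyDuplicated(pair[used]))
    stop("duplicated MID pairing(s): ",
         paste(unique(pair[used][duplicated(pair[used])]), collapse = ", "))
  if (any(a$isd_amount < 0)) stop("isd_amount must be nonnegative")
  structure(list(assignments = a, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), isd_unit = isd_unit),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("plate_layout: %dx%d plate, %d assigned well(s)\n",
              x$n_rows, x$n_cols, n))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$assignments$role)),
                                table(x$assignments$role)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rotate a plate layout by 180 degrees
#'
#' Models the common handling error of a plate placed the wrong way round:
#' well (r, c) maps to (n_rows-1-r, n_cols-1-c). Applying the rotation
#' twice restores the original layout. (90-degree rotations are physically
#' impossible for rectangular plates in their holders.)
#'
#' @param layout a [plate_layout()].
#' @return the rotated `plate_layout`.
#' @export
rotate_layout <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  a <- layout$assignments
  wc <- well_from_label(a$well, layout$n_rows, layout$n_cols)
  a$well <- label_from_well(layout$n_rows - 1L - wc$row,
                            layout$n_cols - 1L - wc$col)
  plate_layout(a, layout$n_rows, layout$n_cols, layout$isd_unit)
}

#' Build the one-coligo-per-well diagonal layout
#'
#' Convenience constructor for the standard validation design: well i gets
#' forward MID i, reverse MID i, and coligo i.
#'
#' @param fwd_mid_ids,rev_mid_ids,coligo_ids id vectors, recycled across the
#'   plate in row-major well order; must each supply at least
#'   `n_rows * n_cols` ids.
#' @param n_rows,n_cols plate geometry.
#' @param isd_amount per-well ISD spike amount.
#' @param isd_unit unit label for `isd_amount`.
#' @return a [plate_layout()].
#' @export
diagonal_layout <- function(fwd_mid_ids, rev_mid_ids, coligo_ids,
                            n_rows = 8L, n_cols = 12L, isd_amount = 1,
                            isd_unit = "pg/ul") {
  n <- n_rows * n_cols
  if (length(fwd_mid_ids) < n || length(rev_mid_ids) < n ||
      length(coligo_ids) < n)
    stop("need at least ", n, " ids of each kind")
  grid <- expand.grid(col = 0:(n_cols - 1L), row = 0:(n_rows - 1L))
  plate_layout(data.frame(
    well = label_from_well(grid$row, grid$col),
    sample_id = sprintf("S%03d", seq_len(n)),
    fwd_mid_id = fwd_mid_ids[seq_len(n)],
    rev_mid_id = rev_mid_ids[seq_len(n)],
    expected_coligo_id = coligo_ids[seq_len(n)],
    isd_amount = isd_amount,
    role = "sample",
    stringsAsFactors = FALSE), n_rows, n_cols, isd_unit)
}

#' Read / write plate layouts
#'
#' Tab- or comma-separated sample sheets with header columns
#' `well,sample_id,fwd_mid_id,rev_mid_id,expected_coligo_id,isd_amount,role`
#' and wells given as labels ("A1".."H12").
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param n_rows,n_cols plate geometry.
#' @return `read_plate_layout`: a [plate_layout()].
#' @export
read_plate_layout <- function(path, n_rows = 8L, n_cols = 12L) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  df$isd_amount <- as.numeric(df$isd_amount)
  df$expected_coligo_id[is.na(df$expected_coligo_id)] <- ""
  plate_layout(df, n_rows, n_cols)
}

#' @rdname read_plate_layout
#' @param layout a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(layout$assignments, path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
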