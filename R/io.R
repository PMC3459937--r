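# Tabular I/O for the screen's artifacts. One dialect everywhere:
# comma-separated, UTF-8, header row. File schemas:
#   library.csv:      gene_symbol, refseq, sirna_index, sense, antisense, gene_class
#   layout.csv:       plate_id, well, content_type, gene_symbol, sirna_index
#                     (+ optional replicate_index, written by write_layouts)
#   measurements.csv: plate_id, well, channel, value

CHANNELS <- c("fluc_ires", "fluc_cap", "atp")
CONTENT_TYPES <- c("gene", "scrambled_control", "fluc_control",
                   "plk1_control", "mock", "empty")

#' Parse a plate well coordinate
#'
#' Accepts `"A1"`-style coordinates (rows A-H, columns 1-12),
#' case-insensitively and with optional zero padding (`"A01"`). The
#' canonical written form is unpadded upper case, see [format_well()].
#'
#' @param coord Character vector of well coordinates.
#' @return A tibble with 0-based `row` and `column` integer columns.
#' @examples
#' parse_well("A1")   # row 0, column 0
#' parse_well("H12")  # row 7, column 11
#' @export
parse_well <- function(coord) {
  coord_chr <- toupper(trimws(as.character(coord)))
  m <- regmatches(coord_chr, regexec("^([A-Z])0?([0-9]{1,2})$", coord_chr))
  bad <- vapply(m, length, integer(1)) != 3L
  row <- rep(NA_integer_, length(coord_chr))
  col <- rep(NA_integer_, length(coord_chr))
  row[!bad] <- match(vapply(m[!bad], `[`, character(1), 2L), LETTERS) - 1L
  col[!bad] <- as.integer(vapply(m[!bad], `[`, character(1), 3L)) - 1L
  out_of_range <- !bad & (row > 7L | col > 11L | col < 0L)
  invalid <- bad | out_of_range
  if (any(invalid)) {
    stop("malformed or out-of-range well coordinate(s): ",
         paste(unique(coord[invalid]), collapse = ", "),
         " (expected A1..H12)", call. = FALSE)
  }
  tibble::tibble(row = row, column = col)
}

#' Format 0-based plate coordinates as well addresses
#'
#' @param row,column 0-based integer vectors (rows 0-7, columns 0-11).
#' @return Character vector of `"A1"`-style addresses.
#' @export
format_well <- function(row, column) {
  stopifnot(all(row >= 0 & row <= 7), all(column >= 0 & column <= 11))
  paste0(LETTERS[row + 1L], column + 1L)
}

canonical_well <- function(coord) {
  rc <- parse_well(coord)
  format_well(rc$row, rc$column)
}

read_screen_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read or write a screen library table
#'
#' `read_library()` reads a `library.csv` (columns `gene_symbol`, `refseq`,
#' `sirna_index`, `sense`, `antisense`, `gene_class`). Sequence letters are
#' upper-cased on read; T and U are interchangeable and stored as given.
#' A sequence that is not 21 nt over A/C/G/U/T triggers a warning and is
#' kept with the sequence flagged missing. Duplicate
#' (gene_symbol, sirna_index) pairs are an integrity error.
#'
#' @param path Path to the CSV file.
#' @return A tibble in the internal library format (`gene_symbol`,
#'   `refseq_id`, `sirna_index`, `sense_seq`, `antisense_seq`,
#'   `gene_class`).
#' @export
read_library <- function(path) {
  df <- read_screen_csv(path, c("gene_symbol", "refseq", "sirna_index",
                                "sense", "antisense", "gene_class"))
  dup <- duplicated(df[, c("gene_symbol", "sirna_index")])
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop(sprintf("duplicate library entry for gene %s, siRNA index %s",
                 first$gene_symbol, first$sirna_index), call. = FALSE)
  }
  clean_seq <- function(x) {
    x <- toupper(trimws(x))
    ok <- !is.na(x) & grepl("^[ACGUT]{21}$", x)
    if (any(!ok & !is.na(x) & nzchar(x))) {
      warning("sequence(s) not 21 nt over A/C/G/U/T flagged missing for: ",
              paste(unique(df$gene_symbol[!ok]), collapse = ", "),
              call. = FALSE)
    }
    x[!ok] <- NA_character_
    x
  }
  tibble::tibble(
    gene_symbol = df$gene_symbol,
    refseq_id = df$refseq,
    sirna_index = as.integer(df$sirna_index),
    sense_seq = clean_seq(df$sense),
    antisense_seq = clean_seq(df$antisense),
    gene_class = df$gene_class
  )
}

#' @rdname read_library
#' @param library A library tibble as produced by [make_library()] or
#'   [read_library()].
#' @export
write_library <- function(library, path) {
  out <- data.frame(
    gene_symbol = library$gene_symbol,
    refseq = library$refseq_id,
    sirna_index = library$sirna_index,
    sense = library$sense_seq,
    antisense = library$antisense_seq,
    gene_class = library$gene_class
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write plate layout tables
#'
#' `layout.csv` columns: `plate_id`, `well`, `content_type`, `gene_symbol`,
#' `sirna_index` (an optional `replicate_index` column is preserved; when
#' absent it is derived from the order of first appearance of plate ids).
#' Well addresses are canonicalized; duplicate wells within a plate and
#' unknown content types are integrity errors.
#'
#' @param path Path to the CSV file.
#' @return A layouts tibble.
#' @export
read_layouts <- function(path) {
  df <- read_screen_csv(path, c("plate_id", "well", "content_type",
                                "gene_symbol", "sirna_index"))
  df$well <- canonical_well(df$well)
  bad_type <- setdiff(unique(df$content_type), CONTENT_TYPES)
  if (length(bad_type) > 0L) {
    stop("unknown content_type(s): ", paste(bad_type, collapse = ", "),
         "; allowed: ", paste(CONTENT_TYPES, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("plate_id", "well")])) {
    stop("duplicate well address within a plate in ", path, call. = FALSE)
  }
  if (!"replicate_index" %in% names(df)) {
    df$replicate_index <- match(df$plate_id, unique(df$plate_id))
  }
  df$sirna_index <- as.integer(df$sirna_index)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$gene_symbol[!nzchar(df$gene_symbol) | is.na(df$gene_symbol)] <- NA_character_
  df[, c("plate_id", "replicate_index", "well", "content_type",
         "gene_symbol", "sirna_index")]
}

#' @rdname read_layouts
#' @param layouts A layouts tibble.
#' @export
write_layouts <- function(layouts, path) {
  out <- layouts[, c("plate_id", "well", "content_type",
                     "gene_symbol", "sirna_index", "replicate_index")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write per-well measurement tables
#'
#' `measurements.csv` columns: `plate_id`, `well`, `channel`, `value`.
#' Values must be non-negative reals; channels must be one of `fluc_ires`,
#' `fluc_cap`, `atp`; duplicate (plate, well, channel) rows are rejected.
#' Missing wells are permitted (dropped reactions are handled downstream).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `plate_id`, `well`, `channel`, `raw_value`.
#' @export
read_measurements <- function(path) {
  df <- read_screen_csv(path, c("plate_id", "well", "channel", "value"))
  df$well <- canonical_well(df$well)
  bad_chan <- setdiff(unique(df$channel), CHANNELS)
  if (length(bad_chan) > 0L) {
    stop("unknown channel label(s): ", paste(bad_chan, collapse = ", "),
         "; allowed: ", paste(CHANNELS, collapse = ", "), call. = FALSE)
  }
  value <- as.numeric(df$value)
  if (any(is.na(value))) {
    stop("non-numeric measurement value(s) in ", path, call. = FALSE)
  }
  if (any(value < 0)) {
    stop("negative measurement value(s) in ", path,
         " (luminescence counts must be >= 0)", call. = FALSE)
  }
  if (anyDuplicated(df[, c("plate_id", "well", "channel")])) {
    stop("duplicate (plate_id, well, channel) measurement in ", path,
         call. = FALSE)
  }
  tibble::tibble(plate_id = df$plate_id, well = df$well,
                 channel = df$channel, raw_value = value)
}

#' @rdname read_measurements
#' @param measurements A measurements tibble (`plate_id`, `well`, `channel`,
#'   `raw_value`).
#' @export
write_measurements <- function(measurements, path) {
  out <- data.frame(
    plate_id = measurements$plate_id,
    well = canonical_well(measurements$well),
    channel = measurements$channel,
    value = measurements$raw_value
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
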