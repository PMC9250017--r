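#' @useDynLib clockvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois rlnorm rgeom runif t.test ks.test shapiro.test
#'   sd var acf
#' @importFrom utils read.csv write.csv head
NULL

CELL_TABLE_COLUMNS <- c("embryo_id", "genotype", "half", "slice_index",
                        "cell_id", "her1_count", "her7_count", "volume")

#' Construct a validated per-cell smFISH count table
#'
#' A cell table holds one row per segmented cell: absolute `her1` and `her7`
#' transcript counts from single-molecule FISH, the cell volume, and the
#' cell's position as a single-cell-wide posterior-to-anterior slice index
#' within one half (left or right) of the presomitic mesoderm. Cells sharing
#' an `(embryo_id, half, slice_index)` key are at the same oscillation phase
#' and form the population over which variability is computed.
#'
#' @param df data.frame with columns `embryo_id`, `genotype`, `half`
#'   (`"left"`/`"right"`), `slice_index` (integer >= 0, 0 = most posterior),
#'   `cell_id`, `her1_count`, `her7_count` (non-negative), `volume`
#'   (positive, um^3).
#' @param volume_corrected logical; `TRUE` when counts have been divided by
#'   cell volume (concentrations, molecules/um^3). Raw tables require integer
#'   counts; corrected tables allow real values.
#' @param provenance optional character scalar recording the source.
#' @return A `cell_table` (a data.frame subclass).
#' @export
cell_table <- function(df, volume_corrected = FALSE, provenance = NA_character_) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("cell table is empty", call. = FALSE)
  }
  df <- as.data.frame(df)[CELL_TABLE_COLUMNS]
  df$embryo_id <- as.character(df$embryo_id)
  df$genotype  <- as.character(df$genotype)
  df$half      <- as.character(df$half)
  df$cell_id   <- as.character(df$cell_id)
  df$slice_index <- as.integer(df$slice_index)
  df$her1_count <- as.numeric(df$her1_count)
  df$her7_count <- as.numeric(df$her7_count)
  df$volume <- as.numeric(df$volume)

  problems <- validate_cell_rows(df, volume_corrected)
  if (length(problems) > 0L) {
    stop("invalid cell table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(df,
            class = c("cell_table", "data.frame"),
            volume_corrected = volume_corrected,
            provenance = provenance)
}

validate_cell_rows <- function(df, volume_corrected) {
  problems <- character(0)
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      sprintf("%s on row(s) %s", what,
              paste(head(idx, 10L), collapse = ", "))
    } else character(0)
  }
  problems <- c(problems,
    bad_row(!df$half %in% c("left", "right"), "half must be 'left' or 'right'"),
    bad_row(is.na(df$slice_index) | df$slice_index < 0L, "negative or missing slice_index"),
    bad_row(is.na(df$her1_count) | df$her1_count < 0, "negative or missing her1_count"),
    bad_row(is.na(df$her7_count) | df$her7_count < 0, "negative or missing her7_count"),
    bad_row(is.na(df$volume) | df$volume <= 0, "non-positive or missing volume"))
  if (!volume_corrected) {
    problems <- c(problems,
      bad_row(df$her1_count != floor(df$her1_count), "non-integer her1_count"),
      bad_row(df$her7_count != floor(df$her7_count), "non-integer her7_count"))
  }
  key <- paste(df$embryo_id, df$half, df$slice_index, df$cell_id, sep = "\r")
  problems <- c(problems,
    bad_row(duplicated(key), "duplicate (embryo_id, half, slice_index, cell_id)"))
  problems
}

#' Read a per-cell smFISH count table from delimited text
#'
#' @param path path to a CSV or TSV file whose header names the canonical
#'   columns (see [cell_table()]).
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param volume_corrected logical; set `TRUE` if the file stores
#'   volume-normalized concentrations rather than integer counts.
#' @return A validated [cell_table()].
#' @export
read_cell_table <- function(path, dialect = c("csv", "tsv"),
                            volume_corrected = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  df <- tryCatch(
    read.csv(path, sep = sep, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty input: ", path, call. = FALSE)
  # numeric conversion is locale-independent: read.csv + as.numeric use the
  # C decimal point and accept scientific notation
  for (col in c("slice_index", "her1_count", "her7_count", "volume")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  cell_table(df, volume_corrected = volume_corrected, provenance = path)
}

#' Write a cell table as canonical CSV
#'
#' The header is exactly
#' `embryo_id,genotype,half,slice_index,cell_id,her1_count,her7_count,volume`.
#'
#' @param table a [cell_table()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(table, path) {
  if (!inherits(table, "cell_table")) {
    table <- cell_table(table)
  }
  if (nrow(table) == 0L) stop("refusing to write an empty cell table",
                              call. = FALSE)
  df <- as.data.frame(table)[CELL_TABLE_COLUMNS]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a spreadsheet export with non-canonical column names
#'
#' Published per-cell tables rarely use one column layout; this maps a
#' user-supplied `name -> canonical` column mapping onto the canonical
#' schema, filling `genotype` and `half` with constants when the source
#' lacks them.
#'
#' @param path delimited text file (CSV/TSV export of a spreadsheet).
#' @param mapping named character vector: names are source columns, values
#'   are canonical column names (see [cell_table()]).
#' @param defaults named list of constant values for canonical columns the
#'   source does not carry (e.g. `list(genotype = "wt", half = "right")`).
#' @param dialect `"csv"` or `"tsv"`.
#' @return A validated [cell_table()].
#' @export
import_mapped_table <- function(path, mapping, defaults = list(),
                                dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  missing_src <- setdiff(names(mapping), names(df))
  if (length(missing_src) > 0L) {
    stop("source file lacks mapped column(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  out <- df[names(mapping)]
  names(out) <- unname(mapping)
  for (col in names(defaults)) out[[col]] <- defaults[[col]]
  if (!"cell_id" %in% names(out)) {
    out$cell_id <- as.character(seq_len(nrow(out)))
  }
  cell_table(out, provenance = path)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "<cell_table> %d cells, %d embryo(s), genotype(s): %s%s\n",
    nrow(x), length(unique(x$embryo_id)),
    paste(unique(x$genotype), collapse = ", "),
    if (isTRUE(attr(x, "volume_corrected"))) " [volume-corrected]" else ""))
  NextMethod()
}
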