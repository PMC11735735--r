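#' Read a tag count matrix from a Matrix Market directory
#'
#' Reads a CellRanger-style directory holding a Matrix Market coordinate file
#' (`matrix.mtx`), a features table (`features.tsv`, one feature per line; if
#' the table has several columns the second is taken as the display name, as in
#' CellRanger output), and a barcodes table (`barcodes.tsv`). Each file may be
#' gzip-compressed (`.gz` suffix). The matrix on disk is features x cells.
#'
#' @param path directory containing the three files.
#' @return a [tag_counts] matrix (tags x cells).
#' @seealso [write_tag_mtx()], [read_tag_dense()]
#' @export
read_tag_mtx <- function(path) {
  if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
  mtx <- find_part(path, c("matrix.mtx", "matrix.mtx.gz"))
  feats <- find_part(path, c("features.tsv", "features.tsv.gz",
                             "genes.tsv", "genes.tsv.gz"))
  bcs <- find_part(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)
  ft <- utils::read.table(feats, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  tag_names <- if (ncol(ft) >= 2) ft[[2]] else ft[[1]]
  bc <- utils::read.table(bcs, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")[[1]]
  if (nrow(m) != length(tag_names)) {
    stop("matrix has ", nrow(m), " rows but features table has ",
         length(tag_names), " entries", call. = FALSE)
  }
  if (ncol(m) != length(bc)) {
    stop("matrix has ", ncol(m), " columns but barcodes table has ",
         length(bc), " entries", call. = FALSE)
  }
  tag_counts(as.matrix(m), tag_names = tag_names, barcodes = bc)
}

find_part <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("missing ", candidates[[1]], " (or .gz) in ", dir, call. = FALSE)
}

#' Write a tag count matrix as a Matrix Market directory
#'
#' Inverse of [read_tag_mtx()]: writes `matrix.mtx` (features x cells, sparse
#' coordinate format), `features.tsv` and `barcodes.tsv` into `path`.
#'
#' @param x a [tag_counts] matrix (or plain named matrix).
#' @param path output directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_tag_mtx <- function(x, path) {
  x <- as_tag_counts(x)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(unclass(x), sparse = TRUE)
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(rownames(x), file.path(path, "features.tsv"))
  writeLines(colnames(x), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a tag count matrix from dense delimited text
#'
#' The first row holds cell barcodes, the first column tag names; fields are
#' separated by a tab (default) or comma (`.csv`). The header row may either
#' carry a leading field for the tag-name column or omit it.
#'
#' @param path file path (gzip transparently supported via `.gz`).
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return a [tag_counts] matrix.
#' @export
read_tag_dense <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- guess_sep(path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("dense matrix needs a header and rows", call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  body_len <- unique(lengths(fields[-1]))
  if (length(body_len) != 1) {
    stop("ragged rows: row lengths ", paste(sort(body_len), collapse = ", "),
         call. = FALSE)
  }
  header <- fields[[1]]
  n_cells <- body_len - 1L
  if (length(header) == n_cells + 1L) header <- header[-1] # leading corner field
  if (length(header) != n_cells) {
    stop("header has ", length(header), " barcodes but rows have ",
         n_cells, " value fields", call. = FALSE)
  }
  rows <- fields[-1]
  tag_names <- vapply(rows, `[[`, character(1), 1)
  vals <- vapply(rows, function(f) as.numeric(f[-1]), numeric(n_cells))
  m <- if (n_cells == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(m)) stop("non-numeric entries in dense matrix", call. = FALSE)
  tag_counts(m, tag_names = tag_names, barcodes = header)
}

#' Write a tag count matrix as dense delimited text
#'
#' @inheritParams write_tag_mtx
#' @param path output file; `.csv` selects comma separation, anything else tab.
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_tag_dense <- function(x, path, sep = NULL) {
  x <- as_tag_counts(x)
  if (is.null(sep)) sep <- guess_sep(path)
  header <- paste(c("tag", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], as.character(unclass(x)[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

guess_sep <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a per-cell label table
#'
#' Labels are read from a CSV with header `barcode,label,confidence`
#' (confidence optional). When `vocabulary` is given, each label must be one of
#' its entries (tag names plus `"Doublet"` and `"Negative"`).
#'
#' @param path CSV file.
#' @param vocabulary optional character vector of allowed labels.
#' @return data.frame with columns `barcode`, `label` and, when present,
#'   `confidence`.
#' @export
read_labels <- function(path, vocabulary = NULL) {
  df <- utils::read.csv(path, colClasses = NA, stringsAsFactors = FALSE)
  need <- c("barcode", "label")
  if (!all(need %in% names(df))) {
    stop("label table must have columns barcode and label", call. = FALSE)
  }
  df$barcode <- as.character(df$barcode)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$barcode)) stop("duplicate barcodes in label table",
                                      call. = FALSE)
  check_vocab(df$label, vocabulary)
  if ("confidence" %in% names(df)) df$confidence <- as.numeric(df$confidence)
  df
}

#' Write a per-cell label table
#'
#' Accepts either a [demux_ensemble()] result or a data.frame with columns
#' `barcode`, `label` and optionally `confidence`; writes CSV with header
#' `barcode,label,confidence` readable by [read_labels()].
#'
#' @param x labels (demux result or data.frame).
#' @param path output CSV path.
#' @param vocabulary optional allowed label set; a demux result supplies its
#'   own (its tag names plus Doublet/Negative).
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path, vocabulary = NULL) {
  if (inherits(x, "demux_result")) {
    if (is.null(vocabulary)) vocabulary <- label_vocabulary(x$tag_names)
    x <- as.data.frame(x)
  }
  if (!is.data.frame(x) || !all(c("barcode", "label") %in% names(x))) {
    stop("need a demux result or a data.frame with barcode and label columns",
         call. = FALSE)
  }
  check_vocab(x$label, vocabulary)
  out <- data.frame(barcode = as.character(x$barcode),
                    label = as.character(x$label),
                    confidence = if ("confidence" %in% names(x))
                      as.numeric(x$confidence) else NA_real_)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_vocab <- function(labels, vocabulary) {
  if (is.null(vocabulary)) return(invisible())
  bad <- setdiff(unique(labels), vocabulary)
  if (length(bad)) {
    stop("labels outside the declared vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible()
}
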