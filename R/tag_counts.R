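#' Construct a validated tag-by-cell count matrix
#'
#' A `tag_counts` object is an integer matrix of hashtag read counts with
#' `M >= 2` tags as rows and `N` cells as columns. Row names are tag names,
#' column names are cell barcodes; both must be unique and non-empty.
#'
#' @param counts numeric matrix (or coercible) of non-negative integer read
#'   counts, tags x cells.
#' @param tag_names character vector of length `nrow(counts)`; defaults to the
#'   row names of `counts`.
#' @param barcodes character vector of length `ncol(counts)`; defaults to the
#'   column names of `counts`.
#' @return an integer matrix of class `tag_counts` with tag names as row names
#'   and barcodes as column names.
#' @examples
#' m <- matrix(c(50, 0, 3, 40), nrow = 2,
#'             dimnames = list(c("HTO1", "HTO2"), c("cell1", "cell2")))
#' tag_counts(m)
#' @export
tag_counts <- function(counts, tag_names = rownames(counts),
                       barcodes = colnames(counts)) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("tag counts must be numeric", call. = FALSE)
  }
  if (is.null(tag_names) || is.null(barcodes)) {
    stop("tag names and barcodes are required", call. = FALSE)
  }
  tag_names <- as.character(tag_names)
  barcodes <- as.character(barcodes)
  if (length(tag_names) != nrow(counts)) {
    stop("number of tag names (", length(tag_names),
         ") does not match number of matrix rows (", nrow(counts), ")",
         call. = FALSE)
  }
  if (length(barcodes) != ncol(counts)) {
    stop("number of barcodes (", length(barcodes),
         ") does not match number of matrix columns (", ncol(counts), ")",
         call. = FALSE)
  }
  if (anyDuplicated(tag_names)) stop("duplicate tag names", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes", call. = FALSE)
  if (nrow(counts) < 2) {
    stop("demultiplexing needs at least 2 tags", call. = FALSE)
  }
  if (anyNA(counts)) stop("tag counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("tag counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("tag counts must be integral", call. = FALSE)
  }
  counts <- matrix(as.integer(round(counts)), nrow = nrow(counts),
                   dimnames = list(tag_names, barcodes))
  class(counts) <- c("tag_counts", class(matrix()))
  counts
}

#' @export
print.tag_counts <- function(x, ...) {
  cat(sprintf("tag_counts: %d tags x %d cells (total reads: %s)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  cat("tags:", paste(utils::head(rownames(x), 8), collapse = ", "),
      if (nrow(x) > 8) "..." else "", "\n")
  invisible(x)
}

# Coerce any accepted matrix input (tag_counts, plain matrix with dimnames)
# to a validated tag_counts object.
as_tag_counts <- function(x) {
  if (inherits(x, "tag_counts")) return(x)
  tag_counts(x)
}

# Label vocabulary for a set of tag names
label_vocabulary <- function(tag_names) {
  c(tag_names, "Doublet", "Negative")
}

# Evaluate an expression with a locally seeded RNG, restoring (or removing)
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
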