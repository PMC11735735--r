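#' Normalize a tag count matrix
#'
#' Four normalizations of the raw tag counts \eqn{r_{ij}} (tag \eqn{i}, cell
#' \eqn{j}); all logarithms are natural:
#'
#' \describe{
#'   \item{`lognorm`}{\eqn{n_{ij} = \ln(r_{ij}\,s / S_j + 1)} with \eqn{S_j}
#'     the cell's total tag count and \eqn{s} the scale factor (default
#'     \eqn{10^4}). Removes per-cell sequencing-depth variability.}
#'   \item{`rc`}{relative counts, \eqn{n_{ij} = r_{ij}\,s / S_j}; columns of
#'     cells with positive totals sum to \eqn{s}.}
#'   \item{`clr_exp_bias`}{per-tag centered log-ratio,
#'     \eqn{n_{ij} = \ln(r_{ij}/G_i + 1)} with \eqn{G_i} the geometric mean of
#'     tag \eqn{i} across all cells. Removes tag-specific (ambient) baseline
#'     bias; monotone within each tag, so it never changes per-tag rankings.}
#'   \item{`clr_seq_depth`}{per-cell centered log-ratio,
#'     \eqn{n_{ij} = \ln(r_{ij}/G_j + 1)} with \eqn{G_j} the geometric mean of
#'     all tags in cell \eqn{j}. Treats each cell's tags as compositional and
#'     removes depth variability; the recommended default for clustering.}
#' }
#'
#' Counts contain zeros, so the geometric means use a pseudocount of one:
#' \eqn{G = \exp(\mathrm{mean}(\ln(1 + r)))} over the row (per tag) or column
#' (per cell). Cells with a zero total get all-zero `lognorm`/`rc` values and
#' a warning (they are empty droplets; downstream labeling calls them
#' Negative).
#'
#' @param x a [tag_counts] matrix (or plain named count matrix).
#' @param method one of `"clr_seq_depth"`, `"clr_exp_bias"`, `"lognorm"`,
#'   `"rc"`.
#' @param scale scale factor used by `lognorm` and `rc` (default `1e4`).
#' @return a numeric matrix of class `norm_tags`, same shape and dimnames as
#'   `x`, with attributes `method` and `scale_factor`.
#' @examples
#' m <- tag_counts(matrix(c(30, 10, 0, 8), 2,
#'                        dimnames = list(c("A", "B"), c("c1", "c2"))))
#' normalize_tags(m, "rc")
#' @export
normalize_tags <- function(x,
                           method = c("clr_seq_depth", "clr_exp_bias",
                                      "lognorm", "rc"),
                           scale = 1e4) {
  method <- match.arg(method)
  x <- as_tag_counts(x)
  r <- unclass(x)
  storage.mode(r) <- "double"
  n <- switch(method,
    lognorm = depth_scaled(r, scale, log = TRUE),
    rc = depth_scaled(r, scale, log = FALSE),
    clr_exp_bias = {
      g <- exp(rowMeans(log1p(r)))
      log1p(r / g)
    },
    clr_seq_depth = {
      g <- exp(colMeans(log1p(r)))
      log1p(sweep(r, 2, g, "/"))
    }
  )
  dimnames(n) <- dimnames(x)
  structure(n, class = c("norm_tags", class(matrix())),
            method = method,
            scale_factor = if (method %in% c("lognorm", "rc")) scale else NA_real_)
}

depth_scaled <- function(r, scale, log) {
  s <- colSums(r)
  empty <- s == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total tag counts; ",
            "normalized values set to 0", call. = FALSE)
    s[empty] <- 1 # avoids 0/0; numerators in those columns are all zero
  }
  n <- sweep(r * scale, 2, s, "/")
  if (log) log1p(n) else n
}

#' @export
print.norm_tags <- function(x, ...) {
  cat(sprintf("norm_tags: %d tags x %d cells, method = %s\n",
              nrow(x), ncol(x), attr(x, "method")))
  invisible(x)
}

#' @rdname normalize_tags
#' @export
log_normalize <- function(x, scale = 1e4) normalize_tags(x, "lognorm", scale)

#' @rdname normalize_tags
#' @export
relative_counts <- function(x, scale = 1e4) normalize_tags(x, "rc", scale)

#' @rdname normalize_tags
#' @export
clr_per_tag <- function(x) normalize_tags(x, "clr_exp_bias")

#' @rdname normalize_tags
#' @export
clr_per_cell <- function(x) normalize_tags(x, "clr_seq_depth")

as_norm_tags <- function(x) {
  if (inherits(x, "norm_tags")) return(x)
  if (is.matrix(x) && is.numeric(x)) {
    return(structure(x, class = c("norm_tags", class(matrix())),
                     method = "unknown", scale_factor = NA_real_))
  }
  stop("expected a normalized tag matrix", call. = FALSE)
}
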