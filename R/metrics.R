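#' Per-tag F-scores of a demultiplexing prediction
#'
#' For each tag class \eqn{t} present in the truth, precision and recall of
#' the binary problem (`pred == t` vs `truth == t`) are computed and combined
#' into \eqn{F = 2PR/(P+R)} (0 when \eqn{P+R=0}). The reported average is the
#' macro-average over tag classes; `Doublet` and `Negative` are not averaged
#' classes but wrong calls against them still cost precision/recall.
#'
#' @param pred,truth label tables (data.frames with `barcode`, `label`) over
#'   the same barcodes, e.g. `as.data.frame(demux_ensemble(...))` and a
#'   [simulate_dataset()] `$truth`.
#' @param tags tag classes to score; default: all truth labels that are
#'   neither `"Doublet"` nor `"Negative"`, sorted.
#' @param average `"macro"` (default) or `"micro"` (pooled counts over tags).
#' @return list with `per_tag_f` (named numeric) and `average_f`.
#' @export
f_score <- function(pred, truth, tags = NULL, average = c("macro", "micro")) {
  average <- match.arg(average)
  al <- align_labels(pred, truth)
  if (is.null(tags)) {
    tags <- sort(setdiff(unique(al$truth), c("Doublet", "Negative")))
  }
  cm <- vapply(tags, function(t) {
    tp <- sum(al$pred == t & al$truth == t)
    fp <- sum(al$pred == t & al$truth != t)
    fn <- sum(al$pred != t & al$truth == t)
    c(tp = tp, fp = fp, fn = fn)
  }, numeric(3))
  f1 <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  per_tag <- vapply(seq_along(tags),
                    function(i) f1(cm["tp", i], cm["fp", i], cm["fn", i]),
                    numeric(1))
  names(per_tag) <- tags
  avg <- if (average == "macro") mean(per_tag)
         else f1(sum(cm["tp", ]), sum(cm["fp", ]), sum(cm["fn", ]))
  list(per_tag_f = per_tag, average_f = avg)
}

align_labels <- function(pred, truth) {
  pred <- as_label_df(pred)
  truth <- as_label_df(truth)
  if (nrow(pred) != nrow(truth) ||
      !setequal(pred$barcode, truth$barcode)) {
    stop("prediction and truth must cover the same barcodes", call. = FALSE)
  }
  idx <- match(truth$barcode, pred$barcode)
  list(pred = pred$label[idx], truth = truth$label, barcode = truth$barcode)
}

as_label_df <- function(x) {
  if (inherits(x, "demux_result")) x <- as.data.frame(x)
  if (!is.data.frame(x) || !all(c("barcode", "label") %in% names(x))) {
    stop("expected a label table with barcode and label columns",
         call. = FALSE)
  }
  x
}

#' Doublet-to-singlet misclassification rate
#'
#' Fraction of ground-truth doublets that the prediction assigned to a sample
#' (any tag name); predicting `Doublet` or `Negative` for a true doublet does
#' not count. Defined as 0 (with a warning) when the truth holds no doublets.
#'
#' @inheritParams f_score
#' @return a rate in `[0, 1]`.
#' @export
doublet_misclassification <- function(pred, truth) {
  al <- align_labels(pred, truth)
  doub <- al$truth == "Doublet"
  if (!any(doub)) {
    warning("no doublets in ground truth; rate defined as 0", call. = FALSE)
    return(0)
  }
  mean(!al$pred[doub] %in% c("Doublet", "Negative"))
}

#' Precision-recall separability (AUCPR) of one tag
#'
#' Quantifies how well a tag's counts separate the cells that carry it from
#' the cells that do not. Ground-truth doublets are excluded; positives are
#' cells whose truth label equals `tag`, everything else is negative. Cells
#' are ranked by the tag's (raw or normalized) value and the area under the
#' precision-recall curve is computed over all distinct thresholds, tied
#' scores entering at a single threshold.
#'
#' @param x tag matrix, raw [tag_counts] or `norm_tags`.
#' @param truth ground-truth label table (`barcode`, `label`).
#' @param tag tag name (must be a row of `x`).
#' @param interpolation `"nonlinear"` (default) integrates the exact
#'   hyperbolic precision path between operating points (the standard
#'   PR-curve interpolation for imbalanced problems); `"step"` uses
#'   right-endpoint rectangles (average-precision style).
#' @return AUCPR in `[0, 1]`, or `NA` (with a warning) when no positives
#'   remain after doublet exclusion.
#' @export
aucpr_separability <- function(x, truth, tag,
                               interpolation = c("nonlinear", "step")) {
  interpolation <- match.arg(interpolation)
  m <- as.matrix(x)
  if (!tag %in% rownames(m)) stop("unknown tag: ", tag, call. = FALSE)
  truth <- as_label_df(truth)
  idx <- match(truth$barcode, colnames(m))
  if (anyNA(idx)) stop("truth barcodes missing from the matrix", call. = FALSE)
  keep <- truth$label != "Doublet"
  scores <- m[tag, idx[keep]]
  positive <- truth$label[keep] == tag
  if (!any(positive)) {
    warning("no positive cells for tag ", tag, " after doublet exclusion",
            call. = FALSE)
    return(NA_real_)
  }
  if (!any(!positive)) {
    warning("no negative cells for tag ", tag, call. = FALSE)
    return(NA_real_)
  }
  aucpr(scores, positive, interpolation)
}

# Area under the precision-recall curve.
#
# Operating points are the cumulative (TP, FP) after each distinct score,
# descending, anchored at (0, 0). "nonlinear" integrates precision exactly
# along the linear (TP, FP) path between consecutive points:
#   int_0^1 (TPa + s*dTP) / (Ca + s*dC) ds
# with C = TP + FP, which has the closed form
#   dTP/dC + (TPa - Ca*dTP/dC)/dC * log((Ca + dC)/Ca).
aucpr <- function(scores, positive, interpolation = "nonlinear") {
  stopifnot(length(scores) == length(positive))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- positive[o]
  last <- cumsum(rle(s)$lengths) # last index of each distinct score
  tp <- c(0, cumsum(p)[last])
  fp <- c(0, cumsum(!p)[last])
  n_pos <- sum(positive)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    area <- area + pr_segment_area(tp[i], fp[i], tp[i + 1], fp[i + 1],
                                   n_pos, interpolation)
  }
  min(max(area, 0), 1) # guard rounding at the [0, 1] bounds
}

pr_segment_area <- function(tpa, fpa, tpb, fpb, n_pos, interpolation) {
  dtp <- tpb - tpa
  if (dtp == 0) return(0)
  if (interpolation == "step") {
    return((dtp / n_pos) * tpb / (tpb + fpb))
  }
  ca <- tpa + fpa
  dc <- (tpb + fpb) - ca
  mean_prec <- if (ca == 0) {
    dtp / dc # path from the origin has constant precision dTP/dC
  } else if (dc == 0) {
    (tpa + dtp / 2) / ca
  } else {
    dtp / dc + (tpa - ca * dtp / dc) / dc * log((ca + dc) / ca)
  }
  (dtp / n_pos) * mean_prec
}

#' Baseline expression variability of a dataset
#'
#' Coefficient of variation (sample sd / mean) of the per-tag medians of
#' \eqn{\ln(\mathrm{count} + 1)} across cells. High values indicate strong
#' tag-specific ambient background (some tags elevated in all cells).
#'
#' @param x raw [tag_counts] matrix.
#' @return CV (>= 0), or `NA` with a warning when the mean of medians is 0.
#' @export
baseline_expression_variability <- function(x) {
  m <- as.matrix(x)
  med <- apply(log1p(m), 1, stats::median)
  if (mean(med) == 0) {
    warning("mean of per-tag medians is 0; statistic undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::sd(med) / mean(med)
}

#' Sequencing depth variability of a dataset
#'
#' Ratio of the 99th to the 1st percentile of per-cell total tag counts
#' (linear-interpolation quantiles). Values much above 1 indicate that cell
#' totals span a wide range, which degrades raw-count comparisons across
#' cells.
#'
#' @param x raw [tag_counts] matrix.
#' @return ratio (>= 1), `Inf` with a warning when the 1st percentile is 0.
#' @export
sequencing_depth_variability <- function(x) {
  totals <- colSums(as.matrix(x))
  q <- stats::quantile(totals, c(0.01, 0.99), names = FALSE)
  if (q[1] == 0) {
    warning("1st percentile of totals is 0; variability infinite",
            call. = FALSE)
    return(Inf)
  }
  q[2] / q[1]
}

#' Full evaluation report of a demultiplexing prediction
#'
#' Assembles per-tag and average F-score, doublet-to-singlet
#' misclassification, per-tag AUCPR separability (on the supplied matrix,
#' typically raw counts), and the two dataset noise metrics into one
#' JSON-serializable report.
#'
#' @inheritParams f_score
#' @param x raw [tag_counts] matrix of the dataset.
#' @return list of class `evaluation_report`; tags with undefined AUCPR are
#'   reported as `NA` (serialized as `null`, not 0).
#' @seealso [write_report()]
#' @export
evaluate_demux <- function(pred, truth, x) {
  x <- as_tag_counts(x)
  fs <- f_score(pred, truth)
  tags <- names(fs$per_tag_f)
  auc <- vapply(tags, function(t) {
    tryCatch(suppressWarnings(aucpr_separability(x, truth, t)),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(per_tag_f = as.list(fs$per_tag_f),
                 average_f = fs$average_f,
                 doublet_to_singlet_rate = doublet_misclassification(pred, truth),
                 per_tag_aucpr = as.list(auc),
                 baseline_expression_variability =
                   suppressWarnings(baseline_expression_variability(x)),
                 sequencing_depth_variability =
                   suppressWarnings(sequencing_depth_variability(x))),
            class = "evaluation_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate_demux()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  average F-score: %.4f\n", x$average_f))
  cat(sprintf("  doublet-to-singlet rate: %.4f\n", x$doublet_to_singlet_rate))
  cat(sprintf("  per-tag F: %s\n",
              paste(sprintf("%s=%.3f", names(x$per_tag_f),
                            unlist(x$per_tag_f)), collapse = " ")))
  cat(sprintf("  baseline expression variability: %.4f\n",
              x$baseline_expression_variability))
  cat(sprintf("  sequencing depth variability: %.2f\n",
              x$sequencing_depth_variability))
  invisible(x)
}
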