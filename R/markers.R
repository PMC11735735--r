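# Marker statistics for every (cluster, tag) contrast.
#
# One-vs-rest two-sided Wilcoxon rank-sum test on the normalized values of
# each tag, vectorized over clusters: each tag's values are ranked once and
# the rank-sum statistic for every cluster is read off the shared ranking.
# Normal approximation with tie correction and continuity correction,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE).
#
# logFC is the fold change of de-normalized means with pseudocount 1:
# ln( (mean(expm1(n_in)) + 1) / (mean(expm1(n_out)) + 1) ).
#
# Clusters of size 1 give a degenerate test and are skipped with a warning.
marker_stats <- function(N, clusters) {
  m <- as.matrix(N)
  cl <- cluster_vector(clusters, ncol(m))
  ids <- sort(unique(cl))
  sizes <- table(factor(cl, levels = ids))
  singletons <- ids[sizes == 1]
  if (length(singletons)) {
    warning("skipping ", length(singletons),
            " singleton cluster(s): rank-sum test degenerate", call. = FALSE)
    ids <- setdiff(ids, singletons)
  }
  n <- ncol(m)
  out <- vector("list", length(ids) * nrow(m))
  slot <- 0L
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    r <- rank(v)
    ties <- table(v)
    tie_term <- sum(ties^3 - ties)
    expr_pos <- v > 0
    denorm <- expm1(v)
    for (c_id in ids) {
      inC <- cl == c_id
      n1 <- sum(inC)
      n2 <- n - n1
      u <- sum(r[inC]) - n1 * (n1 + 1) / 2
      mu <- n1 * n2 / 2
      sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1))))
      if (sigma == 0) {
        p <- 1
      } else {
        z <- u - mu
        z <- (z - sign(z) * 0.5) / sigma
        p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
      }
      lfc <- log((mean(denorm[inC]) + 1) / (mean(denorm[!inC]) + 1))
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        cluster_id = c_id, tag = rownames(m)[i], log_fc = lfc, p_value = p,
        fraction_expressed_in_cluster = mean(expr_pos[inC]))
    }
  }
  res <- do.call(rbind, out[seq_len(slot)])
  if (is.null(res)) {
    res <- data.frame(cluster_id = integer(), tag = character(),
                      log_fc = numeric(), p_value = numeric(),
                      fraction_expressed_in_cluster = numeric())
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "bonferroni")
  res
}

cluster_vector <- function(clusters, n_cells) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.integer(clusters)
  if (length(cl) != n_cells) {
    stop("cluster assignment length does not match number of cells",
         call. = FALSE)
  }
  cl
}

#' Find marker tags per cluster
#'
#' For each (cluster, tag) pair a one-vs-rest two-sided Wilcoxon rank-sum test
#' is run on the normalized tag values. A record is retained as a marker when
#' all three hold: the tag is detected (count > 0) in every cell of the
#' cluster, the Bonferroni-adjusted p-value is below 0.05, and the log
#' fold-change of de-normalized cluster means (natural log, pseudocount 1) is
#' at least `log_fc_threshold`.
#'
#' @param N normalized tag matrix ([normalize_tags()]).
#' @param clusters a [louvain()] assignment (or integer vector per cell).
#' @param log_fc_threshold minimum log fold-change for retention.
#' @param p_adjust multiple-testing correction across all (cluster, tag) tests
#'   of the pass: `"bonferroni"` (default) or `"BH"`.
#' @return data.frame of retained markers with columns `cluster_id`, `tag`,
#'   `log_fc`, `p_value`, `p_adjusted`, `fraction_expressed_in_cluster`.
#' @export
find_markers <- function(N, clusters, log_fc_threshold = 0,
                         p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stats <- marker_stats(N, clusters)
  if (p_adjust != "bonferroni") {
    stats$p_adjusted <- stats::p.adjust(stats$p_value, method = p_adjust)
  }
  filter_markers(stats, log_fc_threshold)
}

filter_markers <- function(stats, log_fc_threshold) {
  keep <- stats$fraction_expressed_in_cluster == 1 &
    stats$p_adjusted < 0.05 &
    stats$log_fc >= log_fc_threshold
  res <- stats[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label cells from per-cluster markers
#'
#' Applies the cluster-to-label rule: a cluster with no marker tags is
#' `"Negative"`, one with two or more markers is `"Doublet"`, and one with
#' exactly one marker takes that tag's name. Every member cell inherits its
#' cluster's label.
#'
#' @param clusters a [louvain()] assignment (or integer vector).
#' @param markers retained markers from [find_markers()].
#' @return character vector of per-cell labels.
#' @export
label_from_markers <- function(clusters, markers) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else as.integer(clusters)
  ids <- sort(unique(cl))
  lab_by_cluster <- vapply(ids, function(c_id) {
    tags <- markers$tag[markers$cluster_id == c_id]
    if (length(tags) == 0) "Negative"
    else if (length(tags) > 1) "Doublet"
    else tags
  }, character(1))
  names(lab_by_cluster) <- as.character(ids)
  unname(lab_by_cluster[as.character(cl)])
}

#' Calibrate the marker log fold-change threshold to a target doublet rate
#'
#' Each candidate threshold is used to filter the (cluster, tag) marker table;
#' cells are labeled by [label_from_markers()] and the achieved doublet rate
#' (fraction of all cells labeled Doublet) is recorded. The candidate whose
#' achieved rate is closest to `target_rate` wins; ties go to the smallest
#' threshold. Marker statistics are computed once — only the filter varies
#' with the threshold.
#'
#' @inheritParams find_markers
#' @param target_rate expected doublet rate (see [expected_doublet_rate()]).
#' @param candidate_grid thresholds to scan (default `seq(0.1, 2, by = 0.1)`).
#' @return list with `chosen_log_fc`, `labels` (per-cell), `achieved_rate`,
#'   `markers` (retained at the chosen threshold) and `candidate_rates`
#'   (named numeric vector over the grid).
#' @export
calibrate_log_fc <- function(N, clusters, target_rate,
                             candidate_grid = seq(0.1, 2, by = 0.1),
                             p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(candidate_grid) == 0) stop("empty candidate grid", call. = FALSE)
  grid <- sort(as.numeric(candidate_grid))
  stats <- marker_stats(N, clusters)
  if (p_adjust != "bonferroni") {
    stats$p_adjusted <- stats::p.adjust(stats$p_value, method = p_adjust)
  }
  rates <- vapply(grid, function(th) {
    labs <- label_from_markers(clusters, filter_markers(stats, th))
    mean(labs == "Doublet")
  }, numeric(1))
  best <- which.min(abs(rates - target_rate)) # first minimum = smallest logFC
  chosen <- grid[best]
  markers <- filter_markers(stats, chosen)
  list(chosen_log_fc = chosen,
       labels = label_from_markers(clusters, markers),
       achieved_rate = rates[best],
       markers = markers,
       candidate_rates = stats::setNames(rates, format(grid)))
}
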