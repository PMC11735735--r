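#' Expected doublet rate for a standard droplet assay
#'
#' Estimates the anticipated fraction of same-droplet multi-sample captures
#' from the number of loaded cells and the number of multiplexed samples
#' (tags), using the loading-rate rule of thumb for a standard 10x 3' v3.1
#' assay:
#' \deqn{8 \times 10^{-6} \cdot n_{cells} \cdot (n_{tags} - 1) / n_{tags}.}
#' The \eqn{(T-1)/T} factor keeps only doublets made of two different samples,
#' the only kind a hashtag experiment can detect.
#'
#' @param n_cells number of cells.
#' @param n_tags number of tags (samples).
#' @return expected doublet rate (fraction of cells).
#' @examples
#' expected_doublet_rate(5000, 5) # 0.032
#' @export
expected_doublet_rate <- function(n_cells, n_tags) {
  if (length(n_cells) != 1 || length(n_tags) != 1 ||
      is.na(n_cells) || is.na(n_tags) || n_cells < 1 || n_tags < 1) {
    stop("n_cells and n_tags must be positive counts", call. = FALSE)
  }
  8e-6 * n_cells * (n_tags - 1) / n_tags
}

#' One demultiplexing run at a fixed (k, resolution)
#'
#' Composition of the pipeline pieces: [build_snn()] at `k`, [louvain()] at
#' `resolution`, then [calibrate_log_fc()] against `expected_rate`.
#'
#' @param N normalized tag matrix.
#' @param k kNN neighborhood size.
#' @param resolution Louvain resolution.
#' @param seed RNG seed for the clustering heuristic.
#' @param expected_rate target doublet rate for threshold calibration.
#' @param log_fc_grid candidate logFC thresholds.
#' @param prune SNN Jaccard pruning threshold.
#' @return object of class `run_labeling`: list with `k`, `resolution`,
#'   `seed`, `chosen_log_fc`, `labels`, `doublet_rate_achieved`,
#'   `n_clusters`.
#' @export
demux_single <- function(N, k, resolution, seed = 0L, expected_rate,
                         log_fc_grid = seq(0.1, 2, by = 0.1),
                         prune = 1 / 15) {
  snn <- build_snn(N, k = k, prune = prune)
  cl <- louvain(snn, resolution = resolution, seed = seed)
  cal <- calibrate_log_fc(N, cl, target_rate = expected_rate,
                          candidate_grid = log_fc_grid)
  structure(list(k = as.integer(k), resolution = resolution,
                 seed = as.integer(seed),
                 chosen_log_fc = cal$chosen_log_fc,
                 labels = cal$labels,
                 doublet_rate_achieved = cal$achieved_rate,
                 n_clusters = cl$n_clusters),
            class = "run_labeling")
}

#' Ensemble clustering-based demultiplexing
#'
#' The full workflow: the raw counts are normalized once, then a
#' demultiplexing run ([demux_single()]) is performed for every combination of
#' `k_grid` and `resolution_grid`. The grids are chosen to over-cluster, so
#' every group of cells sharing a tag combination can surface as its own
#' cluster at some setting. Each cell's final label is the modal label across
#' runs, and its confidence is the fraction of runs agreeing with that label.
#' Vote ties are resolved conservatively: `Negative` over `Doublet` over tag
#' names (alphabetically) — an ambiguous cell is not assigned to a sample.
#'
#' A failed run is dropped with a warning (the confidence denominator
#' shrinks); all runs failing is an error.
#'
#' @param x raw [tag_counts] matrix.
#' @param method normalization method (see [normalize_tags()]); per-cell CLR
#'   is the default, the most robust choice across contamination regimes.
#' @param k_grid kNN sizes (default `c(5, 10, 15, 20, 25, 30)`).
#' @param resolution_grid Louvain resolutions (default `1:4`).
#' @param expected_rate `"auto"` (default) computes
#'   [expected_doublet_rate()] from the matrix dimensions; or a number set by
#'   the user.
#' @param seed base seed; run `r` uses `seed + r - 1`.
#' @param scale scale factor for `lognorm`/`rc`.
#' @param log_fc_grid candidate logFC thresholds for calibration.
#' @param prune SNN pruning threshold.
#' @return object of class `demux_result`: list with `barcodes`, `tag_names`,
#'   `final_labels`, `confidence`, `runs` (list of `run_labeling`),
#'   `expected_doublet_rate`, `method`. `as.data.frame()` yields a
#'   `barcode,label,confidence` table for [write_labels()].
#' @export
demux_ensemble <- function(x,
                           method = c("clr_seq_depth", "clr_exp_bias",
                                      "lognorm", "rc"),
                           k_grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                           resolution_grid = 1:4,
                           expected_rate = "auto",
                           seed = 0L,
                           scale = 1e4,
                           log_fc_grid = seq(0.1, 2, by = 0.1),
                           prune = 1 / 15) {
  method <- match.arg(method)
  x <- as_tag_counts(x)
  if (length(k_grid) == 0 || length(resolution_grid) == 0) {
    stop("k and resolution grids must be nonempty", call. = FALSE)
  }
  if (identical(expected_rate, "auto")) {
    expected_rate <- expected_doublet_rate(ncol(x), nrow(x))
  }
  N <- normalize_tags(x, method, scale = scale)
  grid <- expand.grid(k = as.integer(k_grid), resolution = resolution_grid,
                      KEEP.OUT.ATTRS = FALSE)
  runs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    runs[[r]] <- tryCatch(
      demux_single(N, k = grid$k[r], resolution = grid$resolution[r],
                   seed = as.integer(seed) + r - 1L,
                   expected_rate = expected_rate,
                   log_fc_grid = log_fc_grid, prune = prune),
      error = function(e) {
        warning("run (k = ", grid$k[r], ", resolution = ", grid$resolution[r],
                ") failed and was dropped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) stop("all ensemble runs failed", call. = FALSE)
  lab_mat <- do.call(rbind, lapply(runs, `[[`, "labels"))
  vote <- majority_vote(lab_mat, tag_names = rownames(x))
  structure(list(barcodes = colnames(x), tag_names = rownames(x),
                 final_labels = vote$label, confidence = vote$confidence,
                 runs = runs, expected_doublet_rate = expected_rate,
                 method = method, seed = as.integer(seed)),
            class = "demux_result")
}

# Majority vote over a runs x cells label matrix. Ties resolved in priority
# Negative > Doublet > tags alphabetically.
majority_vote <- function(labels, tag_names) {
  priority <- c("Negative", "Doublet", sort(tag_names))
  n_runs <- nrow(labels)
  res <- apply(labels, 2, function(lab) {
    tab <- table(lab)
    winners <- names(tab)[tab == max(tab)]
    pick <- priority[priority %in% winners][1]
    c(pick, as.character(max(tab)))
  })
  list(label = unname(res[1, ]),
       confidence = as.numeric(res[2, ]) / n_runs)
}

#' @export
as.data.frame.demux_result <- function(x, ...) {
  data.frame(barcode = x$barcodes, label = x$final_labels,
             confidence = x$confidence)
}

#' @export
print.demux_result <- function(x, ...) {
  tab <- table(factor(x$final_labels,
                      levels = c(sort(x$tag_names), "Doublet", "Negative")))
  cat(sprintf("demux_result: %d cells, %d tags, %d runs (%s)\n",
              length(x$barcodes), length(x$tag_names), length(x$runs),
              x$method))
  cat(sprintf("expected doublet rate: %.4f\n", x$expected_doublet_rate))
  print(tab)
  cat(sprintf("mean confidence: %.3f\n", mean(x$confidence)))
  invisible(x)
}

#' Per-run calibration report
#'
#' Summarizes the ensemble runs: parameters, chosen logFC threshold, achieved
#' doublet rate and cluster count per run.
#'
#' @param x a [demux_ensemble()] result.
#' @return data.frame with one row per retained run.
#' @export
run_report <- function(x) {
  stopifnot(inherits(x, "demux_result"))
  do.call(rbind, lapply(x$runs, function(r) {
    data.frame(k = r$k, resolution = r$resolution, seed = r$seed,
               chosen_log_fc = r$chosen_log_fc,
               doublet_rate_achieved = r$doublet_rate_achieved,
               n_clusters = r$n_clusters)
  }))
}
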