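#' Simulation configuration for synthetic hashtag datasets
#'
#' The generator emulates a pooled hashing experiment: each cell carries a
#' uniform-integer signal for its own tag(s), on top of which two
#' contamination sources are layered — cell-bound contamination (spurious tag
#' reads physically attached to the cell, a fixed fraction of its bound
#' reads) and ambient contamination (cell-free tag background, Poisson counts
#' with a tag-specific level).
#'
#' @param n_tags number of tags (samples), >= 2.
#' @param cells_per_tag cells per tag; total cells = `n_tags * cells_per_tag`.
#' @param doublet_rate fraction of all cells that are doublets (two distinct
#'   tags), in `[0, 1)`.
#' @param signal_low,signal_high own-tag signal bounds, reads; each tagged
#'   cell draws UniformInt(`signal_low`, `signal_high`) for its tag.
#' @param cell_bound_fraction fraction of each cell's bound reads that are
#'   contamination; the generator adds `round(f/(1-f) * signal)` reads spread
#'   multinomially over the non-own tags proportionally to ambient levels.
#' @param ambient_max ambient level (mean reads/cell) of the most contaminated
#'   tag; tag 1 is pinned at this level.
#' @param ambient_min lower bound of the log-uniform ambient levels of the
#'   other tags (default 1 read).
#' @param seed RNG seed; the whole dataset is a deterministic function of the
#'   config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tags = 5L, cells_per_tag = 1000L, doublet_rate = 0.1,
                       signal_low = 10L, signal_high = 1000L,
                       cell_bound_fraction = 0.02,
                       ambient_max = 100, ambient_min = 1, seed = 0L) {
  stopifnot(n_tags >= 1, cells_per_tag >= 1,
            doublet_rate >= 0, doublet_rate < 1,
            signal_low <= signal_high, signal_low >= 1,
            cell_bound_fraction >= 0, cell_bound_fraction < 1,
            ambient_min <= ambient_max || ambient_max <= 0)
  if (doublet_rate > 0 && n_tags < 2) {
    stop("doublets need at least 2 tags", call. = FALSE)
  }
  structure(list(n_tags = as.integer(n_tags),
                 cells_per_tag = as.integer(cells_per_tag),
                 doublet_rate = doublet_rate,
                 signal_low = as.integer(signal_low),
                 signal_high = as.integer(signal_high),
                 cell_bound_fraction = cell_bound_fraction,
                 ambient_max = ambient_max, ambient_min = ambient_min,
                 seed = as.integer(seed)),
        class = "sim_config")
}

#' Simulate a hashtag count dataset with ground truth
#'
#' Generation, all from the seeded generator:
#' \enumerate{
#'   \item `n_tags * cells_per_tag` cells, tag blocks of equal size;
#'     `round(doublet_rate * total)` of them become doublets, spread evenly
#'     across tag blocks, each with a pair of two distinct tags drawn
#'     uniformly.
#'   \item Own-tag signal: UniformInt(`signal_low`, `signal_high`) per owned
#'     tag (each tag of a doublet draws independently); other tags get zero.
#'   \item Ambient levels: tag 1 pinned at `ambient_max`; the others are
#'     log-uniform in `[ambient_min, ambient_max]`.
#'   \item Cell-bound contamination: `round(f/(1-f) * signal)` reads per cell,
#'     multinomially split over the non-own tags proportional to ambient
#'     levels, so contamination makes up fraction `f` of the cell's bound
#'     reads in expectation.
#'   \item Ambient counts: per (cell, tag), Poisson with the tag's level.
#' }
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset`: `matrix` ([tag_counts]), `truth`
#'   (data.frame `barcode`, `label` — tag name or `"Doublet"` —, `tag1`,
#'   `tag2`), `ambient_levels` (named per-tag), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  M <- cfg$n_tags
  n_total <- M * cfg$cells_per_tag
  tags <- sprintf("Tag%d", seq_len(M))
  barcodes <- sprintf("cell%0*d", nchar(n_total), seq_len(n_total))
  block <- rep(seq_len(M), each = cfg$cells_per_tag)

  # doublets: evenly allocated across tag blocks, pairs uniform over
  # unordered distinct tag pairs
  n_doub <- round(cfg$doublet_rate * n_total)
  per_block <- rep(n_doub %/% M, M)
  extra <- n_doub - sum(per_block)
  if (extra > 0) {
    bump <- sample.int(M, extra)
    per_block[bump] <- per_block[bump] + 1L
  }
  is_doublet <- logical(n_total)
  for (t in seq_len(M)) {
    idx <- which(block == t)
    if (per_block[t] > 0) is_doublet[sample(idx, per_block[t])] <- TRUE
  }
  own <- vector("list", n_total)
  for (j in seq_len(n_total)) {
    own[[j]] <- if (is_doublet[j]) sort(sample.int(M, 2)) else block[j]
  }

  # own-tag signal
  counts <- matrix(0, nrow = M, ncol = n_total)
  for (j in seq_len(n_total)) {
    counts[own[[j]], j] <- sample(cfg$signal_low:cfg$signal_high,
                                  length(own[[j]]), replace = TRUE)
  }

  # ambient levels (tag 1 pinned at the max; log-uniform otherwise)
  if (cfg$ambient_max <= 0) {
    lambda <- rep(0, M)
  } else {
    lambda <- c(cfg$ambient_max,
                exp(stats::runif(M - 1, log(cfg$ambient_min),
                                 log(cfg$ambient_max))))
  }
  names(lambda) <- tags

  # cell-bound contamination
  f <- cfg$cell_bound_fraction
  if (f > 0) {
    for (j in seq_len(n_total)) {
      others <- setdiff(seq_len(M), own[[j]])
      if (length(others) == 0) next
      n_cont <- round(f / (1 - f) * sum(counts[own[[j]], j]))
      if (n_cont == 0) next
      p <- lambda[others]
      if (sum(p) == 0) p <- rep(1, length(others))
      counts[others, j] <- counts[others, j] +
        stats::rmultinom(1, n_cont, p)[, 1]
    }
  }

  # ambient contamination
  if (cfg$ambient_max > 0) {
    counts <- counts + matrix(stats::rpois(M * n_total, lambda),
                              nrow = M, ncol = n_total)
  }

  truth <- data.frame(
    barcode = barcodes,
    label = vapply(seq_len(n_total), function(j) {
      if (is_doublet[j]) "Doublet" else tags[own[[j]]]
    }, character(1)),
    tag1 = vapply(own, function(o) tags[o[1]], character(1)),
    tag2 = vapply(own, function(o) if (length(o) > 1) tags[o[2]]
                  else NA_character_, character(1)))

  structure(list(matrix = tag_counts(counts, tag_names = tags,
                                     barcodes = barcodes),
                 truth = truth, ambient_levels = lambda, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d tags x %d cells (%.1f%% doublets, cell-bound %.0f%%, ambient max %g)\n",
    nrow(x$matrix), ncol(x$matrix), 100 * mean(x$truth$label == "Doublet"),
    100 * x$config$cell_bound_fraction, x$config$ambient_max))
  invisible(x)
}

#' High-background-noise simulation grid
#'
#' The benchmark grid of contamination regimes: every combination of four
#' cell-bound contamination fractions (2%, 5%, 14%, 37%) and ten maximum
#' ambient levels (100 to 1900 reads, step 200), each `replicates` times —
#' `40 * replicates` datasets of 5 tags, 1000 cells per tag and a 10% doublet
#' rate.
#'
#' @param replicates datasets per grid point (>= 1).
#' @param base_seed seed of the first dataset; dataset `i` uses
#'   `base_seed + i - 1`.
#' @return list of [simulate_dataset()] results, in grid-major order
#'   (cell-bound outer, ambient inner, replicate innermost).
#' @export
noise_grid <- function(replicates = 3L, base_seed = 0L) {
  stopifnot(replicates >= 1)
  cell_bound <- c(0.02, 0.05, 0.14, 0.37)
  ambient <- seq(100, 1900, by = 200)
  grid <- expand.grid(rep = seq_len(replicates), ambient_max = ambient,
                      cell_bound = cell_bound, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    simulate_dataset(sim_config(
      n_tags = 5L, cells_per_tag = 1000L, doublet_rate = 0.1,
      cell_bound_fraction = grid$cell_bound[i],
      ambient_max = grid$ambient_max[i],
      seed = as.integer(base_seed) + i - 1L))
  })
}

#' Scalability simulation grid
#'
#' Sixteen low-contamination configurations crossing tag counts
#' {5, 10, 20, 40} with cells-per-tag {100, 200, 400, 800}; all with ~2%
#' cell-bound contamination, maximum ambient level 100 and a 10% doublet
#' rate. Returns configs (not datasets) so callers can time generation and
#' demultiplexing separately.
#'
#' @param base_seed seed of the first config; config `i` uses
#'   `base_seed + i - 1`.
#' @return list of 16 [sim_config()] objects.
#' @export
scalability_grid <- function(base_seed = 0L) {
  grid <- expand.grid(cells_per_tag = c(100L, 200L, 400L, 800L),
                      n_tags = c(5L, 10L, 20L, 40L), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sim_config(n_tags = grid$n_tags[i], cells_per_tag = grid$cells_per_tag[i],
               doublet_rate = 0.1, cell_bound_fraction = 0.02,
               ambient_max = 100, seed = as.integer(base_seed) + i - 1L)
  })
}
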