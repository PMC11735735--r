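# Shared fixtures, built in code.

# Small deterministic count matrix
small_counts <- function() {
  tag_counts(matrix(c(5L, 0L, 3L,
                      0L, 7L, 2L,
                      1L, 2L, 0L,
                      9L, 4L, 6L),
                    nrow = 3,
                    dimnames = list(c("HTO1", "HTO2", "HTO3"),
                                    c("c1", "c2", "c3", "c4"))))
}

# Two well-separated groups in normalized space: group 1 high on tag A,
# group 2 high on tag B, with deterministic jitter.
two_group_norm <- function(n_per = 20) {
  n <- 2 * n_per
  jit <- sin(seq_len(n)) * 0.01
  m <- rbind(A = c(rep(3, n_per), rep(0.1, n_per)) + jit,
             B = c(rep(0.1, n_per), rep(3, n_per)) - jit)
  colnames(m) <- sprintf("c%02d", seq_len(n))
  m
}

label_vocabulary_for <- function(ds) c(rownames(ds$matrix), "Doublet",
                                       "Negative")

# Brute-force enumeration of all set partitions of 1..n
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Resolution-scaled modularity of a partition, computed from first
# principles on a weighted edge list (independent of igraph).
modularity_by_hand <- function(edges, membership, resolution = 1) {
  m <- sum(edges$weight)
  q <- 0
  for (c_id in unique(membership)) {
    inC <- which(membership == c_id)
    e_c <- sum(edges$weight[edges$from %in% inC & edges$to %in% inC])
    deg <- sum(edges$weight[edges$from %in% inC]) +
      sum(edges$weight[edges$to %in% inC])
    q <- q + e_c / m - resolution * (deg / (2 * m))^2
  }
  q
}

# Independent AUCPR oracle: brute-force (TP, FP) points over all distinct
# thresholds, then numeric integration of the interpolated precision along
# each segment with stats::integrate.
aucpr_oracle <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(positive & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!positive & scores >= t), numeric(1))
  tp <- c(0, tp); fp <- c(0, fp)
  n_pos <- sum(positive)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    dfp <- fp[i + 1] - fp[i]
    prec <- function(s) {
      (tp[i] + s * dtp) / (tp[i] + fp[i] + s * (dtp + dfp))
    }
    val <- stats::integrate(prec, 0, 1, rel.tol = 1e-12,
                            abs.tol = 1e-13)$value
    area <- area + val * dtp / n_pos
  }
  area
}
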