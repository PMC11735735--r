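test_that("expected doublet rate follows the loading-rate equation", {
  expect_equal(expected_doublet_rate(5000, 5), 0.032)
  expect_equal(expected_doublet_rate(10000, 2), 0.04)
  expect_equal(expected_doublet_rate(12345, 1), 0)
  expect_error(expected_doublet_rate(0, 5), "positive")
  expect_error(expected_doublet_rate(100, 0), "positive")
})

# Constant-valued fixture: with constant normalized value a inside a group
# and b outside, the de-normalized-mean logFC is exactly a - b.
marker_fixture <- function() {
  vals <- rbind(A = c(rep(1.6, 50), rep(0.1, 50)),
                B = c(rep(0.9, 50), rep(0.1, 50)),
                C = c(rep(0.1, 50), rep(2.1, 50)))
  colnames(vals) <- sprintf("c%03d", 1:100)
  list(N = vals, clusters = rep(0:1, each = 50))
}

test_that("marker rank-sum p-values match stats::wilcox.test", {
  set.seed(42)
  m <- matrix(round(rexp(120, 0.5), 2), nrow = 3,
              dimnames = list(c("A", "B", "C"), paste0("c", 1:40)))
  cl <- rep(0:2, c(12, 15, 13))
  st <- hashclust:::marker_stats(m, cl)
  for (r in seq_len(nrow(st))) {
    v <- m[st$tag[r], ]
    inC <- cl == st$cluster_id[r]
    ref <- stats::wilcox.test(v[inC], v[!inC], exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(st$p_value[r], ref, tolerance = 1e-12)
  }
})

test_that("markers require full detection, significance and logFC", {
  fx <- marker_fixture()
  mk <- find_markers(fx$N, fx$clusters, log_fc_threshold = 0.5)
  expect_setequal(mk$tag[mk$cluster_id == 0], c("A", "B"))
  expect_setequal(mk$tag[mk$cluster_id == 1], "C")
  expect_equal(mk$log_fc[mk$cluster_id == 0 & mk$tag == "A"], 1.5)
  expect_equal(mk$log_fc[mk$cluster_id == 1 & mk$tag == "C"], 2.0)

  # a single zero raw count in the cluster disqualifies the tag
  N2 <- fx$N
  N2["A", 1] <- 0
  mk2 <- find_markers(N2, fx$clusters, log_fc_threshold = 0.5)
  expect_false("A" %in% mk2$tag[mk2$cluster_id == 0])

  # threshold above every logFC empties the list
  expect_equal(nrow(find_markers(fx$N, fx$clusters, log_fc_threshold = 5)), 0)
})

test_that("cluster labels follow the 0/1/many marker rule", {
  cl <- rep(0:2, each = 4)
  mk <- data.frame(cluster_id = c(0, 0, 2), tag = c("HTO1", "HTO2", "HTO3"))
  labs <- label_from_markers(cl, mk)
  expect_equal(labs[1:4], rep("Doublet", 4))
  expect_equal(labs[5:8], rep("Negative", 4))
  expect_equal(labs[9:12], rep("HTO3", 4))
})

test_that("logFC calibration picks the closest rate, ties to smallest", {
  fx <- marker_fixture()
  # thresholds <= 0.8 give doublet rate 0.5; (0.8, 1.5] give 0; > 1.5 give 0
  cal <- calibrate_log_fc(fx$N, fx$clusters, target_rate = 0.5,
                          candidate_grid = c(0.5, 1.0, 1.8, 0.3))
  expect_equal(cal$chosen_log_fc, 0.3) # both 0.3 and 0.5 hit 0.5 exactly
  expect_equal(cal$achieved_rate, 0.5)
  expect_true(all(cal$labels[1:50] == "Doublet"))

  cal0 <- calibrate_log_fc(fx$N, fx$clusters, target_rate = 0,
                           candidate_grid = c(0.5, 1.0, 1.8))
  expect_equal(cal0$chosen_log_fc, 1.0) # 1.0 and 1.8 tie at rate 0
  expect_equal(cal0$achieved_rate, 0)
  expect_true(all(cal0$labels[1:50] == "A"))

  # exhaustive re-evaluation: chosen threshold minimizes |achieved - target|
  grid <- seq(0.1, 2, by = 0.1)
  cal2 <- calibrate_log_fc(fx$N, fx$clusters, target_rate = 0.1,
                           candidate_grid = grid)
  rates <- vapply(grid, function(th) {
    mean(label_from_markers(fx$clusters,
                            find_markers(fx$N, fx$clusters, th)) == "Doublet")
  }, numeric(1))
  expect_equal(unname(cal2$candidate_rates), rates)
  expect_equal(abs(cal2$achieved_rate - 0.1), min(abs(rates - 0.1)))
  expect_equal(cal2$chosen_log_fc,
               grid[which.min(abs(rates - 0.1))])
})

test_that("majority vote counts runs and breaks ties conservatively", {
  mv <- hashclust:::majority_vote
  runs <- matrix(c(rep("HTO2", 13), rep("Negative", 11)), ncol = 1)
  v <- mv(runs, tag_names = c("HTO1", "HTO2"))
  expect_equal(v$label, "HTO2")
  expect_equal(v$confidence, 13 / 24)

  tie <- matrix(c(rep("HTO1", 12), rep("Negative", 12)), ncol = 1)
  expect_equal(mv(tie, tag_names = c("HTO1", "HTO2"))$label, "Negative")
  tie2 <- matrix(c(rep("HTO1", 6), rep("Doublet", 6)), ncol = 1)
  expect_equal(mv(tie2, tag_names = c("HTO1", "HTO2"))$label, "Doublet")
  tie3 <- matrix(c(rep("HTO3", 6), rep("HTO1", 6)), ncol = 1)
  expect_equal(mv(tie3, tag_names = c("HTO3", "HTO1"))$label, "HTO1")

  all_agree <- matrix(rep("HTO1", 24), ncol = 1)
  expect_equal(mv(all_agree, tag_names = "HTO1")$confidence, 1)
})

test_that("a single run is deterministic and labels partition the cells", {
  ds <- simulate_dataset(sim_config(n_tags = 4, cells_per_tag = 100,
                                    seed = 33))
  N <- clr_per_cell(ds$matrix)
  r1 <- demux_single(N, k = 10, resolution = 1, seed = 5,
                     expected_rate = 0.1)
  r2 <- demux_single(N, k = 10, resolution = 1, seed = 5,
                     expected_rate = 0.1)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$chosen_log_fc, r2$chosen_log_fc)
  expect_true(all(r1$labels %in% label_vocabulary_for(ds)))
  expect_equal(r1$doublet_rate_achieved, mean(r1$labels == "Doublet"))
})

test_that("the ensemble votes, reports confidence and tolerates failed runs", {
  ds <- simulate_dataset(sim_config(n_tags = 4, cells_per_tag = 60,
                                    seed = 12))
  res <- demux_ensemble(ds$matrix, k_grid = c(10, 15),
                        resolution_grid = c(1, 2), seed = 3,
                        expected_rate = 0.1)
  expect_equal(length(res$final_labels), 240)
  expect_true(all(res$final_labels %in% label_vocabulary_for(ds)))
  expect_true(all(res$confidence >= 1 / length(res$runs)))
  expect_true(all(res$confidence <= 1))
  rep <- run_report(res)
  expect_equal(nrow(rep), 4)

  # k = 500 exceeds the cell count: that run fails and is dropped
  expect_warning(
    res2 <- demux_ensemble(ds$matrix, k_grid = c(10, 500),
                           resolution_grid = 1, seed = 3,
                           expected_rate = 0.1),
    "dropped")
  expect_equal(length(res2$runs), 1)
  expect_error(
    suppressWarnings(demux_ensemble(ds$matrix, k_grid = 500,
                                    resolution_grid = 1,
                                    expected_rate = 0.1)),
    "all ensemble runs failed")
})

test_that("ensemble demux recovers singlet identities on low-noise data", {
  ds <- simulate_dataset(sim_config(n_tags = 4, cells_per_tag = 150,
                                    seed = 77))
  res <- demux_ensemble(ds$matrix, k_grid = c(10, 20), resolution_grid = 1:2,
                        seed = 7, expected_rate = 0.1)
  singlet <- ds$truth$label != "Doublet"
  acc <- mean(res$final_labels[singlet] == ds$truth$label[singlet])
  expect_gte(acc, 0.9)
})
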