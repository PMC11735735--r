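lab_df <- function(barcodes, labels) data.frame(barcode = barcodes,
                                                label = labels)

test_that("per-tag F-scores match hand contingency tables", {
  bc <- paste0("c", 1:8)
  truth <- lab_df(bc, c("A", "A", "A", "A", "B", "B", "Doublet", "Negative"))
  pred <- lab_df(bc, c("A", "A", "A", "Negative", "B", "B", "B", "Negative"))
  fs <- f_score(pred, truth)
  # A: P = 1, R = 3/4 -> F = 6/7; B: P = 2/3, R = 1 -> F = 4/5
  expect_equal(unname(fs$per_tag_f["A"]), 6 / 7)
  expect_equal(unname(fs$per_tag_f["B"]), 4 / 5)
  expect_equal(fs$average_f, mean(c(6 / 7, 4 / 5)))

  perfect <- f_score(truth, truth)
  expect_true(all(perfect$per_tag_f == 1))
  expect_equal(perfect$average_f, 1)

  # a tag never predicted scores 0
  none <- lab_df(bc, rep("Negative", 8))
  expect_equal(unname(f_score(none, truth)$per_tag_f), c(0, 0))

  expect_error(f_score(pred[1:7, ], truth), "same barcodes")
})

test_that("doublet-to-singlet rate counts only tag assignments", {
  bc <- paste0("c", 1:6)
  truth <- lab_df(bc, c("Doublet", "Doublet", "Doublet", "Doublet", "A", "B"))
  pred <- lab_df(bc, c("A", "Doublet", "Negative", "B", "A", "B"))
  expect_equal(doublet_misclassification(pred, truth), 0.5)
  safe <- lab_df(bc, c("Doublet", "Doublet", "Negative", "Negative", "A", "B"))
  expect_equal(doublet_misclassification(safe, truth), 0)
  no_doub <- lab_df(bc[5:6], c("A", "B"))
  expect_warning(r <- doublet_misclassification(no_doub[1:2, ],
                                               lab_df(bc[5:6], c("A", "B"))),
                 "no doublets")
  expect_equal(r, 0)
})

test_that("AUCPR hits closed-form anchor cases", {
  # perfect separation
  expect_equal(hashclust:::aucpr(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  # constant scores: one operating point, area = prevalence
  expect_equal(hashclust:::aucpr(rep(2, 10), rep(c(TRUE, FALSE), c(3, 7))),
               0.3)
  # worst ranking pos={1}, neg={2,3}: exact integral of the
  # interpolated segment from (TP,FP)=(0,2) to (1,2) is 1 - 2 ln(3/2)
  expect_equal(hashclust:::aucpr(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               1 - 2 * log(1.5))
})

test_that("AUCPR agrees with the enumeration + numeric-integration oracle", {
  set.seed(123)
  for (case in 1:100) {
    n <- sample(4:20, 1)
    n_pos <- sample(seq_len(n - 1), 1)
    positive <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
    scores <- sample(0:8, n, replace = TRUE) # heavy ties
    expect_equal(hashclust:::aucpr(scores, positive),
                 aucpr_oracle(scores, positive), tolerance = 1e-9)
  }
})

test_that("AUCPR is invariant under strictly monotone score transforms", {
  set.seed(9)
  scores <- rpois(50, 20)
  positive <- rep(c(TRUE, FALSE), c(15, 35))
  base <- hashclust:::aucpr(scores, positive)
  expect_equal(hashclust:::aucpr(log1p(scores / 7), positive), base)
  expect_equal(hashclust:::aucpr(scores^3, positive), base)
})

test_that("aucpr_separability excludes doublets and flags empty classes", {
  m <- tag_counts(matrix(c(9L, 1L, 8L, 2L, 1L, 9L, 5L, 5L), nrow = 2,
                         dimnames = list(c("A", "B"), paste0("c", 1:4))))
  truth <- lab_df(paste0("c", 1:4), c("A", "A", "B", "Doublet"))
  # after excluding c4, tag A scores are 9, 8 (pos) vs 1 (neg): perfect
  expect_equal(aucpr_separability(m, truth, "A"), 1)
  expect_warning(r <- aucpr_separability(m, lab_df(paste0("c", 1:4),
                                                  c("B", "B", "B", "B")),
                                         "A"),
                 "no positive")
  expect_true(is.na(r))
  expect_error(aucpr_separability(m, truth, "Z"), "unknown tag")
})

test_that("noise metrics match direct evaluation", {
  # two tags with constant counts 8 and 0: medians {ln 9, 0}
  x <- tag_counts(matrix(c(8L, 0L, 8L, 0L, 8L, 0L), nrow = 2,
                         dimnames = list(c("A", "B"), paste0("c", 1:3))))
  med <- c(log(9), 0)
  expect_equal(baseline_expression_variability(x), sd(med) / mean(med))
  # identical distributions across tags -> zero variability
  y <- tag_counts(matrix(rep(c(3L, 7L), each = 4), nrow = 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), paste0("c", 1:4))))
  y2 <- tag_counts(rbind(A = c(3L, 7L), B = c(7L, 3L)),
                   barcodes = c("c1", "c2"))
  expect_equal(baseline_expression_variability(y2), 0)
  expect_warning(
    r <- baseline_expression_variability(
      tag_counts(matrix(0L, 2, 2, dimnames = list(c("A", "B"),
                                                  c("c1", "c2"))))),
    "undefined")
  expect_true(is.na(r))

  # depth variability: equal totals -> 1; scale invariance
  expect_equal(sequencing_depth_variability(y), 1)
  totals <- seq(100L, 10000L, length.out = 101)
  z <- tag_counts(rbind(A = as.integer(totals), B = 0L),
                  barcodes = paste0("c", seq_along(totals)))
  expect_equal(sequencing_depth_variability(z),
               unname(quantile(totals, 0.99) / quantile(totals, 0.01)))
  z3 <- tag_counts(unclass(z) * 3L, rownames(z), colnames(z))
  expect_equal(sequencing_depth_variability(z3),
               sequencing_depth_variability(z))
  zero_cell <- tag_counts(rbind(A = c(rep(0L, 10), rep(5L, 191)), B = 0L),
                          barcodes = paste0("c", 1:201))
  expect_warning(r <- sequencing_depth_variability(zero_cell), "infinite")
  expect_equal(r, Inf)
})

test_that("evaluation reports aggregate and serialize faithfully", {
  ds <- simulate_dataset(sim_config(n_tags = 3, cells_per_tag = 40,
                                    doublet_rate = 0, seed = 2))
  perfect <- lab_df(ds$truth$barcode, ds$truth$label)
  rep <- suppressWarnings(evaluate_demux(perfect, ds$truth, ds$matrix))
  expect_equal(rep$average_f, 1)
  expect_equal(rep$doublet_to_singlet_rate, 0)
  expect_equal(rep$average_f, mean(unlist(rep$per_tag_f)))
  expect_true(all(unlist(rep$per_tag_aucpr) >= 0 &
                    unlist(rep$per_tag_aucpr) <= 1))

  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$average_f, rep$average_f)
  expect_equal(unlist(back$per_tag_f), unlist(rep$per_tag_f))

  # an undefined AUCPR serializes as null, not 0
  rep$per_tag_aucpr$Tag1 <- NA_real_
  write_report(rep, f)
  raw <- paste(readLines(f), collapse = "")
  expect_match(raw, "\"Tag1\":null")
})
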