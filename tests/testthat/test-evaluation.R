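# brute-force confusion oracle over all unordered valid pairs
confusion_oracle <- function(p, truth, cutoff) {
  L <- truth$length
  tm <- labels_matrix(truth)
  tp <- fp <- fn <- 0L
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    if (j - i < 3) next
    pred_pos <- p[i, j] >= cutoff
    is_true <- tm[i, j] > 0.5
    if (pred_pos && is_true) tp <- tp + 1L
    if (pred_pos && !is_true) fp <- fp + 1L
    if (!pred_pos && is_true) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}

test_that("confusion counts match the brute-force oracle", {
  set.seed(61)
  for (k in 1:10) {
    L <- 12
    p <- toy_symmetric_map(L, seed = 61 + k)
    truth <- pairing_labels(L, rbind(c(0, 5), c(1, 4), c(7, 11)))
    cutoff <- runif(1)
    got <- confusion_counts(pairing_prob_map(p), truth, cutoff)
    want <- confusion_oracle(pairing_prob_map(p)$probs, truth, cutoff)
    expect_identical(got, want)
  }
  # trivial cases
  empty <- pairing_labels(10, NULL)
  zeros <- pairing_prob_map(matrix(0, 10, 10))
  expect_identical(confusion_counts(zeros, empty, 0.5),
                   list(TP = 0L, FP = 0L, FN = 0L))
  one <- matrix(0, 10, 10); one[1, 6] <- one[6, 1] <- 0.9
  expect_identical(confusion_counts(pairing_prob_map(one),
                                    pairing_labels(10, rbind(c(0, 5))),
                                    0.5),
                   list(TP = 1L, FP = 0L, FN = 0L))
  expect_error(confusion_counts(zeros, pairing_labels(12, NULL), 0.5),
               "labels have L")
})

test_that("precision/recall/F1 arithmetic and 0/0 conventions", {
  expect_equal(precision_recall_f1(list(TP = 0, FP = 0, FN = 0)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(list(TP = 3, FP = 1, FN = 1)),
               c(precision = 0.75, recall = 0.75, f1 = 0.75))
  expect_equal(precision_recall_f1(list(TP = 1, FP = 0, FN = 3)),
               c(precision = 1, recall = 0.25, f1 = 0.4))
})

test_that("f1_from_rates reproduces the benchmark-table arithmetic", {
  # Printed (precision, recall, F1) rows of the two published benchmark
  # tables; F1 must reproduce to 2 decimal places from P and R alone.
  rows <- rbind(
    c(77.34, 67.80, 72.26), c(21.31, 60.76, 31.55),
    c(69.91, 54.81, 61.45), c(59.18, 53.41, 56.15),
    c(78.71, 68.44, 73.22), c(20.99, 60.24, 31.13),
    c(69.10, 58.19, 63.18), c(60.04, 55.21, 57.52))
  for (k in seq_len(nrow(rows))) {
    expect_equal(round(f1_from_rates(rows[k, 1], rows[k, 2]), 2),
                 rows[k, 3])
  }
  # harmonic mean of equal values is the value itself
  expect_equal(f1_from_rates(40, 40), 40)
  expect_equal(f1_from_rates(0, 0), 0)
  expect_error(f1_from_rates(101, 50), ">=|<=|must")
})

# exhaustive AUPRC oracle: step integration over every distinct score
auprc_oracle <- function(score, true) {
  thr <- sort(unique(score), decreasing = TRUE)
  prev_r <- 0
  auc <- 0
  for (t in thr) {
    tp <- sum(score >= t & true)
    fp <- sum(score >= t & !true)
    p <- tp / (tp + fp)
    r <- tp / sum(true)
    auc <- auc + (r - prev_r) * p
    prev_r <- r
  }
  auc
}

test_that("pr_curve matches the exhaustive oracle", {
  set.seed(62)
  for (k in 1:10) {
    L <- 15
    p <- toy_symmetric_map(L, seed = 62 + k)
    pairs <- rbind(c(0, 6), c(2, 9), c(4, 12), c(1, 13))
    truth <- pairing_labels(L, pairs)
    pc <- pr_curve(pairing_prob_map(p), truth)
    valid <- upper.tri(p) & separation_mask(L)
    pm <- pairing_prob_map(p)$probs
    want <- auprc_oracle(pm[valid], labels_matrix(truth)[valid] > 0.5)
    expect_equal(pc$auprc, want, tolerance = 1e-10)
    # curve structure: thresholds strictly decreasing, recall
    # non-decreasing along the curve
    expect_true(all(diff(pc$thresholds) < 0))
    expect_true(all(diff(pc$recall) >= 0))
  }
})

test_that("AUPRC is 1 under perfect separation and monotone-invariant", {
  L <- 12
  truth <- pairing_labels(L, rbind(c(0, 6), c(2, 9)))
  p <- matrix(0.1, L, L)
  p[1, 7] <- p[7, 1] <- 0.9
  p[3, 10] <- p[10, 3] <- 0.8
  pc <- pr_curve(pairing_prob_map(p), truth)
  expect_equal(pc$auprc, 1.0, tolerance = 1e-12)
  # strictly monotone transform of the scores preserves the AUPRC
  q <- sqrt(p)
  pc2 <- pr_curve(pairing_prob_map(q / max(q) * 0.99), truth)
  expect_equal(pc2$auprc, pc$auprc, tolerance = 1e-12)
  expect_error(pr_curve(pairing_prob_map(p), pairing_labels(L, NULL)),
               "no true pairs")
})

test_that("select_cutoff matches exhaustive search and breaks ties up", {
  set.seed(63)
  for (k in 1:6) {
    L <- 14
    p1 <- pairing_prob_map(toy_symmetric_map(L, seed = 70 + k))
    p2 <- pairing_prob_map(toy_symmetric_map(L, seed = 80 + k))
    t1 <- pairing_labels(L, rbind(c(0, 6), c(2, 10)))
    t2 <- pairing_labels(L, rbind(c(1, 8), c(3, 12), c(0, 13)))
    got <- select_cutoff(list(p1, p2), list(t1, t2))
    # exhaustive oracle over all distinct pooled scores
    valid <- upper.tri(matrix(0, L, L)) & separation_mask(L)
    s <- c(p1$probs[valid], p2$probs[valid])
    y <- c(labels_matrix(t1)[valid], labels_matrix(t2)[valid]) > 0.5
    f1_at <- function(cut) {
      tp <- sum(s >= cut & y); fp <- sum(s >= cut & !y)
      fn <- sum(s < cut & y)
      precision_recall_f1(list(TP = tp, FP = fp, FN = fn))[["f1"]]
    }
    cand <- sort(unique(s), decreasing = TRUE)
    best <- max(vapply(cand, f1_at, numeric(1)))
    expect_equal(f1_at(got), best, tolerance = 1e-10)
    # ties break toward the higher cutoff
    winners <- cand[abs(vapply(cand, f1_at, numeric(1)) - best) < 1e-12]
    expect_equal(got, max(winners), tolerance = 1e-12)
  }
  expect_error(select_cutoff(list(), list()), "empty")
})

test_that("per-protein report and pooled row match hand computation", {
  L <- 12
  t1 <- pairing_labels(L, rbind(c(0, 6)))
  t2 <- pairing_labels(L, rbind(c(1, 8), c(2, 7)))
  p1 <- matrix(0, L, L); p1[1, 7] <- p1[7, 1] <- 0.9       # TP
  p2 <- matrix(0, L, L)
  p2[2, 9] <- p2[9, 2] <- 0.9                              # TP
  p2[4, 11] <- p2[11, 4] <- 0.8                            # FP; (2,7) is FN
  tab <- evaluate_per_protein(list(pairing_prob_map(p1),
                                   pairing_prob_map(p2)),
                              list(t1, t2), cutoff = 0.5,
                              ids = c("a", "b"))
  expect_identical(tab$id, c("a", "b", "pooled"))
  expect_equal(tab$f1[1], 1)
  expect_equal(tab$precision[2], 0.5)
  expect_equal(tab$recall[2], 0.5)
  # pooled row equals precision_recall_f1 of the summed counts
  expect_equal(tab$TP[3], 2)
  expect_equal(unname(unlist(tab[3, c("precision", "recall", "f1")])),
               unname(precision_recall_f1(list(TP = 2, FP = 1, FN = 1))))
})

test_that("win fraction uses strict inequality", {
  L <- 12
  truths <- list(pairing_labels(L, rbind(c(0, 6))),
                 pairing_labels(L, rbind(c(1, 8))))
  good <- lapply(truths, function(tr) {
    m <- labels_matrix(tr) * 0.9
    pairing_prob_map(m)
  })
  expect_equal(f1_win_fraction(good, good, truths, 0.5, 0.5), 0)
  bad <- lapply(truths, function(tr) pairing_prob_map(
    matrix(0, L, L)))
  expect_equal(f1_win_fraction(good, bad, truths, 0.5, 0.5), 1)
})
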