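.pred_matrix <- function(pred) {
  if (inherits(pred, "pairing_prob_map")) pred$probs else as.matrix(pred)
}

# scores and 0/1 truth over unordered valid pairs (i < j, separation >= 3)
.scored_pairs <- function(pred, truth) {
  p <- .pred_matrix(pred)
  stopifnot(inherits(truth, "pairing_labels"))
  L <- truth$length
  if (!all(dim(p) == c(L, L))) {
    stop("prediction is ", nrow(p), " x ", ncol(p),
         " but labels have L = ", L)
  }
  valid <- upper.tri(p) & separation_mask(L)
  list(score = p[valid], true = labels_matrix(truth)[valid] > 0.5)
}

#' Confusion counts at a cutoff
#'
#' Counted over unordered residue pairs at sequence separation >= 3:
#' a pair is predicted positive when its score is >= `cutoff`.
#'
#' @param pred A [pairing_prob_map()] or plain matrix.
#' @param truth A [pairing_labels()].
#' @param cutoff Decision threshold in \[0, 1\].
#' @return List with integer fields `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth, cutoff) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  sp <- .scored_pairs(pred, truth)
  pos <- sp$score >= cutoff
  list(TP = sum(pos & sp$true), FP = sum(pos & !sp$true),
       FN = sum(!pos & sp$true))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; every 0/0 case is defined as 0, so a
#' predictor that outputs nothing scores 0 rather than NA.
#'
#' @param counts List or vector with `TP`, `FP`, `FN`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' F1 from precision and recall in percent
#'
#' Harmonic mean on the percent scale: the benchmark tables print
#' precision, recall and F1 as percentages.
#'
#' @param precision,recall Percentages in \[0, 100\].
#' @return F1 as a percentage.
#' @export
f1_from_rates <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 100),
            all(recall >= 0 & recall <= 100))
  denom <- precision + recall
  ifelse(denom > 0, 2 * precision * recall / denom, 0)
}

#' Precision-recall curve and AUPRC
#'
#' One (precision, recall) point per distinct predicted score taken as
#' the cutoff, cutoffs descending. The area under the curve uses step
#' (right-continuous) integration `sum((R_k - R_{k-1}) * P_k)` with
#' `R_0 = 0`, which avoids the optimistic bias of trapezoidal
#' interpolation on PR curves.
#'
#' @param pred A [pairing_prob_map()] or matrix, or a list of them
#'   (pooled curve).
#' @param truth A [pairing_labels()] with at least one pair, or a
#'   matching list.
#' @return An object of class `"pr_curve"`: list with `thresholds`,
#'   `precision`, `recall`, `auprc`.
#' @export
pr_curve <- function(pred, truth) {
  if (!is.list(pred) || inherits(pred, "pairing_prob_map")) {
    pred <- list(pred)
  }
  if (!is.list(truth) || inherits(truth, "pairing_labels")) {
    truth <- list(truth)
  }
  stopifnot(length(pred) == length(truth))
  sps <- Map(.scored_pairs, pred, truth)
  sp <- list(score = unlist(lapply(sps, `[[`, "score")),
             true = unlist(lapply(sps, `[[`, "true")))
  if (!any(sp$true)) {
    stop("no true pairs: the precision-recall curve is undefined")
  }
  ord <- order(sp$score, decreasing = TRUE)
  s <- sp$score[ord]
  y <- sp$true[ord]
  cum_tp <- cumsum(y)
  cum_pos <- seq_along(y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each score
  thr <- s[last]
  tp <- cum_tp[last]
  pos <- cum_pos[last]
  prec <- tp / pos
  rec <- tp / sum(sp$true)
  auprc <- sum((rec - c(0, head(rec, -1))) * prec)
  structure(list(thresholds = thr, precision = prec, recall = rec,
                 auprc = auprc),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve: %d points, AUPRC = %.4f\n",
              length(x$thresholds), x$auprc))
  invisible(x)
}

#' Select the F1-optimal cutoff over a validation pool
#'
#' Pools the scored pairs of all proteins and returns the cutoff (one of
#' the distinct predicted scores) that maximizes pooled F1; ties break
#' toward the higher cutoff.
#'
#' @param preds List of predictions ([pairing_prob_map()] or matrices),
#'   or a single prediction.
#' @param truths List of [pairing_labels()] matching `preds`.
#' @return The selected cutoff.
#' @export
select_cutoff <- function(preds, truths) {
  if (!is.list(preds) || inherits(preds, "pairing_prob_map")) {
    preds <- list(preds)
  }
  if (!is.list(truths) || inherits(truths, "pairing_labels")) {
    truths <- list(truths)
  }
  if (!length(preds)) stop("empty validation pool")
  stopifnot(length(preds) == length(truths))
  sp <- Map(.scored_pairs, preds, truths)
  s <- unlist(lapply(sp, `[[`, "score"))
  y <- unlist(lapply(sp, `[[`, "true"))
  if (!any(y)) stop("validation pool has no true pairs")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  y <- y[ord]
  cum_tp <- cumsum(y)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cum_tp[last]
  pos <- seq_along(y)[last]
  n_true <- sum(y)
  prec <- tp / pos
  rec <- tp / n_true
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # ties toward the higher cutoff: thresholds are descending, pick first max
  s[last][which.max(f1)]
}

#' Per-protein precision/recall/F1 report
#'
#' One row per protein at the given cutoff plus a pooled
#' (micro-averaged) row computed from the summed confusion counts.
#'
#' @param preds List of predictions.
#' @param truths List of [pairing_labels()].
#' @param cutoff Decision threshold.
#' @param ids Optional protein identifiers.
#' @return Data frame with columns `id`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `f1`; the last row (`id == "pooled"`) micro-averages.
#' @export
evaluate_per_protein <- function(preds, truths, cutoff, ids = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(ids)) ids <- sprintf("protein_%03d", seq_along(preds))
  rows <- Map(function(p, tr) {
    cc <- confusion_counts(p, tr, cutoff)
    c(TP = cc$TP, FP = cc$FP, FN = cc$FN, precision_recall_f1(cc))
  }, preds, truths)
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(id = ids, tab)
  pooled <- colSums(tab[, c("TP", "FP", "FN")])
  prf <- precision_recall_f1(as.list(pooled))
  rbind(tab, data.frame(id = "pooled", TP = pooled[["TP"]],
                        FP = pooled[["FP"]], FN = pooled[["FN"]],
                        precision = prf[["precision"]],
                        recall = prf[["recall"]], f1 = prf[["f1"]]))
}

#' Fraction of proteins where one prediction set beats another
#'
#' Strict inequality of per-protein F1 at each set's own cutoff.
#'
#' @param preds_a,preds_b Prediction lists over the same proteins.
#' @param truths List of [pairing_labels()].
#' @param cutoff_a,cutoff_b Decision thresholds for the two sets.
#' @return Fraction of proteins with `F1_a > F1_b`.
#' @export
f1_win_fraction <- function(preds_a, preds_b, truths, cutoff_a, cutoff_b) {
  stopifnot(length(preds_a) == length(truths),
            length(preds_b) == length(truths))
  f1s <- function(preds, cut) {
    vapply(seq_along(preds), function(k) {
      precision_recall_f1(confusion_counts(preds[[k]], truths[[k]],
                                           cut))[["f1"]]
    }, numeric(1))
  }
  mean(f1s(preds_a, cutoff_a) > f1s(preds_b, cutoff_b))
}
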