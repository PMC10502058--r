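#' Confusion matrix and per-class precision/recall/F1
#'
#' From true labels and top-1 calls, builds the confusion matrix (rows =
#' truth, columns = prediction) and, per class c with true positives TP,
#' false negatives FN and false positives FP:
#' recall = TP / (TP + FN), precision = TP / (TP + FP),
#' F1 = 2 recall precision / (recall + precision), and overall
#' accuracy = sum of TP over all classes divided by the sample count.
#' A class never predicted gets precision and F1 reported as 0 with the
#' \code{undefined} flag set, so macro averages stay defined.
#'
#' @param truth character vector of true labels.
#' @param pred character vector of top-1 predicted labels (same length).
#' @return list with \code{confusion}, \code{per_class} (data.frame with
#'   recall, precision, f1, n, undefined flag) and \code{accuracy}.
#' @export
confusion_and_prf <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stopf("truth and predictions differ in length (%d vs %d)",
          length(truth), length(pred))
  }
  classes <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, classes), factor(pred, classes))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  undefined <- tp + fp == 0
  precision <- ifelse(undefined, 0, tp / (tp + fp))
  f1 <- ifelse(undefined | recall + precision == 0, 0,
               2 * recall * precision / (recall + precision))
  list(confusion = cm,
       per_class = data.frame(class = classes, n = as.integer(rowSums(cm)),
                              recall = as.numeric(recall),
                              precision = as.numeric(precision),
                              f1 = as.numeric(f1), undefined = undefined,
                              row.names = NULL, stringsAsFactors = FALSE),
       accuracy = sum(tp) / length(truth))
}

#' Top-k accuracy from ranked predictions
#'
#' @param truth character vector of true labels.
#' @param ranked a samples x ranks character matrix (column j = j-th ranked
#'   class), or a \code{too_prediction}.
#' @param k rank depth.
#' @return fraction of samples whose true label appears within the first k
#'   ranks.
#' @export
topk_accuracy <- function(truth, ranked, k) {
  if (!is_count(k)) stopf("k must be a positive integer")
  ranked <- ranked_matrix(ranked)
  stopifnot(nrow(ranked) == length(truth))
  k <- min(k, ncol(ranked))
  mean(vapply(seq_along(truth),
              function(i) truth[i] %in% ranked[i, seq_len(k)], logical(1)))
}

ranked_matrix <- function(ranked) {
  if (inherits(ranked, "too_prediction")) {
    ids <- unique(ranked$sample_id)
    kk <- max(ranked$rank)
    m <- matrix(NA_character_, length(ids), kk, dimnames = list(ids, NULL))
    m[cbind(match(ranked$sample_id, ids), ranked$rank)] <- ranked$class
    m
  } else {
    as.matrix(ranked)
  }
}

#' Confidence-tier summary of predictions
#'
#' Counts correct predictions per confidence tier (high: top probability
#' > 0.75, medium: > 0.5, low otherwise) and traces the cumulative
#' fraction-correct among samples whose top probability is at least each
#' threshold of a grid.
#'
#' @param max_prob numeric vector of per-sample top probabilities.
#' @param correct logical vector, was the top-1 call correct.
#' @param thresholds threshold grid (default 0, 0.05, ..., 1).
#' @return list with \code{tiers} (data.frame tier/n/n_correct) and
#'   \code{curve} (data.frame threshold/n/frac_correct).
#' @export
confidence_summary <- function(max_prob, correct,
                               thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(length(max_prob) == length(correct))
  tier <- ifelse(max_prob > 0.75, "high", ifelse(max_prob > 0.5, "medium", "low"))
  tiers <- data.frame(tier = c("low", "medium", "high"), stringsAsFactors = FALSE)
  tiers$n <- vapply(tiers$tier, function(t) sum(tier == t), integer(1))
  tiers$n_correct <- vapply(tiers$tier, function(t) sum(correct[tier == t]),
                            integer(1))
  curve <- data.frame(threshold = thresholds)
  curve$n <- vapply(thresholds, function(th) sum(max_prob >= th), integer(1))
  curve$frac_correct <- vapply(thresholds, function(th) {
    sel <- max_prob >= th
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  list(tiers = tiers, curve = curve)
}

#' Macro one-vs-rest AUC
#'
#' Unweighted mean over classes of the rank-based one-vs-rest AUC (ties
#' count one half). Classes absent from the truth are skipped with a
#' warning.
#'
#' @param truth character vector of true labels.
#' @param prob samples x classes probability (or score) matrix with class
#'   column names.
#' @return macro AUC in \[0, 1\].
#' @export
macro_auc <- function(truth, prob) {
  stopifnot(is.matrix(prob), nrow(prob) == length(truth),
            !is.null(colnames(prob)))
  aucs <- numeric()
  for (cl in colnames(prob)) {
    pos <- truth == cl
    if (!any(pos)) {
      warning(sprintf("class '%s' absent from truth; skipped in macro AUC", cl))
      next
    }
    if (all(pos)) next
    r <- rank(prob[, cl])
    n1 <- sum(pos)
    n0 <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

#' Binomially thin haplotype counts
#'
#' Emulates sequencing a fraction of the library: every unit of every
#' record's count is retained independently with the given probability;
#' records thinned to zero are dropped. Deterministic given the seed.
#'
#' @param records a haplotype record data.frame (a \code{count} column).
#' @param fraction retention probability in (0, 1\].
#' @param seed integer seed.
#' @return the thinned records.
#' @export
downsample_records <- function(records, fraction, seed = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stopf("fraction must lie in (0, 1]")
  }
  if (fraction == 1) return(records)
  kept <- with_seed(derive_seed(seed, "downsample"),
                    stats::rbinom(nrow(records), records$count, fraction))
  out <- records[kept > 0, , drop = FALSE]
  out$count <- kept[kept > 0]
  rownames(out) <- NULL
  out
}

#' Top-1 accuracy stratified by a covariate
#'
#' @param covariate numeric per-sample covariate (tumor content, reads...).
#' @param correct logical per-sample top-1 correctness.
#' @param breaks bin edges; bins are left-open, right-closed (lowest edge
#'   included).
#' @return data.frame bin/n/accuracy (accuracy \code{NA} for empty bins).
#' @export
accuracy_by_bin <- function(covariate, correct, breaks) {
  stopifnot(length(covariate) == length(correct))
  bin <- cut(covariate, breaks = breaks, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin), stringsAsFactors = FALSE)
  out$n <- vapply(levels(bin), function(b) sum(bin == b, na.rm = TRUE), integer(1))
  out$accuracy <- vapply(levels(bin), function(b) {
    sel <- !is.na(bin) & bin == b
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  out
}

#' Full evaluation report from ranked predictions
#'
#' Combines the confusion matrix, Eqs.-style per-class metrics, top-k
#' accuracies for every available k, per-class top-k sensitivity, the
#' confidence-tier summary and the macro one-vs-rest AUC.
#'
#' @param truth named or plain character vector of true labels (if named,
#'   matched to the prediction's sample ids).
#' @param pred a \code{too_prediction}.
#' @return object of class \code{too_eval}.
#' @export
evaluate_predictions <- function(truth, pred) {
  stopifnot(inherits(pred, "too_prediction"))
  ranked <- ranked_matrix(pred)
  if (!is.null(names(truth))) truth <- truth[rownames(ranked)]
  truth <- as.character(truth)
  prf <- confusion_and_prf(truth, ranked[, 1])
  ks <- seq_len(ncol(ranked))
  topk <- vapply(ks, function(k) topk_accuracy(truth, ranked, k), numeric(1))
  sens_topk <- vapply(sort(unique(truth)), function(cl) {
    sel <- truth == cl
    vapply(ks, function(k) topk_accuracy(truth[sel],
                                         ranked[sel, , drop = FALSE], k),
           numeric(1))
  }, numeric(length(ks)))
  prob <- prediction_prob(pred)
  max_prob <- apply(prob, 1, max)
  correct <- ranked[, 1] == truth
  conf <- confidence_summary(max_prob, correct)
  auc <- suppressWarnings(macro_auc(truth, prob))
  structure(list(confusion = prf$confusion, per_class = prf$per_class,
                 accuracy = prf$accuracy, topk = stats::setNames(topk, ks),
                 sensitivity_topk = sens_topk, confidence = conf,
                 macro_auc = auc, n = length(truth)),
            class = "too_eval")
}

#' @export
print.too_eval <- function(x, ...) {
  cat(sprintf("<too_eval> n=%d: top-1 %.1f%%, top-3 %.1f%%, macro AUC %.3f\n",
              x$n, 100 * x$topk[1],
              100 * x$topk[min(3, length(x$topk))], x$macro_auc))
  cat("per-class recall/precision/F1:\n")
  print(transform(x$per_class, recall = round(recall, 2),
                  precision = round(precision, 2), f1 = round(f1, 2)))
  invisible(x)
}

#' Round a fraction to a whole percentage (half away from zero)
#'
#' @param x fractions in \[0, 1\].
#' @return integer percentages (91.2\% prints as 91).
#' @export
percent <- function(x) floor(100 * x + 0.5)
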