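test_that("confusion matrix and per-class metrics follow their definitions", {
  truth <- rep(c("A", "B"), c(10, 10))
  pred <- c(rep("A", 8), rep("B", 2), rep("B", 8), rep("A", 2))
  r <- confusion_and_prf(truth, pred)
  a <- r$per_class[r$per_class$class == "A", ]
  expect_equal(a$recall, 0.8)      # TP=8, FN=2
  expect_equal(a$precision, 0.8)   # FP=2
  expect_equal(a$f1, 0.8)
  expect_equal(r$accuracy, 16 / 20)
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion), r$accuracy)
  expect_equal(rowSums(r$confusion), table(factor(truth))[rownames(r$confusion)],
               ignore_attr = TRUE)
  # F1 is the harmonic mean of recall and precision
  pc <- r$per_class
  expect_equal(pc$f1, 2 * pc$recall * pc$precision / (pc$recall + pc$precision))
  expect_error(confusion_and_prf(truth, pred[-1]), "length")
})

test_that("a never-predicted class is flagged, not dropped", {
  r <- confusion_and_prf(c("A", "A", "B"), c("A", "A", "A"))
  b <- r$per_class[r$per_class$class == "B", ]
  expect_true(b$undefined)
  expect_equal(b$precision, 0)
  expect_equal(b$f1, 0)
  all_right <- confusion_and_prf(c("A", "B"), c("A", "B"))
  expect_equal(all_right$accuracy, 1)
  expect_true(all(all_right$per_class$f1 == 1))
})

test_that("top-k accuracy counts the true label anywhere in the first k ranks", {
  truth <- c("A", "B", "C")
  ranked <- rbind(c("A", "B", "C"),
                  c("C", "B", "A"),
                  c("A", "B", "C"))
  expect_equal(topk_accuracy(truth, ranked, 1), 1 / 3)
  expect_equal(topk_accuracy(truth, ranked, 2), 2 / 3)
  expect_equal(topk_accuracy(truth, ranked, 3), 1)
  for (k in 1:2) {
    expect_gte(topk_accuracy(truth, ranked, k + 1),
               topk_accuracy(truth, ranked, k))
  }
  expect_error(topk_accuracy(truth, ranked, 0), "positive integer")
})

test_that("confidence tiers split on the strict 0.5 / 0.75 boundaries", {
  cs <- confidence_summary(c(0.9, 0.6, 0.4), c(TRUE, TRUE, TRUE))
  expect_equal(cs$tiers$n_correct, c(1L, 1L, 1L))
  bd <- confidence_summary(c(0.75, 0.5), c(TRUE, FALSE))
  expect_equal(bd$tiers$n[bd$tiers$tier == "medium"], 1L)  # 0.75 -> medium
  expect_equal(bd$tiers$n[bd$tiers$tier == "low"], 1L)     # 0.50 -> low
  expect_equal(bd$tiers$n[bd$tiers$tier == "high"], 0L)
  empty <- confidence_summary(numeric(), logical())
  expect_true(all(empty$tiers$n == 0))
  curve <- cs$curve
  expect_equal(curve$frac_correct[curve$threshold == 0], 1)
})

test_that("macro AUC matches pairwise concordance and its edge cases", {
  # one concordant and one discordant positive-negative pair -> 0.5
  expect_equal(macro_auc(c("pos", "pos", "neg"),
                         cbind(pos = c(0.9, 0.1, 0.8),
                               neg = c(0.1, 0.9, 0.2))), 0.5)
  truth <- rep(c("A", "B"), each = 3)
  perfect <- cbind(A = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3),
                   B = c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7))
  expect_equal(macro_auc(truth, perfect), 1)
  flat <- cbind(A = rep(0.5, 6), B = rep(0.5, 6))
  expect_equal(macro_auc(truth, flat), 0.5)
  expect_warning(
    macro_auc(c("A", "A"), cbind(A = c(0.6, 0.4), B = c(0.4, 0.6))),
    "absent")
})

test_that("macro AUC equals brute-force all-pairs counting", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    truth <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(truth)) < 3) next
    prob <- matrix(stats::runif(3 * n), n, dimnames = list(NULL, c("A", "B", "C")))
    brute <- mean(vapply(c("A", "B", "C"), function(cl) {
      s <- prob[, cl]
      pos <- which(truth == cl)
      neg <- which(truth != cl)
      pairs <- expand.grid(p = pos, q = neg)
      mean(ifelse(s[pairs$p] > s[pairs$q], 1,
                  ifelse(s[pairs$p] == s[pairs$q], 0.5, 0)))
    }, numeric(1)))
    expect_equal(macro_auc(truth, prob), brute, tolerance = 1e-12)
  }
})

test_that("count thinning is binomial, seeded and bounded", {
  rec <- hap_records(rep("chr1", 100), seq(1, 5000, 50), seq(1, 5000, 50),
                     rep("1", 100), count = 100)
  expect_identical(downsample_records(rec, 1), rec)
  d1 <- downsample_records(rec, 0.5, seed = 7)
  d2 <- downsample_records(rec, 0.5, seed = 7)
  expect_identical(d1, d2)
  total <- sum(d1$count)
  expect_lt(abs(total - 5000), 3 * sqrt(10000 * 0.25))  # 3 sigma
  expect_true(all(d1$count >= 1))
  expect_error(downsample_records(rec, 0), "\\(0, 1\\]")
  expect_error(downsample_records(rec, 1.5), "\\(0, 1\\]")
})

test_that("accuracy by covariate bin partitions the samples", {
  cov <- c(0.1, 0.2, 0.45, 0.8, 0.9)
  correct <- c(FALSE, TRUE, TRUE, TRUE, TRUE)
  tab <- accuracy_by_bin(cov, correct, breaks = c(0, 0.3, 0.6, 1))
  expect_equal(sum(tab$n), 5L)
  expect_equal(tab$accuracy, c(0.5, 1, 1))
  empty <- accuracy_by_bin(c(0.1, 0.2), c(TRUE, TRUE),
                           breaks = c(0, 0.3, 0.6, 1))
  expect_equal(empty$n[3], 0L)
  expect_true(is.na(empty$accuracy[3]))
})

test_that("percentages round half away from zero as printed tables do", {
  expect_equal(percent(55 / 68), 81)
  expect_equal(percent(63 / 68), 93)
  expect_equal(percent(0.125), 13)
  expect_equal(percent(c(0, 1)), c(0, 100))
})
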